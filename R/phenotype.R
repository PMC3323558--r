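#' Expected-lifespan reference table
#'
#' Wraps a data frame mapping (sex, birth-cohort band) to expected
#' lifespan in years, as used to convert attained ages into excess
#' longevity.  Lookups inside a band return the band value; years between
#' bands are linearly interpolated on band midpoints; years outside the
#' covered range use the nearest band (constant extrapolation).
#'
#' @param table data frame with columns `sex` (`male`/`female`),
#'   `cohort_start`, `cohort_end` (integer years, inclusive) and
#'   `expected_lifespan` (> 0 years).
#' @return An object of class `expected_lifespan_table`.
#' @export
expected_lifespan_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("sex", "cohort_start", "cohort_end", "expected_lifespan")
  if (!all(need %in% names(table)))
    stop("expected-lifespan table needs columns: ",
         paste(need, collapse = ", "))
  table$sex <- .normalize_sex(table$sex)
  if (any(table$expected_lifespan <= 0))
    stop("expected lifespan must be positive")
  if (any(table$cohort_end < table$cohort_start))
    stop("cohort_end before cohort_start")
  structure(table[order(table$sex, table$cohort_start), , drop = FALSE],
            class = c("expected_lifespan_table", "data.frame"))
}

#' Look up expected lifespan for sex and birth year
#'
#' @param table an [expected_lifespan_table()].
#' @param sex,birth_year vectors (recycled to common length).
#' @return Numeric vector of expected lifespans; `NA` where sex is unknown.
#' @export
expected_lifespan <- function(table, sex, birth_year) {
  stopifnot(inherits(table, "expected_lifespan_table"))
  nn <- max(length(sex), length(birth_year))
  sex <- .normalize_sex(rep_len(sex, nn))
  birth_year <- rep_len(as.numeric(birth_year), nn)
  out <- rep(NA_real_, nn)
  for (s in unique(sex)) {
    if (s == "unknown") next
    rows <- table[table$sex == s, , drop = FALSE]
    if (nrow(rows) == 0L) stop("no expected-lifespan rows for sex '", s, "'")
    sel <- which(sex == s & !is.na(birth_year))
    if (!length(sel)) next
    y <- birth_year[sel]
    band <- findInterval(y, rows$cohort_start)
    inband <- band >= 1L & y <= rows$cohort_end[pmax(band, 1L)]
    val <- rep(NA_real_, length(y))
    val[inband] <- rows$expected_lifespan[band[inband]]
    if (any(!inband)) {
      if (nrow(rows) == 1L) {
        val[!inband] <- rows$expected_lifespan
      } else {
        mids <- (rows$cohort_start + rows$cohort_end) / 2
        val[!inband] <- stats::approx(mids, rows$expected_lifespan,
                                      xout = y[!inband], rule = 2,
                                      ties = "ordered")$y
      }
    }
    out[sel] <- val
  }
  out
}

#' Excess longevity (EL)
#'
#' EL is an individual's observed lifespan minus the expected lifespan for
#' their sex and birth cohort.  Lifespan is the attained age when
#' recorded, otherwise death year minus birth year.
#'
#' @param phen data frame with columns `id`, `sex`, `birth_year` and
#'   `attained_age` and/or `death_year`.
#' @param table an [expected_lifespan_table()].
#' @param on_missing `"na"` (default) returns `NA` for individuals whose
#'   lifespan, sex or cohort cannot be resolved; `"error"` stops instead.
#' @return Named numeric vector of EL in years (names are ids).
#' @examples
#' lt <- expected_lifespan_table(data.frame(
#'   sex = c("male", "female"), cohort_start = 1850, cohort_end = 1950,
#'   expected_lifespan = c(79, 81)))
#' phen <- data.frame(id = "a", sex = "female", birth_year = 1900,
#'                    attained_age = 95.2)
#' excess_longevity(phen, lt)  # 95.2 - 81 = 14.2
#' @export
excess_longevity <- function(phen, table, on_missing = c("na", "error")) {
  on_missing <- match.arg(on_missing)
  stopifnot(is.data.frame(phen), "id" %in% names(phen))
  age <- if ("attained_age" %in% names(phen)) as.numeric(phen$attained_age)
         else rep(NA_real_, nrow(phen))
  if (all(c("birth_year", "death_year") %in% names(phen))) {
    fallback <- as.numeric(phen$death_year) - as.numeric(phen$birth_year)
    age[is.na(age)] <- fallback[is.na(age)]
  }
  sex <- if ("sex" %in% names(phen)) phen$sex else "unknown"
  by <- if ("birth_year" %in% names(phen)) phen$birth_year else NA
  exp_ls <- expected_lifespan(table, sex, by)
  el <- age - exp_ls
  if (on_missing == "error" && anyNA(el))
    stop("cannot compute EL for individual '",
         phen$id[is.na(el)][1L], "' (missing lifespan, sex or cohort)")
  stats::setNames(el, as.character(phen$id))
}

#' Familial excess longevity (FEL)
#'
#' FEL of individual i is the kinship-weighted average of EL over all
#' relatives: \eqn{FEL_i = \sum_{j \ne i} w_{ij} EL_j / \sum_{j \ne i}
#' w_{ij}} with \eqn{w_{ij} = 2\phi(i,j)} (expected allele-sharing
#' proportion), excluding i itself and normalizing by the weight sum so
#' that FEL stays on the years scale.  `NA` is returned when i has no
#' relative with positive kinship and known EL.
#'
#' @param ped a [pedigree()].
#' @param el named numeric vector of EL values (names are ids; individuals
#'   without an EL may be absent or `NA`).
#' @param ids ids to score; default all pedigree members.
#' @return Named numeric vector of FEL (years), `NA` where unscorable.
#' @export
familial_excess_longevity <- function(ped, el, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(ids)) ids <- ped$members$id
  ids <- as.character(ids)
  el_full <- rep(NA_real_, ped$n)
  hit <- match(names(el), ped$members$id)
  el_full[hit[!is.na(hit)]] <- as.numeric(el)[!is.na(hit)]
  scorable <- !is.na(el_full)
  fel <- rep(NA_real_, ped$n)
  comp <- .ped_components(ped)
  # kinship is block-diagonal over family components
  for (cc in seq_len(max(comp))) {
    idx <- which(comp == cc)
    ck <- .component_kinship(ped, idx)
    W <- 2 * ck$K
    diag(W) <- 0
    sc <- scorable[idx]
    e0 <- ifelse(sc, el_full[idx], 0)
    num <- as.numeric(W %*% e0)
    den <- as.numeric(W %*% as.numeric(sc))
    fel[idx] <- ifelse(den > 0, num / den, NA_real_)
  }
  stats::setNames(fel[.ped_index(ped, ids)], ids)
}

#' Affection selection rule
#'
#' Defines how "affected" individuals are selected: either by fixed EL and
#' FEL thresholds, by study-derived top quartiles of EL and FEL, by an EL
#' quartile alone, or by attained age regardless of sex or family history.
#' Thresholds are closed (\eqn{\ge}).
#'
#' @param mode one of `"el_fel_thresholds"`, `"el_fel_quartile"`,
#'   `"el_quartile"`, `"attained_age"`.
#' @param el_min,fel_min EL/FEL thresholds in years (mode
#'   `el_fel_thresholds`; defaults 3.0 and 1.75, the top-quartile cutoffs
#'   used in the study design this package reproduces).
#' @param age_min attained-age threshold in years (mode `attained_age`).
#' @return A `selection_rule` object.
#' @export
selection_rule <- function(mode = c("el_fel_thresholds", "el_fel_quartile",
                                    "el_quartile", "attained_age"),
                           el_min = 3.0, fel_min = 1.75, age_min = 95) {
  mode <- match.arg(mode)
  stopifnot(is.finite(el_min), is.finite(fel_min), is.finite(age_min))
  structure(list(mode = mode, el_min = el_min, fel_min = fel_min,
                 age_min = age_min), class = "selection_rule")
}

#' Select affected individuals
#'
#' @param records data frame with columns `id`, `EL`, `FEL`,
#'   `attained_age` (whichever the rule needs; `NA` never selects).
#' @param rule a [selection_rule()].
#' @return Character vector of selected ids.
#' @export
select_affected <- function(records, rule) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            inherits(rule, "selection_rule"))
  id <- as.character(records$id)
  sel <- switch(rule$mode,
    el_fel_thresholds = records$EL >= rule$el_min &
      records$FEL >= rule$fel_min,
    el_fel_quartile = {
      elq <- quartile_thresholds(records$EL)
      felq <- quartile_thresholds(records$FEL)
      records$EL >= elq & records$FEL >= felq
    },
    el_quartile = records$EL >= quartile_thresholds(records$EL),
    attained_age = records$attained_age >= rule$age_min
  )
  sel[is.na(sel)] <- FALSE
  id[sel]
}

#' Top-quartile threshold of a set of values
#'
#' Returns the 75th-percentile cutoff under the linear-interpolation
#' quantile definition (`stats::quantile` type 7), so that affection
#' status can be driven by data-derived quartiles rather than fixed
#' thresholds.  `NA` values are dropped.
#'
#' @param values numeric vector (at least 4 non-missing values).
#' @param prob probability of the cutoff; default 0.75.
#' @return The cutoff value.
#' @examples
#' quartile_thresholds(1:8)        # 6.25
#' quartile_thresholds(c(0, 0, 0, 100))  # 25
#' @export
quartile_thresholds <- function(values, prob = 0.75) {
  values <- values[!is.na(values)]
  if (length(values) < 4L)
    stop("need at least 4 non-missing values for a quartile threshold")
  unname(stats::quantile(values, probs = prob, type = 7))
}
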