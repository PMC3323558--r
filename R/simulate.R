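#' Configuration of a synthetic longevity study
#'
#' Bundles every parameter of the simulator: pedigree structure
#' (founder couples, generations, offspring counts), the causal longevity
#' allele (frequency, inheritance mode, all-cause mortality hazard
#' ratio), sex-specific Gompertz baseline mortality, the microsatellite
#' marker panel (chromosome lengths, spacing, allele counts, Dirichlet
#' concentration of frequencies), genotyping missingness, and the causal
#' locus position.
#'
#' Defaults emulate the study conditions this package reproduces: a
#' dominant longevity allele at frequency 0.01 with mortality hazard
#' ratio 0.5, multigenerational pedigrees with large sibships, and a
#' multiallelic panel at 3.4 cM average spacing.
#'
#' @param n_pedigrees number of independent pedigrees in a study.
#' @param n_founder_couples founder couples seeding each pedigree.
#' @param n_generations pedigree depth (>= 2).
#' @param mean_offspring mean number of offspring per couple.
#' @param offspring_dispersion negative-binomial size parameter of the
#'   offspring-count distribution; `Inf` (default) gives Poisson.
#' @param p_reproduce probability that an offspring founds a family
#'   (non-final generations).
#' @param p_within probability that a spouse is sought among unrelated
#'   same-generation pedigree members (connecting founder lineages)
#'   rather than marrying in.
#' @param causal_freq causal allele frequency (default 0.01).
#' @param inheritance `"dominant"` (default), `"additive"`, `"recessive"`.
#' @param hazard_ratio carrier all-cause mortality hazard ratio
#'   (default 0.5; values < 1 extend life).
#' @param gompertz_a,gompertz_b female Gompertz baseline hazard
#'   \eqn{h(t) = a e^{bt}} (per year).
#' @param male_hazard_scale multiplicative male excess hazard.
#' @param chr_lengths_cM numeric vector of chromosome lengths in cM.
#' @param marker_spacing_cM target mean marker spacing (default 3.4).
#' @param allele_range integer range of allele counts per marker.
#' @param dirichlet_conc Dirichlet concentration for marker allele
#'   frequencies.
#' @param missing_rate per-genotype missingness probability.
#' @param causal_chrom,causal_pos_cM map location of the causal locus.
#' @param base_birth_year,generation_gap birth-year model: generation g
#'   is born around `base_birth_year + (g-1) * generation_gap`.
#' @return A validated `sim_config` object (a list).
#' @export
sim_config <- function(n_pedigrees = 20L, n_founder_couples = 2L,
                       n_generations = 3L, mean_offspring = 3,
                       offspring_dispersion = Inf, p_reproduce = 0.8,
                       p_within = 0.25,
                       causal_freq = 0.01,
                       inheritance = c("dominant", "additive", "recessive"),
                       hazard_ratio = 0.5,
                       gompertz_a = 1e-4, gompertz_b = 0.085,
                       male_hazard_scale = 1.35,
                       chr_lengths_cM = 150,
                       marker_spacing_cM = 3.4,
                       allele_range = c(2L, 38L),
                       dirichlet_conc = 1,
                       missing_rate = 0.05,
                       causal_chrom = 1L, causal_pos_cM = 50,
                       base_birth_year = 1850, generation_gap = 28) {
  inheritance <- match.arg(inheritance)
  stopifnot(n_pedigrees >= 1, n_founder_couples >= 1, n_generations >= 2,
            mean_offspring > 0, offspring_dispersion > 0,
            p_reproduce > 0, p_reproduce <= 1, p_within >= 0, p_within <= 1,
            causal_freq > 0, causal_freq < 1, hazard_ratio > 0,
            gompertz_a > 0, gompertz_b > 0, male_hazard_scale > 0,
            all(chr_lengths_cM > 0), marker_spacing_cM > 0,
            length(allele_range) == 2L, allele_range[1L] >= 2L,
            allele_range[2L] >= allele_range[1L], dirichlet_conc > 0,
            missing_rate >= 0, missing_rate < 1,
            causal_chrom >= 1L, causal_chrom <= length(chr_lengths_cM),
            causal_pos_cM >= 0,
            causal_pos_cM <= chr_lengths_cM[causal_chrom])
  structure(as.list(environment()), class = "sim_config")
}

# ---- Gompertz lifespans --------------------------------------------------

#' Gompertz proportional-hazards lifespan distribution
#'
#' Hazard \eqn{h(t) = c\, a e^{bt}} with proportionality factor `hr`
#' (the carrier hazard ratio).  `rgompertz` samples by inverse-transform,
#' `qgompertz` is the closed-form quantile, `gompertz_mean` integrates
#' the survival function numerically.
#'
#' @param n number of draws.
#' @param p probability.
#' @param a,b Gompertz baseline parameters (per year).
#' @param hr hazard ratio (default 1).
#' @return Lifespans in years.
#' @export
rgompertz <- function(n, a, b, hr = 1) {
  stopifnot(a > 0, b > 0, hr > 0)
  u <- stats::runif(n)
  log1p(-b * log(u) / (a * hr)) / b
}

#' @rdname rgompertz
#' @export
qgompertz <- function(p, a, b, hr = 1) {
  stopifnot(a > 0, b > 0, hr > 0, all(p >= 0), all(p < 1))
  log1p(-b * log(1 - p) / (a * hr)) / b
}

#' @rdname rgompertz
#' @export
gompertz_mean <- function(a, b, hr = 1) {
  stopifnot(a > 0, b > 0, hr > 0)
  surv <- function(t) exp(-(a * hr / b) * expm1(b * t))
  stats::integrate(surv, 0, Inf, rel.tol = 1e-8)$value
}

# ---- pedigree simulation -------------------------------------------------

#' Simulate one multigenerational pedigree
#'
#' Builds a pedigree by random mating: founder couples seed generation 1;
#' each couple draws an offspring count (negative binomial, Poisson in
#' the `Inf`-dispersion limit); offspring of non-final generations found
#' families either with an unrelated same-generation pedigree member
#' (connecting founder lineages, probability `p_within`) or with a
#' married-in founder.  Spouses are always unrelated, so the pedigree
#' stays non-inbred; the graph is acyclic by construction.  Birth years
#' follow the generation clock in the config.
#'
#' @param cfg a [sim_config()].
#' @param prefix id prefix (used to keep ids unique across pedigrees).
#' @param seed optional integer seed.
#' @return A [pedigree()] whose members carry `generation` and
#'   `birth_year` columns.
#' @export
simulate_pedigree <- function(cfg, prefix = "P1", seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  counter <- 0L
  rows <- list()
  new_ind <- function(gen, sex, father = NA_character_,
                      mother = NA_character_, lineage) {
    counter <<- counter + 1L
    id <- sprintf("%s_%04d", prefix, counter)
    rows[[length(rows) + 1L]] <<- list(id = id, father = father,
                                       mother = mother, sex = sex,
                                       generation = gen, lineage = lineage)
    id
  }
  lineages <- new.env(parent = emptyenv())  # id -> founder-lineage set
  n_off <- function() {
    if (is.infinite(cfg$offspring_dispersion))
      stats::rpois(1L, cfg$mean_offspring)
    else stats::rnbinom(1L, size = cfg$offspring_dispersion,
                        mu = cfg$mean_offspring)
  }
  couples <- list()
  for (k in seq_len(cfg$n_founder_couples)) {
    f <- new_ind(1L, "male", lineage = 2L * k - 1L)
    m <- new_ind(1L, "female", lineage = 2L * k)
    assign(f, 2L * k - 1L, envir = lineages)
    assign(m, 2L * k, envir = lineages)
    couples[[length(couples) + 1L]] <- c(f, m)
  }
  next_lineage <- 2L * cfg$n_founder_couples
  for (g in seq_len(cfg$n_generations - 1L)) {
    children <- list()  # list of (id, lineage set, sex)
    for (cp in couples) {
      lin <- sort(unique(c(get(cp[1L], envir = lineages),
                           get(cp[2L], envir = lineages))))
      k <- n_off()
      for (o in seq_len(k)) {
        sex <- if (stats::runif(1L) < 0.5) "male" else "female"
        id <- new_ind(g + 1L, sex, father = cp[1L], mother = cp[2L],
                      lineage = NA)
        assign(id, lin, envir = lineages)
        children[[length(children) + 1L]] <-
          list(id = id, lineage = lin, sex = sex)
      }
    }
    if (g + 1L == cfg$n_generations) break
    couples <- list()
    unmarried <- children
    while (length(unmarried)) {
      ch <- unmarried[[1L]]
      unmarried <- unmarried[-1L]
      if (stats::runif(1L) > cfg$p_reproduce) next
      spouse <- NULL
      if (length(unmarried) && stats::runif(1L) < cfg$p_within) {
        ok <- which(vapply(unmarried, function(u)
          u$sex != ch$sex &&
            !any(u$lineage %in% ch$lineage), logical(1)))
        if (length(ok)) {
          pick <- ok[sample.int(length(ok), 1L)]
          spouse <- unmarried[[pick]]
          unmarried <- unmarried[-pick]
        }
      }
      if (is.null(spouse)) {
        next_lineage <- next_lineage + 1L
        sp_sex <- if (ch$sex == "male") "female" else "male"
        sp_id <- new_ind(g + 1L, sp_sex, lineage = next_lineage)
        assign(sp_id, next_lineage, envir = lineages)
        spouse <- list(id = sp_id, sex = sp_sex)
      }
      pair <- if (ch$sex == "male") c(ch$id, spouse$id)
              else c(spouse$id, ch$id)
      couples[[length(couples) + 1L]] <- pair
    }
    if (length(couples) == 0L)
      stop("pedigree died out before reaching ", cfg$n_generations,
           " generations; increase mean_offspring or p_reproduce")
  }
  members <- do.call(rbind, lapply(rows, function(r)
    data.frame(id = r$id, father = r$father, mother = r$mother,
               sex = r$sex, generation = r$generation,
               stringsAsFactors = FALSE)))
  members$birth_year <- cfg$base_birth_year +
    (members$generation - 1L) * cfg$generation_gap +
    round(stats::rnorm(nrow(members), 0, 3))
  validate_pedigree(members)
}

# Forest of cfg$n_pedigrees independent pedigrees as one pedigree object.
# A lineage that dies out before reaching the target depth (possible with
# small sibships) is redrawn.
.simulate_forest <- function(cfg, max_tries = 50L) {
  parts <- lapply(seq_len(cfg$n_pedigrees), function(k) {
    for (try in seq_len(max_tries)) {
      ped <- tryCatch(simulate_pedigree(cfg, prefix = sprintf("F%02d", k)),
                      error = function(e) NULL)
      if (!is.null(ped)) return(ped$members)
    }
    stop("pedigree simulation failed ", max_tries, " times; ",
         "config is infeasible (offspring mean too low?)")
  })
  members <- do.call(rbind, parts)
  members$fid <- sub("_.*$", "", members$id)
  validate_pedigree(members)
}

# ---- genotype simulation -------------------------------------------------

# Marker map implied by the config: evenly spaced markers at the target
# spacing on each chromosome.
.make_map <- function(cfg) {
  maps <- lapply(seq_along(cfg$chr_lengths_cM), function(cc) {
    len <- cfg$chr_lengths_cM[cc]
    nm <- max(1L, round(len / cfg$marker_spacing_cM))
    pos <- seq(cfg$marker_spacing_cM / 2, by = cfg$marker_spacing_cM,
               length.out = nm)
    pos <- pmin(pos, len)
    data.frame(chrom = as.character(cc),
               marker = sprintf("M%02d_%03d", cc, seq_len(nm)),
               position_cM = pos, stringsAsFactors = FALSE)
  })
  genetic_map(do.call(rbind, maps))
}

.make_freqs <- function(cfg, map) {
  qlist <- lapply(map$marker, function(mk) {
    K <- sample(seq(cfg$allele_range[1L], cfg$allele_range[2L]), 1L)
    q <- stats::rgamma(K, shape = cfg$dirichlet_conc)
    q <- pmax(q, 1e-6)
    q <- q / sum(q)
    stats::setNames(q, as.character(seq_len(K)))
  })
  names(qlist) <- map$marker
  allele_freq_table(qlist)
}

#' Simulate marker genotypes and causal-locus truth for a pedigree
#'
#' Builds the marker map and allele-frequency panel implied by the
#' config, then gene-drops every chromosome (founder haplotypes at
#' linkage equilibrium, Haldane recombination) jointly with the causal
#' locus inserted at its configured map position.  Genotyping missingness
#' is applied to the marker panel only -- never to the carrier truth.
#'
#' @param ped a [pedigree()].
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return List with `panel` (a [genotype_panel()]), `map`
#'   (a [genetic_map()]), `freqs` (the true [allele_freq_table()]),
#'   `carrier_copies` (named integer vector, 0/1/2 causal copies) and
#'   `causal` (chromosome and position).
#' @export
simulate_genotypes <- function(ped, cfg, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  map <- .make_map(cfg)
  freqs <- .make_freqs(cfg, map)
  n <- ped$n
  a1 <- NULL; a2 <- NULL
  copies <- integer(n)
  for (cc in unique(map$chrom)) {
    rows <- map[map$chrom == cc, , drop = FALSE]
    qlist <- unclass(freqs)[rows$marker]
    pos <- rows$position_cM
    causal_at <- NA_integer_
    if (as.character(cfg$causal_chrom) == cc) {
      causal_at <- findInterval(cfg$causal_pos_cM, pos) + 1L
      qlist <- append(qlist,
                      list(CAUSAL = c(wild = 1 - cfg$causal_freq,
                                      carrier = cfg$causal_freq)),
                      after = causal_at - 1L)
      pos <- append(pos, cfg$causal_pos_cM, after = causal_at - 1L)
    }
    drop <- .drop_engine(ped, qlist, 1L, haldane_theta(diff(pos)))
    m <- length(qlist)
    pat <- matrix(drop$pat, n, m)
    mat <- matrix(drop$mat, n, m)
    if (!is.na(causal_at)) {
      copies <- copies + (pat[, causal_at] == 2L) + (mat[, causal_at] == 2L)
      pat <- pat[, -causal_at, drop = FALSE]
      mat <- mat[, -causal_at, drop = FALSE]
    }
    lab1 <- matrix(NA_character_, n, ncol(pat))
    lab2 <- lab1
    for (j in seq_len(ncol(pat))) {
      labs <- names(unclass(freqs)[[rows$marker[j]]])
      lab1[, j] <- labs[pat[, j]]
      lab2[, j] <- labs[mat[, j]]
    }
    a1 <- cbind(a1, lab1)
    a2 <- cbind(a2, lab2)
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(a1)) < cfg$missing_rate,
                   nrow(a1), ncol(a1))
    a1[miss] <- NA_character_
    a2[miss] <- NA_character_
  }
  panel <- genotype_panel(ped$members$id, map$marker, a1, a2)
  list(panel = panel, map = map, freqs = freqs,
       carrier_copies = stats::setNames(as.integer(copies),
                                        ped$members$id),
       causal = list(chrom = as.character(cfg$causal_chrom),
                     position_cM = cfg$causal_pos_cM))
}

# hazard multiplier implied by causal copies under the inheritance mode
.hazard_multiplier <- function(copies, cfg) {
  switch(cfg$inheritance,
         dominant = ifelse(copies >= 1L, cfg$hazard_ratio, 1),
         recessive = ifelse(copies == 2L, cfg$hazard_ratio, 1),
         additive = cfg$hazard_ratio^copies)
}

.is_carrier <- function(copies, cfg) {
  if (cfg$inheritance == "recessive") copies == 2L else copies >= 1L
}

#' Simulate attained ages under Gompertz mortality with a carrier effect
#'
#' Lifespans are drawn by inverse-transform sampling from the Gompertz
#' distribution with the sex-specific baseline of the config; carriers of
#' the causal allele have their hazard multiplied by the configured
#' hazard ratio (dominant: any copy; recessive: two copies; additive:
#' per-copy factor).
#'
#' @param ped a [pedigree()].
#' @param carrier_copies named integer vector of causal-allele copies.
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return Named numeric vector of attained ages in years.
#' @export
simulate_lifespans <- function(ped, carrier_copies, cfg, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  copies <- carrier_copies[ped$members$id]
  copies[is.na(copies)] <- 0L
  hr <- .hazard_multiplier(copies, cfg)
  a <- ifelse(ped$members$sex == "male",
              cfg$gompertz_a * cfg$male_hazard_scale, cfg$gompertz_a)
  u <- stats::runif(ped$n)
  ages <- log1p(-cfg$gompertz_b * log(u) / (a * hr)) / cfg$gompertz_b
  stats::setNames(ages, ped$members$id)
}

# Expected-lifespan table implied by the non-carrier Gompertz baseline:
# one wide cohort band per sex.
.expected_table <- function(cfg) {
  years <- c(cfg$base_birth_year - 50,
             cfg$base_birth_year + 50 * cfg$n_generations)
  expected_lifespan_table(data.frame(
    sex = c("female", "male"),
    cohort_start = years[1L], cohort_end = years[2L],
    expected_lifespan = c(gompertz_mean(cfg$gompertz_a, cfg$gompertz_b),
                          gompertz_mean(cfg$gompertz_a *
                                          cfg$male_hazard_scale,
                                        cfg$gompertz_b))))
}

#' Simulate a complete synthetic linkage study
#'
#' Orchestrates [simulate_pedigree()] (a forest of independent
#' pedigrees), [simulate_genotypes()] and [simulate_lifespans()], and
#' derives the phenotype table and the expected-lifespan reference (the
#' non-carrier Gompertz mean lifespan by sex).
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed.
#' @return A `sim_study` list: `ped`, `panel`, `map`, `freqs`, `phen`
#'   (id, sex, birth_year, death_year, attained_age), `expected`,
#'   `carrier_copies`, `causal`, `cfg`, `seed`.
#' @export
simulate_study <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  ped <- .simulate_forest(cfg)
  geno <- simulate_genotypes(ped, cfg)
  ages <- simulate_lifespans(ped, geno$carrier_copies, cfg)
  phen <- data.frame(id = ped$members$id, sex = ped$members$sex,
                     birth_year = ped$members$birth_year,
                     death_year = ped$members$birth_year + round(ages),
                     attained_age = round(ages, 2),
                     stringsAsFactors = FALSE)
  ped$members$attained_age <- phen$attained_age
  ped$members$death_year <- phen$death_year
  structure(list(ped = ped, panel = geno$panel, map = geno$map,
                 freqs = geno$freqs, phen = phen,
                 expected = .expected_table(cfg),
                 carrier_copies = geno$carrier_copies,
                 causal = geno$causal, cfg = cfg, seed = seed),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", x$ped$n, "individuals in", x$cfg$n_pedigrees,
      "pedigrees;", length(x$map$marker), "markers on",
      length(unique(x$map$chrom)), "chromosome(s);",
      sum(.is_carrier(x$carrier_copies, x$cfg)), "carriers\n")
  invisible(x)
}

#' Evaluate an ascertainment design by simulation
#'
#' Repeatedly simulates studies (causal locus and lifespans only -- the
#' marker panel is skipped for speed), applies the selection rule to the
#' EL/FEL phenotypes, and estimates the positive predictive value
#' P(carrier | selected) and sensitivity P(selected | carrier) of the
#' design, with Monte Carlo standard errors.  This is the simulation used
#' to choose between candidate affected-selection criteria.
#'
#' @param cfg a [sim_config()].
#' @param rule a [selection_rule()].
#' @param n_sim number of simulated studies (>= 1).
#' @param seed optional integer seed.
#' @return List with `ppv`, `ppv_se`, `sensitivity`, `sensitivity_se`,
#'   `n_selected`, `n_carriers`, `n_individuals`, `prevalence`.  When no
#'   individual is selected in any replicate, `ppv` is `NA` (reported,
#'   not an error).
#' @export
evaluate_selection_design <- function(cfg, rule, n_sim = 50L, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(rule, "selection_rule"),
            n_sim >= 1L)
  if (!is.null(seed)) set.seed(seed)
  expected <- .expected_table(cfg)
  sel_car <- 0L; sel_tot <- 0L; car_tot <- 0L; n_tot <- 0L; car_sel <- 0L
  for (s in seq_len(n_sim)) {
    ped <- .simulate_forest(cfg)
    copies <- .drop_causal_only(ped, cfg)
    ages <- simulate_lifespans(ped, copies, cfg)
    phen <- data.frame(id = ped$members$id, sex = ped$members$sex,
                       birth_year = ped$members$birth_year,
                       attained_age = ages, stringsAsFactors = FALSE)
    el <- excess_longevity(phen, expected)
    fel <- familial_excess_longevity(ped, el)
    records <- data.frame(id = phen$id, EL = unname(el),
                          FEL = unname(fel[phen$id]),
                          attained_age = ages, stringsAsFactors = FALSE)
    sel <- select_affected(records, rule)
    carrier <- .is_carrier(copies, cfg)
    sel_car <- sel_car + sum(carrier[sel])
    sel_tot <- sel_tot + length(sel)
    car_tot <- car_tot + sum(carrier)
    car_sel <- car_sel + sum(carrier[sel])
    n_tot <- n_tot + ped$n
  }
  ppv <- if (sel_tot > 0L) sel_car / sel_tot else NA_real_
  sens <- if (car_tot > 0L) car_sel / car_tot else NA_real_
  binse <- function(p, n) if (is.na(p) || n == 0L) NA_real_
                          else sqrt(p * (1 - p) / n)
  list(ppv = ppv, ppv_se = binse(ppv, sel_tot),
       sensitivity = sens, sensitivity_se = binse(sens, car_tot),
       n_selected = sel_tot, n_carriers = car_tot, n_individuals = n_tot,
       prevalence = car_tot / n_tot)
}

# Drop only the biallelic causal locus; returns copies per individual.
.drop_causal_only <- function(ped, cfg) {
  qlist <- list(CAUSAL = c(wild = 1 - cfg$causal_freq,
                           carrier = cfg$causal_freq))
  drop <- .drop_engine(ped, qlist, 1L)
  copies <- (drop$pat[, 1L, 1L] == 2L) + (drop$mat[, 1L, 1L] == 2L)
  stats::setNames(as.integer(copies), ped$members$id)
}

#' Write a simulated study to pipeline input files
#'
#' Materializes one seeded [simulate_study()] as the file set the scan
#' pipeline reads: LINKAGE-style `.ped`, `.map`, allele-frequency TSV,
#' phenotype TSV and expected-lifespan TSV, each carrying the seed in a
#' `#` header comment.  The expected-lifespan table is derived from the
#' non-carrier Gompertz mean lifespan by sex.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @param seed integer seed recorded in the file headers.
#' @return Invisibly, a list with the `sim_study` object and the file
#'   `paths`.
#' @export
make_scan_fixture <- function(cfg, dir, seed = 1L) {
  study <- simulate_study(cfg, seed = seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(ped = file.path(dir, "study.ped"),
                map = file.path(dir, "study.map"),
                freq = file.path(dir, "study.freq.tsv"),
                phen = file.path(dir, "study.phen.tsv"),
                expected = file.path(dir, "study.expected.tsv"))
  hdr <- sprintf("# apmlink synthetic study (seed %d)", seed)
  write_ped(study$ped, study$panel, study$map, paths$ped, header = hdr)
  write_map(study$map, paths$map, header = hdr)
  write_freq(study$freqs, paths$freq, header = hdr)
  write_tsv(study$phen, paths$phen, header = hdr)
  write_tsv(as.data.frame(study$expected), paths$expected, header = hdr)
  invisible(list(study = study, paths = paths))
}
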