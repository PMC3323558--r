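#' Scan run configuration
#'
#' @param n_reps gene-drop replicates per chromosome (default 500).
#' @param seed master seed; every chromosome's null ensemble uses a seed
#'   derived deterministically from it, so runs are exactly reproducible.
#' @param weight APM allele-frequency weight form (see
#'   [sharing_statistic()]).
#' @param window_cM half-width of the adaptive multipoint marker window.
#' @param grid_step multipoint grid step in cM.
#' @param call_rate_min marker call-rate threshold (closed, \eqn{\ge}).
#' @param region_p nominal asymptotic p threshold that opens a reported
#'   multipoint region.
#' @param empirical empirical p convention (see [z_and_pvalues()]).
#' @param min_kinship kinship threshold for affected pairs (see
#'   [enumerate_affected_pairs()]).
#' @param controls optional character vector of control ids for allele
#'   frequency estimation.
#' @param selection a [selection_rule()].
#' @return A `scan_config` list.
#' @export
scan_config <- function(n_reps = 500L, seed = 1L,
                        weight = c("inverse_sqrt", "constant", "inverse"),
                        window_cM = 10, grid_step = 1,
                        call_rate_min = 0.5, region_p = 0.01,
                        empirical = c("plugin", "add_one"),
                        min_kinship = 0, controls = NULL,
                        selection = selection_rule()) {
  weight <- match.arg(weight)
  empirical <- match.arg(empirical)
  stopifnot(n_reps >= 2L, inherits(selection, "selection_rule"))
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 weight = weight, window_cM = window_cM,
                 grid_step = grid_step, call_rate_min = call_rate_min,
                 region_p = region_p, empirical = empirical,
                 min_kinship = min_kinship, controls = controls,
                 selection = selection), class = "scan_config")
}

.derive_seed <- function(seed, k) {
  s <- as.numeric(seed) %% 2147483563
  as.integer((s * 69069 + as.numeric(k) * 1234567) %% 2147483563) + 1L
}

#' Read and cross-validate all scan inputs
#'
#' Loads the pedigree + genotypes (.ped), genetic map (.map), phenotype
#' table, expected-lifespan table and (optionally) allele frequencies,
#' and cross-checks them: every genotyped individual and every phenotype
#' id must exist in the pedigree, every marker in the panel must be in
#' the map, and when frequencies are supplied every observed allele must
#' be present in the table (errors name the offending marker and
#' allele).  Allele code 0 is missing; genotypes are unordered.
#'
#' @param ped_file,map_file,phen_file,expected_file,freq_file file paths
#'   (`freq_file` may be `NULL`: frequencies are then estimated from the
#'   data by [estimate_allele_frequencies()] during [run_scan()]).
#' @param config a [scan_config()].
#' @return A `study_inputs` list: `ped`, `panel`, `map`, `freqs`
#'   (or `NULL`), `phen`, `expected`, `config`.
#' @export
read_study_inputs <- function(ped_file, map_file, phen_file, expected_file,
                              freq_file = NULL, config = scan_config()) {
  map <- read_map(map_file)
  pg <- read_ped(ped_file, map)
  members <- pg$fam
  phen <- read_phenotypes(phen_file)
  bad <- setdiff(phen$id, members$id)
  if (length(bad))
    stop("phenotype id '", bad[1L], "' is not in the pedigree file")
  extra <- setdiff(c("birth_year", "death_year", "attained_age"),
                   names(phen))
  for (col in extra) phen[[col]] <- NA_real_
  hit <- match(members$id, phen$id)
  members$birth_year <- phen$birth_year[hit]
  members$death_year <- phen$death_year[hit]
  members$attained_age <- phen$attained_age[hit]
  ped <- validate_pedigree(members)
  expected <- read_expected_lifespan(expected_file)
  freqs <- NULL
  if (!is.null(freq_file)) {
    freqs <- read_freq(freq_file)
    # every observed allele must have a frequency
    .code_panel(pg$panel, freqs,
                markers = intersect(pg$panel$markers, names(freqs)))
    miss <- setdiff(pg$panel$markers, names(freqs))
    if (length(miss))
      stop("marker '", miss[1L], "' absent from frequency table")
  }
  structure(list(ped = ped, panel = pg$panel, map = map, freqs = freqs,
                 phen = phen, expected = expected, config = config),
            class = "study_inputs")
}

#' Marker quality control by call rate
#'
#' Keeps markers successfully typed in at least `threshold` of subjects
#' (closed threshold).
#'
#' @param panel a [genotype_panel()].
#' @param threshold minimum call rate (default 0.50).
#' @return List with `panel` (filtered) and `qc`, a data frame
#'   (`marker`, `call_rate`, `n_alleles`, `kept`) carrying summary
#'   attributes `n_kept`, `n_total`, `pct_kept`.
#' @export
filter_markers <- function(panel, threshold = 0.5) {
  stopifnot(inherits(panel, "genotype_panel"))
  cr <- call_rate(panel)
  nall <- vapply(seq_along(panel$markers), function(j)
    length(unique(stats::na.omit(c(panel$a1[, j], panel$a2[, j])))),
    integer(1))
  kept <- cr >= threshold
  qc <- data.frame(marker = panel$markers, call_rate = unname(cr),
                   n_alleles = nall, kept = unname(kept),
                   stringsAsFactors = FALSE)
  attr(qc, "n_kept") <- sum(kept)
  attr(qc, "n_total") <- length(kept)
  attr(qc, "pct_kept") <- 100 * mean(kept)
  keep_idx <- which(kept)
  fpanel <- genotype_panel(panel$ids, panel$markers[keep_idx],
                           panel$a1[, keep_idx, drop = FALSE],
                           panel$a2[, keep_idx, drop = FALSE])
  list(panel = fpanel, qc = qc)
}

#' Estimate allele frequencies by simple counting
#'
#' Per marker, the frequency of allele g is the count of g among
#' non-missing control alleles divided by the total non-missing control
#' alleles.  A marker with no typed control falls back to counting over
#' all subjects, with a warning.
#'
#' @param panel a [genotype_panel()].
#' @param control_ids character vector of control ids; `NULL` counts
#'   over all subjects.
#' @return An [allele_freq_table()].
#' @export
estimate_allele_frequencies <- function(panel, control_ids = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  rows_all <- seq_along(panel$ids)
  rows <- if (is.null(control_ids)) rows_all
          else match(intersect(as.character(control_ids), panel$ids),
                     panel$ids)
  if (length(rows) == 0L) stop("no control subjects present in the panel")
  qlist <- lapply(seq_along(panel$markers), function(j) {
    al <- c(panel$a1[rows, j], panel$a2[rows, j])
    al <- al[!is.na(al)]
    if (length(al) == 0L) {
      warning("marker '", panel$markers[j],
              "' has no typed control; falling back to all subjects")
      al <- c(panel$a1[rows_all, j], panel$a2[rows_all, j])
      al <- al[!is.na(al)]
    }
    if (length(al) == 0L)
      stop("marker '", panel$markers[j], "' has no typed subject at all")
    tab <- table(al)
    q <- as.numeric(tab) / sum(tab)
    stats::setNames(q, names(tab))
  })
  names(qlist) <- panel$markers
  # a marker monomorphic in the counting sample gets a tiny complementary
  # pseudo-allele so the table stays valid; its null is then degenerate
  # and the locus is flagged, not scored
  for (j in seq_along(qlist)) {
    if (length(qlist[[j]]) < 2L) {
      q <- qlist[[j]] - 1e-6
      qlist[[j]] <- c(q, stats::setNames(1e-6, ".other"))
    }
  }
  allele_freq_table(qlist)
}

# lifespan used for EL and attained-age selection
.lifespan <- function(phen) {
  age <- if ("attained_age" %in% names(phen)) as.numeric(phen$attained_age)
         else rep(NA_real_, nrow(phen))
  if (all(c("birth_year", "death_year") %in% names(phen))) {
    fb <- as.numeric(phen$death_year) - as.numeric(phen$birth_year)
    age[is.na(age)] <- fb[is.na(age)]
  }
  age
}

#' Run the full APM genome scan
#'
#' End-to-end pipeline: EL/FEL phenotyping, affected selection, affected
#' relative-pair enumeration, marker QC, allele-frequency assembly, one
#' linked gene-drop null ensemble per chromosome (serving singlepoint,
#' window-multipoint and 1-cM-grid statistics at every locus -- the
#' per-marker marginal law of a linked drop equals an unlinked drop), Z
#' and asymptotic/empirical p per locus, and experiment-wise adjustment
#' by the distribution of the genome-wide maximum simulated Z across all
#' markers and multipoint intervals.  Fully deterministic under the
#' config seed.
#'
#' @param inputs a `study_inputs` list from [read_study_inputs()], or any
#'   list with elements `ped`, `panel`, `map`, `freqs` (may be `NULL`),
#'   `phen`, `expected`, `config`.
#' @return An `apm_scan` object: data frames `singlepoint`, `multipoint`,
#'   `grid` (scan rows with `z`, `p_asymptotic`, `p_empirical`,
#'   `p_adjusted`), `qc`, plus `records` (EL/FEL per individual),
#'   `affected`, `pairs`, `freqs` and `config`.
#' @export
run_scan <- function(inputs) {
  cfg <- inputs$config
  stopifnot(inherits(cfg, "scan_config"))
  ped <- inputs$ped
  el <- excess_longevity(inputs$phen, inputs$expected)
  fel <- familial_excess_longevity(ped, el, ids = inputs$phen$id)
  records <- data.frame(id = as.character(inputs$phen$id),
                        EL = unname(el), FEL = unname(fel),
                        attained_age = .lifespan(inputs$phen),
                        stringsAsFactors = FALSE)
  affected <- intersect(select_affected(records, cfg$selection),
                        inputs$panel$ids)
  pairs <- enumerate_affected_pairs(ped, affected, cfg$min_kinship)
  if (nrow(pairs) == 0L)
    stop("zero affected relative pairs under the selection rule; ",
         "nothing to scan")
  fm <- filter_markers(inputs$panel, cfg$call_rate_min)
  panel <- fm$panel
  qc <- fm$qc
  freqs <- inputs$freqs
  if (is.null(freqs))
    freqs <- estimate_allele_frequencies(panel, cfg$controls)
  map <- inputs$map[inputs$map$marker %in% panel$markers, , drop = FALSE]
  chroms <- unique(map$chrom)

  sp_list <- list(); wp_list <- list(); gr_list <- list()
  zobs_list <- list(); maxz_mat <- NULL
  for (k in seq_along(chroms)) {
    rows <- map[map$chrom == chroms[k], , drop = FALSE]
    set.seed(.derive_seed(cfg$seed, k))
    theta <- haldane_theta(diff(rows$position_cM))
    ens <- .score_ensemble(ped, pairs, panel, freqs,
                           markers = rows$marker, theta = theta,
                           n_reps = cfg$n_reps, weight = cfg$weight)
    loci_sp <- data.frame(chrom = chroms[k], marker = rows$marker,
                          position_cM = rows$position_cM,
                          stringsAsFactors = FALSE)
    sp <- .scan_rows(loci_sp, ens$obs, ens$null, ens$n_pairs, cfg$n_reps,
                     cfg$empirical)
    sets <- lapply(seq_len(nrow(rows)), function(i)
      which(abs(rows$position_cM - rows$position_cM[i]) <= cfg$window_cM))
    w_obs <- vapply(sets, function(s) sum(ens$obs[s]), numeric(1))
    w_null <- do.call(rbind, lapply(sets, function(s)
      colSums(ens$null[s, , drop = FALSE])))
    w_np <- vapply(sets, function(s) max(ens$n_pairs[s]), numeric(1))
    wp <- .scan_rows(loci_sp, w_obs, w_null, w_np, cfg$n_reps,
                     cfg$empirical)
    gc <- .grid_combine(ens, rows$position_cM, cfg$grid_step)
    loci_gr <- data.frame(chrom = chroms[k], position_cM = gc$grid,
                          stringsAsFactors = FALSE)
    gr <- .scan_rows(loci_gr, gc$obs, gc$null, gc$n_pairs, cfg$n_reps,
                     cfg$empirical)
    # null Z curves over every locus of this chromosome (all three
    # families of statistics), full-ensemble standardization
    zc <- .z_curves(c(ens$obs, w_obs, gc$obs),
                    rbind(ens$null, w_null, gc$null))
    cmax <- apply(zc$z_null, 2L, function(col)
      if (all(is.na(col))) -Inf else max(col, na.rm = TRUE))
    maxz_mat <- if (is.null(maxz_mat)) cmax else pmax(maxz_mat, cmax)
    sp_list[[k]] <- sp; wp_list[[k]] <- wp; gr_list[[k]] <- gr
  }
  adjust <- function(df) {
    df$p_adjusted <- vapply(df$z, function(z)
      if (is.na(z)) NA_real_ else mean(maxz_mat >= z), numeric(1))
    df
  }
  out <- structure(list(
    singlepoint = adjust(do.call(rbind, sp_list)),
    multipoint = adjust(do.call(rbind, wp_list)),
    grid = adjust(do.call(rbind, gr_list)),
    qc = qc, records = records, affected = affected, pairs = pairs,
    freqs = freqs, config = cfg), class = "apm_scan")
  rownames(out$singlepoint) <- rownames(out$multipoint) <-
    rownames(out$grid) <- NULL
  out
}

#' @export
print.apm_scan <- function(x, ...) {
  cat("apm_scan:", nrow(x$singlepoint), "markers,",
      length(unique(x$singlepoint$chrom)), "chromosome(s),",
      length(x$affected), "affected,", nrow(x$pairs), "pairs,",
      x$config$n_reps, "null replicates\n")
  ok <- !is.na(x$singlepoint$z)
  if (any(ok)) {
    top <- x$singlepoint[ok, ][which.max(x$singlepoint$z[ok]), ]
    cat(sprintf("  top singlepoint: %s (chr %s @ %.2f cM) Z = %.2f, p = %.5f, adjusted p = %.3f\n",
                top$marker, top$chrom, top$position_cM, top$z,
                top$p_asymptotic, top$p_adjusted))
  }
  ok <- !is.na(x$grid$z)
  if (any(ok)) {
    top <- x$grid[ok, ][which.max(x$grid$z[ok]), ]
    cat(sprintf("  top multipoint grid: chr %s @ %.2f cM, Z = %.2f\n",
                top$chrom, top$position_cM, top$z))
  }
  invisible(x)
}

#' Summarize significant multipoint regions
#'
#' Collapses contiguous grid positions whose nominal asymptotic p falls
#' below a reporting threshold into regions (per chromosome -- runs are
#' never merged across chromosomes), reporting the low/high bounds in
#' cM, the maximum Z, the minimum nominal p, and the adjusted p at the
#' peak.
#'
#' @param grid the `grid` data frame of an `apm_scan`.
#' @param p_threshold nominal p threshold opening a region (default
#'   0.01).
#' @return Data frame with `chrom`, `low_cM`, `high_cM`, `max_z`,
#'   `min_p`, `p_adjusted` (possibly zero rows).
#' @export
summarize_regions <- function(grid, p_threshold = 0.01) {
  out <- list()
  for (cc in unique(grid$chrom)) {
    g <- grid[grid$chrom == cc, , drop = FALSE]
    g <- g[order(g$position_cM), , drop = FALSE]
    sig <- !is.na(g$p_asymptotic) & g$p_asymptotic < p_threshold
    if (!any(sig)) next
    runs <- rle(sig)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (r in which(runs$values)) {
      seg <- g[starts[r]:ends[r], , drop = FALSE]
      peak <- which.max(seg$z)
      out[[length(out) + 1L]] <- data.frame(
        chrom = cc, low_cM = min(seg$position_cM),
        high_cM = max(seg$position_cM), max_z = seg$z[peak],
        min_p = min(seg$p_asymptotic), p_adjusted = seg$p_adjusted[peak],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), low_cM = numeric(0),
                      high_cM = numeric(0), max_z = numeric(0),
                      min_p = numeric(0), p_adjusted = numeric(0)))
  do.call(rbind, out)
}

#' Write scan results to a report directory
#'
#' Writes `singlepoint.tsv` (per-marker scores, Z and p-values),
#' `multipoint.tsv` (window statistics), `grid.tsv` (1-cM grid),
#' `regions.tsv` (contiguous multipoint regions below the reporting
#' threshold), and `qc.tsv`, each with a run-metadata '#' header (seed,
#' replicates, weight form, thresholds).  Map positions are reported in
#' cM with two decimals.
#'
#' @param scan an `apm_scan` from [run_scan()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_report <- function(scan, dir) {
  stopifnot(inherits(scan, "apm_scan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- scan$config
  hdr <- c(sprintf("# apmlink scan report"),
           sprintf("# seed=%d n_reps=%d weight=%s", cfg$seed, cfg$n_reps,
                   cfg$weight),
           sprintf("# selection=%s el_min=%.2f fel_min=%.2f age_min=%.1f",
                   cfg$selection$mode, cfg$selection$el_min,
                   cfg$selection$fel_min, cfg$selection$age_min),
           sprintf("# call_rate_min=%.2f region_p=%.3f window_cM=%.1f grid_step=%.1f",
                   cfg$call_rate_min, cfg$region_p, cfg$window_cM,
                   cfg$grid_step))
  fmt <- function(df) {
    df$position_cM <- sprintf("%.2f", df$position_cM)
    for (col in c("observed", "null_mean", "null_sd", "z"))
      if (col %in% names(df)) df[[col]] <- sprintf("%.4f", df[[col]])
    for (col in c("p_asymptotic", "p_empirical", "p_adjusted"))
      if (col %in% names(df)) df[[col]] <- sprintf("%.6g", df[[col]])
    df
  }
  paths <- c(singlepoint = file.path(dir, "singlepoint.tsv"),
             multipoint = file.path(dir, "multipoint.tsv"),
             grid = file.path(dir, "grid.tsv"),
             regions = file.path(dir, "regions.tsv"),
             qc = file.path(dir, "qc.tsv"))
  write_tsv(fmt(scan$singlepoint), paths["singlepoint"], header = hdr)
  write_tsv(fmt(scan$multipoint), paths["multipoint"], header = hdr)
  write_tsv(fmt(scan$grid), paths["grid"], header = hdr)
  regions <- summarize_regions(scan$grid, cfg$region_p)
  if (nrow(regions)) {
    regions$low_cM <- sprintf("%.2f", regions$low_cM)
    regions$high_cM <- sprintf("%.2f", regions$high_cM)
    regions$max_z <- sprintf("%.4f", regions$max_z)
    regions$min_p <- sprintf("%.6g", regions$min_p)
    regions$p_adjusted <- sprintf("%.6g", regions$p_adjusted)
  }
  write_tsv(regions, paths["regions"], header = hdr)
  qc <- scan$qc
  qc$call_rate <- sprintf("%.4f", qc$call_rate)
  write_tsv(qc, paths["qc"],
            header = c(hdr, sprintf("# markers kept: %d of %d (%.1f%%)",
                                    attr(scan$qc, "n_kept"),
                                    attr(scan$qc, "n_total"),
                                    attr(scan$qc, "pct_kept"))))
  invisible(paths)
}
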