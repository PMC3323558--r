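# Shared machinery: gene-drop ensembles scored per marker.
#
# An "ensemble" bundles, for one set of markers dropped jointly (one
# chromosome, or unlinked markers), the observed per-marker APM scores and
# an [m x R] matrix of null scores, with the observed missingness pattern
# masked in every replicate so that the null reflects the information
# actually available.

.pair_panel_codes <- function(pairs, panel, coded) {
  ia <- match(as.character(pairs$id_a), panel$ids)
  ib <- match(as.character(pairs$id_b), panel$ids)
  sub <- function(x, idx) {
    out <- x[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
    out[is.na(idx), ] <- NA_integer_
    out
  }
  A1 <- sub(coded$c1, ia); A2 <- sub(coded$c2, ia)
  B1 <- sub(coded$c1, ib); B2 <- sub(coded$c2, ib)
  incl <- !(is.na(A1) | is.na(B1))
  list(A1 = A1, A2 = A2, B1 = B1, B2 = B2, incl = incl)
}

# Build observed scores and an [m x R] null-score matrix for a marker set.
# theta = NULL means unlinked drops (independent markers).
.score_ensemble <- function(ped, pairs, panel, freqs, markers, theta,
                            n_reps, weight, block_reps = 100L) {
  coded <- .code_panel(panel, freqs, markers = markers, weight = weight)
  pc <- .pair_panel_codes(pairs, panel, coded)
  P <- nrow(pc$A1)
  m <- length(markers)
  offs_mat <- matrix(coded$offs, P, m, byrow = TRUE)
  obs <- .score_rep(pc$A1, pc$A2, pc$B1, pc$B2, pc$incl, coded$fglob,
                    offs_mat)
  n_pairs <- colSums(pc$incl)

  pi_idx <- .ped_index(ped, pairs$id_a)
  pj_idx <- .ped_index(ped, pairs$id_b)
  null <- matrix(NA_real_, m, n_reps)
  done <- 0L
  while (done < n_reps) {
    Rb <- min(block_reps, n_reps - done)
    drop <- .drop_engine(ped, coded$qlist, Rb, theta)
    for (r in seq_len(Rb)) {
      A1 <- .slab2(drop$pat, pi_idx, m, r)
      A2 <- .slab2(drop$mat, pi_idx, m, r)
      B1 <- .slab2(drop$pat, pj_idx, m, r)
      B2 <- .slab2(drop$mat, pj_idx, m, r)
      null[, done + r] <- .score_rep(A1, A2, B1, B2, pc$incl, coded$fglob,
                                     offs_mat)
    }
    done <- done + Rb
  }
  list(markers = markers, obs = obs, null = null, n_pairs = n_pairs)
}

.slab2 <- function(a, rows, m, r) {
  x <- a[rows, , r, drop = FALSE]
  dim(x) <- c(length(rows), m)
  x
}

.degenerate_error <- function(marker) {
  stop(structure(class = c("apmlink_degenerate_null", "error", "condition"),
                 list(message = paste0("degenerate null distribution (zero ",
                                       "variance) at locus '", marker, "'"),
                      call = sys.call(-1))))
}

#' Gene-drop null distribution of the APM score at a marker
#'
#' Generates `n_reps` Mendelian gene-drop replicates -- unlinked drops of
#' the single marker, or linked drops of its whole chromosome with
#' Haldane recombination -- and scores each with the APM sum over the same
#' affected pairs, masking the genotypes that are missing in the observed
#' panel so the null reflects the observed information pattern.
#'
#' @param ped a [pedigree()].
#' @param pairs affected pairs data frame (`id_a`, `id_b`).
#' @param panel a [genotype_panel()] (source of the missingness mask).
#' @param freqs an [allele_freq_table()].
#' @param marker marker to score.
#' @param map a [genetic_map()] (required for `mode = "linked"`).
#' @param n_reps number of replicates (>= 2); 500 is the conventional
#'   choice for a per-marker null.
#' @param mode `"unlinked"` (singlepoint null) or `"linked"` (drop the
#'   marker's chromosome jointly).
#' @param weight APM weight form (see [sharing_statistic()]).
#' @param seed optional integer seed.
#' @return Numeric vector of `n_reps` null APM scores.  A null with zero
#'   variance (e.g. a marker monomorphic in practice) raises an error of
#'   class `apmlink_degenerate_null` rather than returning a Z.
#' @export
null_distribution <- function(ped, pairs, panel, freqs, marker, map = NULL,
                              n_reps = 500L,
                              mode = c("unlinked", "linked"),
                              weight = c("inverse_sqrt", "constant",
                                         "inverse"),
                              seed = NULL) {
  mode <- match.arg(mode)
  weight <- match.arg(weight)
  stopifnot(n_reps >= 2L)
  if (!is.null(seed)) set.seed(seed)
  if (mode == "unlinked") {
    ens <- .score_ensemble(ped, pairs, panel, freqs, markers = marker,
                           theta = NULL, n_reps = n_reps, weight = weight)
    scores <- ens$null[1L, ]
  } else {
    if (is.null(map)) stop("mode 'linked' requires a genetic map")
    stopifnot(inherits(map, "genetic_map"))
    chrom <- map$chrom[map$marker == marker]
    if (length(chrom) == 0L) stop("marker '", marker, "' not in map")
    rows <- map[map$chrom == chrom, , drop = FALSE]
    theta <- haldane_theta(diff(rows$position_cM))
    ens <- .score_ensemble(ped, pairs, panel, freqs, markers = rows$marker,
                           theta = theta, n_reps = n_reps, weight = weight)
    scores <- ens$null[match(marker, rows$marker), ]
  }
  if (stats::sd(scores) == 0) .degenerate_error(marker)
  scores
}

#' Z-score and p-values from an observed score and its null sample
#'
#' Z is the observed score minus the null mean, divided by the null
#' standard deviation, signed so that excess sharing gives positive Z.
#' The asymptotic p-value is the upper tail of the standard normal; the
#' empirical p-value is the fraction of null scores greater than or equal
#' to the observed score (plug-in k/n by default; the `(k+1)/(n+1)`
#' convention avoids zero p-values).
#'
#' @param observed observed APM score.
#' @param null numeric vector of null scores (length >= 2, positive SD).
#' @param empirical `"plugin"` (default) or `"add_one"`.
#' @return List with `z`, `p_asymptotic`, `p_empirical`, `null_mean`,
#'   `null_sd`, `n_reps`.
#' @examples
#' z_and_pvalues(10, c(2, 4, 6))$z  # (10 - 4) / 2 = 3
#' @export
z_and_pvalues <- function(observed, null,
                          empirical = c("plugin", "add_one")) {
  empirical <- match.arg(empirical)
  stopifnot(length(null) >= 2L)
  mu <- mean(null)
  sdev <- stats::sd(null)
  if (sdev == 0) .degenerate_error("<observed locus>")
  z <- (observed - mu) / sdev
  k <- sum(null >= observed)  # ties count against the observed score
  n <- length(null)
  p_emp <- if (empirical == "plugin") k / n else (k + 1) / (n + 1)
  list(z = z, p_asymptotic = stats::pnorm(z, lower.tail = FALSE),
       p_empirical = p_emp, null_mean = mu, null_sd = sdev, n_reps = n)
}

#' Interpolation weights for a grid position between two markers
#'
#' A position x between flanking markers L and R receives the weighted
#' combination `w_L * score(L) + w_R * score(R)` with each weight
#' proportional to the inverse recombination probability with the
#' adjoining marker: `w_L = (1/theta(d_L)) / (1/theta(d_L) + 1/theta(d_R))`
#' under [haldane_theta()].  At a marker position the weight is 1 on that
#' marker.
#'
#' @param d_left,d_right distances (cM) from the grid position to the
#'   left and right flanking markers.
#' @return Numeric vector `c(w_left, w_right)` summing to 1.
#' @export
grid_weights <- function(d_left, d_right) {
  stopifnot(d_left >= 0, d_right >= 0)
  if (d_left == 0 && d_right == 0) return(c(0.5, 0.5))
  if (d_left == 0) return(c(1, 0))
  if (d_right == 0) return(c(0, 1))
  tl <- haldane_theta(d_left)
  tr <- haldane_theta(d_right)
  wl <- (1 / tl) / (1 / tl + 1 / tr)
  c(wl, 1 - wl)
}

# Scan-row assembly from observed/null scores at a set of loci.
.scan_rows <- function(loci, obs, null, n_pairs, n_reps, empirical) {
  L <- length(obs)
  out <- data.frame(loci, observed = obs,
                    null_mean = NA_real_, null_sd = NA_real_, z = NA_real_,
                    p_asymptotic = NA_real_, p_empirical = NA_real_,
                    p_adjusted = NA_real_,
                    n_pairs = n_pairs, n_reps = n_reps, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (l in seq_len(L)) {
    mu <- mean(null[l, ])
    sdev <- stats::sd(null[l, ])
    out$null_mean[l] <- mu
    out$null_sd[l] <- sdev
    if (sdev == 0) {
      out$degenerate[l] <- TRUE
      next
    }
    zz <- z_and_pvalues(obs[l], null[l, ], empirical = empirical)
    out$z[l] <- zz$z
    out$p_asymptotic[l] <- zz$p_asymptotic
    out$p_empirical[l] <- zz$p_empirical
  }
  out
}

# Null Z curves standardized by the full-ensemble moments; degenerate rows
# are dropped (flag returned).  Using the same moments for observed and
# null Z makes the genome-wide adjustment exactly compatible with the
# per-locus empirical p (adjusted >= empirical, single-locus reduction).
.z_curves <- function(obs, null) {
  mu <- rowMeans(null)
  sdev <- apply(null, 1L, stats::sd)
  ok <- sdev > 0
  z_obs <- (obs - mu) / ifelse(ok, sdev, NA_real_)
  z_null <- sweep(sweep(null, 1L, mu, "-"), 1L, ifelse(ok, sdev, NA_real_),
                  "/")
  list(z_obs = z_obs, z_null = z_null, ok = ok)
}

#' Multipoint APM scores over marker windows
#'
#' The multipoint APM statistic at a focal marker is the sum of the
#' per-marker APM scores over a set of adjacent markers; its null
#' distribution comes from linked gene drops of the whole chromosome
#' ([drop_linked_chromosome()]), which preserve the recombination-induced
#' dependence among markers.  By default the window at each marker
#' contains all markers within `window_cM` of it (spacing-adaptive); an
#' explicit `window` of adjacent markers may be supplied instead, giving
#' a single row.
#'
#' @param ped a [pedigree()].
#' @param pairs affected pairs data frame.
#' @param panel a [genotype_panel()].
#' @param freqs an [allele_freq_table()].
#' @param map a [genetic_map()].
#' @param chrom chromosome to scan.
#' @param window optional character vector of adjacent marker names.
#' @param window_cM half-width (cM) of the default adaptive window.
#' @param n_reps null replicates per chromosome (default 500).
#' @param weight APM weight form.
#' @param empirical empirical p convention (see [z_and_pvalues()]).
#' @param seed optional integer seed.
#' @return Data frame of scan rows (`chrom`, `marker`, `position_cM`,
#'   `observed`, `null_mean`, `null_sd`, `z`, `p_asymptotic`,
#'   `p_empirical`, `p_adjusted` (NA here; filled by genome-wide
#'   adjustment), `n_pairs`, `n_reps`, `degenerate`).
#' @export
multipoint_window <- function(ped, pairs, panel, freqs, map, chrom,
                              window = NULL, window_cM = 10,
                              n_reps = 500L,
                              weight = c("inverse_sqrt", "constant",
                                         "inverse"),
                              empirical = c("plugin", "add_one"),
                              seed = NULL) {
  weight <- match.arg(weight)
  empirical <- match.arg(empirical)
  stopifnot(inherits(map, "genetic_map"))
  rows <- map[map$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(rows) == 0L) stop("chromosome '", chrom, "' not in map")
  if (!is.null(seed)) set.seed(seed)
  theta <- haldane_theta(diff(rows$position_cM))
  ens <- .score_ensemble(ped, pairs, panel, freqs, markers = rows$marker,
                         theta = theta, n_reps = n_reps, weight = weight)
  if (!is.null(window)) {
    idx <- match(window, rows$marker)
    if (anyNA(idx))
      stop("window marker '", window[is.na(idx)][1L],
           "' not on chromosome '", chrom, "' (windows cannot span ",
           "chromosomes)")
    idx <- sort(idx)
    if (length(idx) > 1L && any(diff(idx) != 1L))
      stop("window markers must be adjacent on the map")
    sets <- list(idx)
    centers <- mean(rows$position_cM[idx])
    labels <- paste(window, collapse = "+")
  } else {
    sets <- lapply(seq_len(nrow(rows)), function(k)
      which(abs(rows$position_cM - rows$position_cM[k]) <= window_cM))
    centers <- rows$position_cM
    labels <- rows$marker
  }
  obs <- vapply(sets, function(s) sum(ens$obs[s]), numeric(1))
  null <- do.call(rbind, lapply(sets, function(s)
    colSums(ens$null[s, , drop = FALSE])))
  npairs <- vapply(sets, function(s) max(ens$n_pairs[s]), numeric(1))
  loci <- data.frame(chrom = as.character(chrom), marker = labels,
                     position_cM = centers, stringsAsFactors = FALSE)
  .scan_rows(loci, obs, null, npairs, n_reps, empirical)
}

# Grid combination of per-marker ensemble scores at `step`-cM intervals.
# Returns list(positions, obs, null, n_pairs).
.grid_combine <- function(ens, positions, step) {
  m <- length(positions)
  grid <- sort(unique(c(seq(positions[1L], positions[m], by = step),
                        positions)))
  obs <- numeric(length(grid))
  null <- matrix(0, length(grid), ncol(ens$null))
  npairs <- numeric(length(grid))
  for (k in seq_along(grid)) {
    x <- grid[k]
    at <- which(abs(positions - x) < 1e-9)
    if (length(at)) {
      # at a marker the weight is 1 on that marker
      obs[k] <- ens$obs[at[1L]]
      null[k, ] <- ens$null[at[1L], ]
      npairs[k] <- ens$n_pairs[at[1L]]
      next
    }
    L <- max(which(positions < x))
    R <- L + 1L
    w <- grid_weights(x - positions[L], positions[R] - x)
    obs[k] <- w[1L] * ens$obs[L] + w[2L] * ens$obs[R]
    null[k, ] <- w[1L] * ens$null[L, ] + w[2L] * ens$null[R, ]
    npairs[k] <- max(ens$n_pairs[L], ens$n_pairs[R])
  }
  list(grid = grid, obs = obs, null = null, n_pairs = npairs)
}

#' Multipoint APM scores on a 1-cM grid
#'
#' Between each pair of adjacent markers, scores are computed at
#' `step`-cM intervals as the convex combination of the two flanking
#' markers' APM scores with weights inversely proportional to the
#' recombination probability with each flank ([grid_weights()]).  The
#' identical linear combination is applied to every linked-null replicate
#' before Z computation, so observed and null live on the same scale.  A
#' single-marker chromosome degenerates to that marker.
#'
#' @inheritParams multipoint_window
#' @param step grid step in cM (default 1).
#' @return Data frame of scan rows at grid positions (marker positions
#'   included).
#' @export
grid_multipoint <- function(ped, pairs, panel, freqs, map, chrom,
                            step = 1, n_reps = 500L,
                            weight = c("inverse_sqrt", "constant",
                                       "inverse"),
                            empirical = c("plugin", "add_one"),
                            seed = NULL) {
  weight <- match.arg(weight)
  empirical <- match.arg(empirical)
  stopifnot(inherits(map, "genetic_map"))
  rows <- map[map$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(rows) == 0L) stop("chromosome '", chrom, "' not in map")
  if (!is.null(seed)) set.seed(seed)
  theta <- haldane_theta(diff(rows$position_cM))
  ens <- .score_ensemble(ped, pairs, panel, freqs, markers = rows$marker,
                         theta = theta, n_reps = n_reps, weight = weight)
  gc <- .grid_combine(ens, rows$position_cM, step)
  loci <- data.frame(chrom = as.character(chrom),
                     position_cM = gc$grid, stringsAsFactors = FALSE)
  .scan_rows(loci, gc$obs, gc$null, gc$n_pairs, n_reps, empirical)
}

#' Experiment-wise (genome-wide) p-value adjustment
#'
#' Adjusts per-locus evidence for the multiplicity of an entire scan by
#' referring each observed Z to the distribution of the genome-wide
#' maximum simulated Z: `adjusted p(locus) = proportion of null
#' replicates whose maximum Z across all loci >= observed Z at that
#' locus`.  Ties count as exceeding (conservative).  The adjusted p is
#' monotone non-increasing in the observed Z, never smaller than the
#' per-locus empirical p computed on the same ensemble, and reduces to
#' the empirical p for a single-locus scan.
#'
#' @param z_obs numeric vector of observed Z-scores (one per locus;
#'   `NA` entries, e.g. degenerate loci, get `NA` adjusted p).
#' @param z_null numeric matrix of null Z-scores, loci x replicates, on
#'   the same standardization as `z_obs`.
#' @return Numeric vector of adjusted p-values.
#' @export
genomewide_adjust <- function(z_obs, z_null) {
  z_null <- as.matrix(z_null)
  if (ncol(z_null) < 2L) stop("need at least 2 null replicates")
  if (ncol(z_null) < 20L)
    warning("fewer than 20 null replicates: adjusted p-values are an ",
            "unstable estimate of the genome-wide tail")
  maxz <- apply(z_null, 2L, max, na.rm = TRUE)
  vapply(z_obs, function(z) {
    if (is.na(z)) return(NA_real_)
    mean(maxz >= z)
  }, numeric(1))
}

#' Combine linkage Z-score curves across studies
#'
#' Weighted mean Z-score meta-analysis: at each shared map position,
#' \deqn{Z_{meta} = \sum_k w_k Z_k / \sqrt{\sum_k w_k^2}.}
#' With the default unit weights and two studies this is
#' \eqn{(Z_1 + Z_2)/\sqrt 2}.  Study curves are linearly interpolated in
#' cM onto a shared grid covering the overlap of the maps.
#'
#' @param studies list of data frames, each with columns `position_cM`
#'   and `z`, sorted by position.
#' @param weights numeric vector of per-study weights (> 0); default all
#'   1 (unweighted).
#' @param step grid step in cM (default 1).
#' @return Data frame with `position_cM`, `z_meta` and upper-tail normal
#'   `p`.
#' @examples
#' a <- data.frame(position_cM = c(0, 10), z = c(3, 3))
#' b <- data.frame(position_cM = c(0, 10), z = c(4, 4))
#' meta_combine(list(a, b))$z_meta[1]  # 7/sqrt(2) = 4.9497...
#' @export
meta_combine <- function(studies, weights = NULL, step = 1) {
  stopifnot(is.list(studies), length(studies) >= 2L)
  if (is.null(weights)) weights <- rep(1, length(studies))
  stopifnot(length(weights) == length(studies), all(weights > 0))
  lo <- max(vapply(studies, function(s) min(s$position_cM), numeric(1)))
  hi <- min(vapply(studies, function(s) max(s$position_cM), numeric(1)))
  if (lo > hi) stop("study maps do not overlap")
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)
  Z <- vapply(studies, function(s)
    stats::approx(s$position_cM, s$z, xout = grid, ties = "ordered")$y,
    numeric(length(grid)))
  Z <- matrix(Z, nrow = length(grid))
  z_meta <- as.numeric(Z %*% weights) / sqrt(sum(weights^2))
  data.frame(position_cM = grid, z_meta = z_meta,
             p = stats::pnorm(z_meta, lower.tail = FALSE))
}
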