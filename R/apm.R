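#' Genotype panel
#'
#' Container for observed genotypes: unordered allele pairs for a set of
#' individuals at a set of markers.  Alleles are stored as labels
#' (character); `NA` marks a missing allele.  A genotype is treated as
#' missing if either of its alleles is missing.
#'
#' @param ids character vector of individual ids (rows).
#' @param markers character vector of marker names (columns).
#' @param a1,a2 character matrices (individuals x markers) of allele
#'   labels; `NA` or `"0"` is missing.
#' @return A `genotype_panel` object.
#' @export
genotype_panel <- function(ids, markers, a1, a2) {
  ids <- as.character(ids)
  markers <- as.character(markers)
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "character"
  storage.mode(a2) <- "character"
  stopifnot(nrow(a1) == length(ids), ncol(a1) == length(markers),
            all(dim(a1) == dim(a2)))
  a1[a1 %in% c("0", "")] <- NA_character_
  a2[a2 %in% c("0", "")] <- NA_character_
  # missingness applies to the genotype, not single alleles
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_
  dimnames(a1) <- dimnames(a2) <- list(ids, markers)
  structure(list(ids = ids, markers = markers, a1 = a1, a2 = a2),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cr <- mean(!is.na(x$a1))
  cat("genotype_panel:", length(x$ids), "individuals x", length(x$markers),
      sprintf("markers (call rate %.1f%%)\n", 100 * cr))
  invisible(x)
}

#' Per-marker call rate of a panel
#'
#' @param panel a [genotype_panel()].
#' @return Named numeric vector: fraction of individuals with a complete
#'   genotype at each marker.
#' @export
call_rate <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  stats::setNames(colMeans(!is.na(panel$a1)), panel$markers)
}

# allele-frequency weight f(q) of the APM family
.weight_fun <- function(form = c("inverse_sqrt", "constant", "inverse")) {
  form <- match.arg(form)
  switch(form,
         constant = function(q) rep(1, length(q)),
         inverse_sqrt = function(q) 1 / sqrt(q),
         inverse = function(q) 1 / q)
}

#' APM pairwise sharing statistic
#'
#' The identity-by-state sharing score between the genotypes of two
#' affected relatives:
#' \deqn{S_{ij} = \frac14 \sum_{a=1}^{2} \sum_{b=1}^{2}
#'   \delta(G_{ia}, G_{jb})\, f(q(G_{ia}))}
#' where \eqn{\delta} is the Kronecker delta and \eqn{f} weights shared
#' alleles by their population frequency: `constant` \eqn{f(q)=1}
#' (plain IBS proportion, in \[0,1\]), `inverse_sqrt` \eqn{f(q)=1/\sqrt q}
#' (the classical choice, up-weighting sharing of rare alleles), or
#' `inverse` \eqn{f(q)=1/q}.
#'
#' @param g_i,g_j length-2 vectors of allele labels (unordered genotype).
#' @param q named numeric vector of allele frequencies for the marker.
#' @param weight weight form; default `"inverse_sqrt"`.
#' @return The sharing score \eqn{S_{ij}}.
#' @examples
#' q <- c(A = 0.25, B = 0.5, C = 0.25)
#' sharing_statistic(c("A", "A"), c("B", "C"), q)           # 0
#' sharing_statistic(c("A", "A"), c("A", "A"), q)           # 2
#' sharing_statistic(c("A", "A"), c("A", "B"), q)           # 1
#' @export
sharing_statistic <- function(g_i, g_j, q,
                              weight = c("inverse_sqrt", "constant",
                                         "inverse")) {
  stopifnot(length(g_i) == 2L, length(g_j) == 2L)
  g_i <- as.character(g_i); g_j <- as.character(g_j)
  if (anyNA(g_i) || anyNA(g_j)) stop("missing allele in sharing_statistic")
  absent <- setdiff(c(g_i, g_j), names(q))
  if (length(absent))
    stop("allele '", absent[1L], "' absent from frequency table")
  fw <- .weight_fun(match.arg(weight))
  s <- 0
  for (a in g_i)
    for (b in g_j)
      if (a == b) s <- s + fw(unname(q[a]))
  s / 4
}

# ---- vectorized scoring --------------------------------------------------

# Code a panel's allele labels against the frequency catalog.
# Returns integer matrices c1, c2 (NA preserved) plus the global weight
# lookup used by .score_block.
.code_panel <- function(panel, freqs, markers = panel$markers,
                        weight = "inverse_sqrt") {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(freqs, "allele_freq_table"))
  miss <- setdiff(markers, names(freqs))
  if (length(miss))
    stop("marker '", miss[1L], "' absent from frequency table")
  qlist <- freqs[markers]
  K <- vapply(qlist, length, integer(1))
  offs <- cumsum(c(0L, K[-length(K)]))
  fw <- .weight_fun(weight)
  fglob <- fw(unlist(qlist, use.names = FALSE))
  m <- length(markers)
  n <- length(panel$ids)
  c1 <- matrix(NA_integer_, n, m)
  c2 <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    labs <- names(qlist[[j]])
    col <- match(markers[j], panel$markers)
    if (is.na(col)) next  # marker not genotyped: stays all-missing
    x1 <- match(panel$a1[, col], labs)
    x2 <- match(panel$a2[, col], labs)
    bad1 <- !is.na(panel$a1[, col]) & is.na(x1)
    bad2 <- !is.na(panel$a2[, col]) & is.na(x2)
    if (any(bad1 | bad2)) {
      al <- c(panel$a1[, col][bad1], panel$a2[, col][bad2])[1L]
      stop("allele '", al, "' of marker '", markers[j],
           "' absent from frequency table")
    }
    c1[, j] <- x1
    c2[, j] <- x2
  }
  list(c1 = c1, c2 = c2, qlist = qlist, K = K, offs = offs, fglob = fglob)
}

# Per-marker APM sums over pairs for one set of genotype matrices.
# A1,A2,B1,B2: [P x m] local integer codes; incl: [P x m] logical
# (pair contributes at marker); returns length-m score vector.
.score_rep <- function(A1, A2, B1, B2, incl, fglob, offs_mat) {
  A1[!incl] <- 1L; A2[!incl] <- 1L; B1[!incl] <- 1L; B2[!incl] <- 1L
  S <- 0.25 * (((A1 == B1) + (A1 == B2)) * fglob[A1 + offs_mat] +
               ((A2 == B1) + (A2 == B2)) * fglob[A2 + offs_mat])
  S[!incl] <- 0
  colSums(S)
}

#' Observed APM score at one marker
#'
#' Sums the pairwise sharing statistic [sharing_statistic()] over all
#' affected relative pairs whose two members both have a complete
#' genotype at the marker; pairs with a missing genotype are excluded
#' from the sum.
#'
#' @param pairs data frame of pairs (`id_a`, `id_b`), as produced by
#'   [enumerate_affected_pairs()].
#' @param panel a [genotype_panel()].
#' @param marker marker name.
#' @param freqs an [allele_freq_table()].
#' @param weight weight form (see [sharing_statistic()]).
#' @return List with `score` (the APM sum) and `n_pairs` (number of
#'   contributing pairs).  Errors if no pair is informative.
#' @export
apm_observed <- function(pairs, panel, marker, freqs,
                         weight = c("inverse_sqrt", "constant", "inverse")) {
  weight <- match.arg(weight)
  stopifnot(is.data.frame(pairs), nrow(pairs) > 0L)
  coded <- .code_panel(panel, freqs, markers = marker, weight = weight)
  ia <- match(as.character(pairs$id_a), panel$ids)
  ib <- match(as.character(pairs$id_b), panel$ids)
  A1 <- coded$c1[ia, , drop = FALSE]; A2 <- coded$c2[ia, , drop = FALSE]
  B1 <- coded$c1[ib, , drop = FALSE]; B2 <- coded$c2[ib, , drop = FALSE]
  A1[is.na(ia), ] <- NA_integer_  # pair member not genotyped at all
  B1[is.na(ib), ] <- NA_integer_
  incl <- !(is.na(A1) | is.na(B1))
  if (!any(incl))
    stop("no informative pairs at marker '", marker, "'")
  A2[is.na(A2)] <- 1L; B2[is.na(B2)] <- 1L
  offs_mat <- matrix(coded$offs, nrow(A1), 1L, byrow = TRUE)
  sc <- .score_rep(A1, A2, B1, B2, incl, coded$fglob, offs_mat)
  list(score = unname(sc), n_pairs = sum(incl))
}
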