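#' Haldane map function
#'
#' Converts genetic map distance to a recombination fraction assuming no
#' crossover interference: \eqn{\theta = (1 - e^{-2d/100})/2} with `d` in
#' centimorgans.
#'
#' @param d_cM map distance in centimorgans (non-negative; vectorized).
#' @return Recombination fraction(s) in \[0, 0.5).
#' @examples
#' haldane_theta(0)    # 0
#' haldane_theta(10)   # 0.0906...
#' @export
haldane_theta <- function(d_cM) {
  if (any(d_cM < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * d_cM / 100)) / 2
}

#' Genetic marker map
#'
#' @param map data frame with columns `chrom`, `marker`, `position_cM`
#'   (optionally `position_bp`, accepted but unused).
#' @return A `genetic_map` object (data frame sorted by chromosome and
#'   position, marker names unique genome-wide).
#' @export
genetic_map <- function(map) {
  stopifnot(is.data.frame(map))
  need <- c("chrom", "marker", "position_cM")
  if (!all(need %in% names(map)))
    stop("genetic map needs columns: ", paste(need, collapse = ", "))
  map$chrom <- as.character(map$chrom)
  map$marker <- as.character(map$marker)
  map$position_cM <- as.numeric(map$position_cM)
  if (anyDuplicated(map$marker))
    stop("duplicate marker name in map: ",
         map$marker[duplicated(map$marker)][1L])
  map <- map[order(match(map$chrom, unique(map$chrom)), map$position_cM), ,
             drop = FALSE]
  rownames(map) <- NULL
  structure(map, class = c("genetic_map", "data.frame"))
}

#' Allele-frequency table
#'
#' @param freqs either a data frame with columns `marker`, `allele`,
#'   `frequency`, or a named list of named numeric vectors
#'   (marker -> allele -> frequency).  Each marker must have at least two
#'   alleles with positive frequencies summing to 1 (tolerance 1e-6).
#' @return An `allele_freq_table`: a named list of named frequency vectors.
#' @export
allele_freq_table <- function(freqs) {
  if (is.data.frame(freqs)) {
    need <- c("marker", "allele", "frequency")
    if (!all(need %in% names(freqs)))
      stop("frequency table needs columns: ", paste(need, collapse = ", "))
    freqs <- lapply(split(freqs, freqs$marker)[unique(freqs$marker)],
                    function(d) stats::setNames(as.numeric(d$frequency),
                                                as.character(d$allele)))
  }
  stopifnot(is.list(freqs), !is.null(names(freqs)))
  for (mk in names(freqs)) {
    q <- freqs[[mk]]
    if (length(q) < 2L)
      stop("marker '", mk, "' has fewer than 2 alleles")
    if (any(q <= 0))
      stop("marker '", mk, "' has non-positive allele frequency")
    if (abs(sum(q) - 1) > 1e-6)
      stop("allele frequencies of marker '", mk, "' sum to ", sum(q))
    if (is.null(names(q)) || anyDuplicated(names(q)))
      stop("marker '", mk, "' needs unique allele labels")
  }
  structure(freqs, class = "allele_freq_table")
}

# ---- gene-dropping engine ------------------------------------------------

# Meiosis phase indicators for one gamete: TRUE = grandpaternal strand.
# theta: recombination fractions between adjacent markers (length m-1).
# The phase along a chromosome is the running parity of the strand-switch
# indicators (uniform start, then Bernoulli(theta) switches), computed as
# a column-wise cumulative sum mod 2 without an inner loop.
.meiosis_mask <- function(m, R, theta) {
  p <- c(0.5, theta)  # switch probability entering each marker
  flips <- stats::runif(m * R) < p  # p recycles down each column
  if (m == 1L) return(matrix(flips, 1L, R))
  v <- cumsum(flips)
  ends <- v[seq.int(m, m * R, by = m)]
  off <- rep(c(0L, ends[-R]), each = m)
  matrix((v - off) %% 2L == 1L, m, R)
}

.slab <- function(a, i, m, R) {
  x <- a[i, , , drop = FALSE]
  dim(x) <- c(m, R)
  x
}

# Drop n_reps replicates of m markers through the pedigree.
# qlist: list of frequency vectors; theta: length m-1 recombination
# fractions (use rep(0.5, m-1) for unlinked markers).
# Returns integer arrays pat, mat of dim [n, m, R] with local allele codes.
.drop_engine <- function(ped, qlist, n_reps, theta = NULL) {
  n <- ped$n
  m <- length(qlist)
  R <- as.integer(n_reps)
  if (is.null(theta)) theta <- rep(0.5, max(m - 1L, 0L))
  pat <- array(0L, c(n, m, R))
  mat <- array(0L, c(n, m, R))
  fidx <- which(ped$fa == 0L)
  nF <- length(fidx)
  for (j in seq_len(m)) {
    q <- qlist[[j]]
    pat[fidx, j, ] <- sample.int(length(q), nF * R, replace = TRUE, prob = q)
    mat[fidx, j, ] <- sample.int(length(q), nF * R, replace = TRUE, prob = q)
  }
  for (i in ped$topo) {
    f <- ped$fa[i]
    if (f == 0L) next
    mo <- ped$mo[i]
    B <- .meiosis_mask(m, R, theta)
    G <- .slab(pat, f, m, R); H <- .slab(mat, f, m, R)
    G[!B] <- H[!B]
    pat[i, , ] <- G
    B <- .meiosis_mask(m, R, theta)
    G <- .slab(pat, mo, m, R); H <- .slab(mat, mo, m, R)
    G[!B] <- H[!B]
    mat[i, , ] <- G
  }
  list(pat = pat, mat = mat)
}

.as_gene_drop <- function(drop, ped, markers, qlist) {
  structure(list(pat = drop$pat, mat = drop$mat,
                 ids = ped$members$id, markers = markers,
                 alleles = lapply(qlist, names),
                 n_reps = dim(drop$pat)[3]),
            class = "gene_drop")
}

#' @export
print.gene_drop <- function(x, ...) {
  cat("gene_drop:", length(x$ids), "individuals x", length(x$markers),
      "markers x", x$n_reps, "replicates\n")
  invisible(x)
}

#' Extract one replicate of a gene drop as allele labels
#'
#' @param drop a `gene_drop` from [drop_unlinked()] or
#'   [drop_linked_chromosome()].
#' @param rep replicate index.
#' @return List with character matrices `paternal` and `maternal`
#'   (individuals x markers).
#' @export
drop_replicate <- function(drop, rep = 1L) {
  stopifnot(inherits(drop, "gene_drop"), rep >= 1L, rep <= drop$n_reps)
  m <- length(drop$markers)
  pat <- matrix(NA_character_, length(drop$ids), m,
                dimnames = list(drop$ids, drop$markers))
  mat <- pat
  for (j in seq_len(m)) {
    al <- drop$alleles[[j]]
    pat[, j] <- al[drop$pat[, j, rep]]
    mat[, j] <- al[drop$mat[, j, rep]]
  }
  list(paternal = pat, maternal = mat)
}

#' Gene-drop a single unlinked marker
#'
#' Simulates genotypes under the null of no linkage: founders receive two
#' alleles i.i.d. from the marker's population frequencies, and each
#' non-founder receives one uniformly chosen allele from each parent
#' (Mendelian segregation).
#'
#' @param ped a [pedigree()].
#' @param freqs an [allele_freq_table()].
#' @param marker marker name present in `freqs`.
#' @param n_reps number of replicates.
#' @param seed optional integer seed for reproducibility.
#' @return A `gene_drop` object with ordered (paternal, maternal) allele
#'   codes for every individual.
#' @export
drop_unlinked <- function(ped, freqs, marker, n_reps = 1L, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(freqs, "allele_freq_table"))
  if (!marker %in% names(freqs)) stop("unknown marker '", marker, "'")
  if (!is.null(seed)) set.seed(seed)
  qlist <- freqs[marker]
  .as_gene_drop(.drop_engine(ped, qlist, n_reps), ped, marker, qlist)
}

#' Gene-drop all markers of one chromosome with recombination
#'
#' Founder haplotypes are drawn marker-wise i.i.d. from the population
#' frequencies (linkage equilibrium); each meiosis starts from a uniformly
#' chosen parental haplotype and switches strands between adjacent markers
#' with probability given by [haldane_theta()] of the inter-marker
#' distance.  This is the null for multipoint statistics, which must
#' respect non-independence among linked markers.
#'
#' @param ped a [pedigree()].
#' @param freqs an [allele_freq_table()] covering the chromosome's markers.
#' @param map a [genetic_map()].
#' @param chrom chromosome identifier present in `map`.
#' @param n_reps number of replicates.
#' @param seed optional integer seed.
#' @return A `gene_drop` object covering the chromosome's markers in map
#'   order.
#' @export
drop_linked_chromosome <- function(ped, freqs, map, chrom, n_reps = 1L,
                                   seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(freqs, "allele_freq_table"),
            inherits(map, "genetic_map"))
  rows <- map[map$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(rows) == 0L) stop("chromosome '", chrom, "' not in map")
  missing_f <- setdiff(rows$marker, names(freqs))
  if (length(missing_f))
    stop("marker '", missing_f[1L], "' on chromosome '", chrom,
         "' has no allele frequencies")
  if (!is.null(seed)) set.seed(seed)
  qlist <- freqs[rows$marker]
  theta <- haldane_theta(diff(rows$position_cM))
  .as_gene_drop(.drop_engine(ped, qlist, n_reps, theta), ped, rows$marker,
                qlist)
}

#' Monte Carlo estimate of expected IBD sharing for a pair
#'
#' Drops a single fully informative locus (every founder carries two
#' unique alleles) through the pedigree `n_reps` times and returns the
#' mean proportion of alleles shared identical-by-descent between `i` and
#' `j`.  For non-inbred pairs this estimates \eqn{2\phi(i,j)}, providing
#' an independent simulation oracle for [kinship_coefficient()].
#'
#' @param ped a [pedigree()].
#' @param i,j individual ids.
#' @param n_reps number of replicates (>= 1).
#' @param seed optional integer seed.
#' @return List with `ibd` (mean shared proportion), `se` (Monte Carlo
#'   standard error) and `n_reps`.
#' @export
estimate_ibd <- function(ped, i, j, n_reps = 1000L, seed = NULL) {
  stopifnot(inherits(ped, "pedigree"), n_reps >= 1L)
  ii <- .ped_index(ped, i)
  jj <- .ped_index(ped, j)
  if (!is.null(seed)) set.seed(seed)
  n <- ped$n
  R <- as.integer(n_reps)
  pat <- matrix(0L, n, R)
  mat <- matrix(0L, n, R)
  fidx <- which(ped$fa == 0L)
  pat[fidx, ] <- 2L * fidx - 1L
  mat[fidx, ] <- 2L * fidx
  for (k in ped$topo) {
    f <- ped$fa[k]
    if (f == 0L) next
    mo <- ped$mo[k]
    b <- stats::runif(R) < 0.5
    pat[k, ] <- ifelse(b, pat[f, ], mat[f, ])
    b <- stats::runif(R) < 0.5
    mat[k, ] <- ifelse(b, pat[mo, ], mat[mo, ])
  }
  a1 <- pat[ii, ]; a2 <- mat[ii, ]
  b1 <- pat[jj, ]; b2 <- mat[jj, ]
  # maximum bipartite matching of the two allele pairs (0, 1 or 2 IBD)
  both <- (a1 == b1 & a2 == b2) | (a1 == b2 & a2 == b1)
  any1 <- (a1 == b1) | (a1 == b2) | (a2 == b1) | (a2 == b2)
  shared <- ifelse(both, 2L, ifelse(any1, 1L, 0L)) / 2
  list(ibd = mean(shared), se = stats::sd(shared) / sqrt(R), n_reps = R)
}
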