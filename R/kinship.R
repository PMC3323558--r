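#' Kinship coefficient between two pedigree members
#'
#' The kinship coefficient \eqn{\phi(i,j)} is the probability that one
#' allele sampled at random from \eqn{i} and one from \eqn{j} at an
#' autosomal locus are identical by descent.  It is computed by the
#' standard recursion \eqn{\phi(i,j) = \tfrac12[\phi(f_i,j)+\phi(m_i,j)]},
#' recursing on the individual that cannot be an ancestor of the other
#' (the one later in topological order), with founder boundary conditions
#' \eqn{\phi(\mathrm{founder}, j) = 0} for \eqn{j \ne} founder and
#' \eqn{\phi(i,i) = \tfrac12[1+\phi(f_i,m_i)]}.  The recursion is memoized,
#' so pedigrees where pairs are related through multiple lines of descent
#' are handled exactly (all paths are summed).
#'
#' @param ped a [pedigree()].
#' @param i,j individual ids.
#' @return The kinship coefficient, a number in \[0, 1\].
#' @examples
#' ped <- pedigree(id = c("f", "m", "a", "b"),
#'                 father = c(NA, NA, "f", "f"),
#'                 mother = c(NA, NA, "m", "m"))
#' kinship_coefficient(ped, "a", "b")  # full sibs: 0.25
#' @export
kinship_coefficient <- function(ped, i, j) {
  stopifnot(inherits(ped, "pedigree"))
  ii <- .ped_index(ped, i)
  jj <- .ped_index(ped, j)
  rank <- integer(ped$n)
  rank[ped$topo] <- seq_len(ped$n)
  cache <- new.env(parent = emptyenv())
  phi <- function(a, b) {
    if (a == 0L || b == 0L) return(0)
    # recurse on the individual later in topological order: it cannot be
    # an ancestor of the other
    if (rank[a] < rank[b]) { tmp <- a; a <- b; b <- tmp }
    key <- paste(a, b)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (a == b) {
      if (ped$fa[a] == 0L) 0.5 else 0.5 * (1 + phi(ped$fa[a], ped$mo[a]))
    } else if (ped$fa[a] == 0L) {
      0  # a founder that is not b shares no descent with anyone earlier
    } else {
      0.5 * (phi(ped$fa[a], b) + phi(ped$mo[a], b))
    }
    cache[[key]] <- val
    val
  }
  phi(ii, jj)
}

#' Full kinship matrix of a pedigree
#'
#' Computes \eqn{\phi} for all pairs by dynamic programming over the
#' topological order (parents before offspring), the matrix analogue of
#' the recursion in [kinship_coefficient()].  Cost is O(n^2).
#'
#' @param ped a [pedigree()].
#' @return A symmetric numeric matrix with dimnames set to the member ids;
#'   diagonal entries are \eqn{\phi(i,i) = \tfrac12(1+\phi(f_i,m_i))}
#'   (0.5 for non-inbred individuals).
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  K <- matrix(0, n, n, dimnames = list(ped$members$id, ped$members$id))
  pos <- 0L
  prev <- integer(0)
  for (i in ped$topo) {
    f <- ped$fa[i]; m <- ped$mo[i]
    if (f == 0L) {
      K[i, i] <- 0.5
      # founder: phi 0 with everyone already placed (no shared descent)
    } else {
      K[i, i] <- 0.5 * (1 + K[f, m])
      if (pos > 0L) {
        v <- 0.5 * (K[f, prev] + K[m, prev])
        K[i, prev] <- v
        K[prev, i] <- v
      }
    }
    pos <- pos + 1L
    prev <- c(prev, i)
  }
  K
}

#' Enumerate affected relative pairs
#'
#' Lists all unordered pairs of affected individuals whose kinship
#' coefficient exceeds a threshold.  By default pairs with \eqn{\phi > 0}
#' are kept (any known biological relationship); passing `min_kinship > 0`
#' keeps pairs with \eqn{\phi \ge} `min_kinship`.  A pair related through
#' several lines of descent appears once, with the summed-path \eqn{\phi}.
#'
#' @param ped a [pedigree()].
#' @param affected character vector of affected ids (subset of members).
#' @param min_kinship kinship threshold; default 0 means "any \eqn{\phi>0}".
#' @return A data frame with columns `id_a`, `id_b`, `kinship`,
#'   `relationship_class` (a best-effort label: `parent-offspring`,
#'   `full-sib`, `half-sib`, `grandparental`, `avuncular`, `first-cousin`,
#'   `double-first-cousin`, or `other`).  May have zero rows.
#' @export
enumerate_affected_pairs <- function(ped, affected, min_kinship = 0) {
  stopifnot(inherits(ped, "pedigree"))
  affected <- unique(as.character(affected))
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      kinship = numeric(0),
                      relationship_class = character(0))
  idx <- .ped_index(ped, affected)
  if (length(idx) < 2L) return(empty)
  keep <- if (min_kinship > 0) function(phi) phi >= min_kinship else
    function(phi) phi > 0
  comp <- .ped_components(ped)
  out <- list()
  # related pairs only exist within a family component
  for (cc in unique(comp[idx])) {
    aidx <- idx[comp[idx] == cc]
    if (length(aidx) < 2L) next
    ck <- .component_kinship(ped, which(comp == cc))
    pos <- match(aidx, ck$idx)
    K <- ck$K[pos, pos, drop = FALSE]
    ut <- which(upper.tri(K), arr.ind = TRUE)
    phi <- K[ut]
    sel <- keep(phi)
    if (!any(sel)) next
    ut <- ut[sel, , drop = FALSE]
    phi <- phi[sel]
    ia <- pos[ut[, 1L]]
    ib <- pos[ut[, 2L]]
    cls <- vapply(seq_along(phi), function(k)
      .relationship_class(ck$ped, ia[k], ib[k], phi[k]), character(1))
    out[[length(out) + 1L]] <- data.frame(
      id_a = ck$ped$members$id[ia], id_b = ck$ped$members$id[ib],
      kinship = phi, relationship_class = cls, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.relationship_class <- function(ped, a, b, phi) {
  fa <- ped$fa; mo <- ped$mo
  is_parent <- function(p, c) fa[c] == p || mo[c] == p
  if (is_parent(a, b) || is_parent(b, a)) return("parent-offspring")
  sibs <- function(x, y) fa[x] > 0L && fa[y] > 0L &&
    fa[x] == fa[y] && mo[x] == mo[y]
  if (sibs(a, b)) return("full-sib")
  share_one <- fa[a] > 0L && fa[b] > 0L &&
    xor(fa[a] == fa[b], mo[a] == mo[b])
  if (share_one) return("half-sib")
  grand <- function(p, c) (fa[c] > 0L && is_parent(p, fa[c])) ||
    (mo[c] > 0L && is_parent(p, mo[c]))
  if (grand(a, b) || grand(b, a)) return("grandparental")
  avunc <- function(u, c) (fa[c] > 0L && sibs(u, fa[c])) ||
    (mo[c] > 0L && sibs(u, mo[c]))
  if (avunc(a, b) || avunc(b, a)) return("avuncular")
  if (fa[a] > 0L && fa[b] > 0L) {
    ff <- sibs(fa[a], fa[b]) || sibs(fa[a], mo[b])
    mm <- sibs(mo[a], mo[b]) || sibs(mo[a], fa[b])
    if (ff && mm) return("double-first-cousin")
    if (ff || mm) return("first-cousin")
  }
  "other"
}
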