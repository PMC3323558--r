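#' Construct and validate a pedigree
#'
#' Builds a `pedigree` object from per-individual records.  A pedigree is a
#' directed acyclic parent--offspring graph; it may contain several
#' disconnected families (a forest), as is typical for study samples drawn
#' from a population genealogy.
#'
#' Validation enforces: unique non-missing ids; parents either both absent
#' (founder) or both present and resolvable to other members; no
#' self-parenting; the two parents of an individual are distinct; recorded
#' parental sexes are consistent (father male, mother female) whenever both
#' are known -- unknown-sex parents are permitted, since genealogies have
#' gaps and Mendelian transmission needs only two distinct parents; and the
#' parent--offspring graph is acyclic.
#'
#' @param id character vector of unique individual identifiers.
#' @param father,mother identifiers of the parents (`NA` for founders).
#' @param sex one of `"male"`, `"female"`, `"unknown"` (also accepts
#'   1/2/0 and "M"/"F" codings); defaults to unknown.
#' @param birth_year,death_year integer years or `NA`.
#' @param attained_age lifespan in years (real) or `NA`.
#' @return An object of class `pedigree`: a list with elements `members`
#'   (data frame), `fa`/`mo` (integer parent indices, 0 for founders),
#'   `topo` (topological order, parents before offspring), `founders`
#'   (character ids) and `n`.
#' @examples
#' ped <- pedigree(id = c("f", "m", "c"),
#'                 father = c(NA, NA, "f"),
#'                 mother = c(NA, NA, "m"),
#'                 sex = c("male", "female", "female"))
#' ped$founders
#' @seealso [validate_pedigree()], [kinship_coefficient()]
#' @export
pedigree <- function(id, father = NA, mother = NA, sex = "unknown",
                     birth_year = NA, death_year = NA, attained_age = NA) {
  members <- data.frame(
    id = as.character(id),
    father = as.character(rep_len(father, length(id))),
    mother = as.character(rep_len(mother, length(id))),
    sex = .normalize_sex(rep_len(sex, length(id))),
    birth_year = as.numeric(rep_len(birth_year, length(id))),
    death_year = as.numeric(rep_len(death_year, length(id))),
    attained_age = as.numeric(rep_len(attained_age, length(id))),
    stringsAsFactors = FALSE
  )
  validate_pedigree(members)
}

.normalize_sex <- function(x) {
  x <- as.character(x)
  out <- rep("unknown", length(x))
  out[x %in% c("male", "M", "m", "1")] <- "male"
  out[x %in% c("female", "F", "f", "2")] <- "female"
  out
}

#' Validate a collection of individuals as a pedigree
#'
#' Accepts a data frame of members (columns `id`, `father`, `mother` and
#' optionally `sex`, `birth_year`, `death_year`, `attained_age`) or an
#' existing `pedigree` object (the operation is idempotent).  Founders are
#' identified and a topological order is cached for downstream kinship and
#' gene-dropping computations.
#'
#' @param members data frame of individuals, or a `pedigree`.
#' @return A validated `pedigree` object.
#' @export
validate_pedigree <- function(members) {
  if (inherits(members, "pedigree")) members <- members$members
  if (!is.data.frame(members) || nrow(members) == 0L)
    stop("pedigree requires a non-empty data frame of members")
  for (col in c("id", "father", "mother"))
    if (!col %in% names(members))
      stop("members must have column '", col, "'")
  members$id <- as.character(members$id)
  members$father <- as.character(members$father)
  members$mother <- as.character(members$mother)
  if (!"sex" %in% names(members)) members$sex <- "unknown"
  members$sex <- .normalize_sex(members$sex)
  for (col in c("birth_year", "death_year", "attained_age"))
    if (!col %in% names(members)) members[[col]] <- NA_real_
  # parent codes "0" / "" are treated as missing (LINKAGE convention)
  members$father[members$father %in% c("0", "")] <- NA_character_
  members$mother[members$mother %in% c("0", "")] <- NA_character_

  id <- members$id
  if (anyNA(id) || any(id == "")) stop("missing individual id")
  if (anyDuplicated(id)) stop("duplicate individual id: ",
                              id[duplicated(id)][1L])

  fa_chr <- members$father
  mo_chr <- members$mother
  one_parent <- xor(is.na(fa_chr), is.na(mo_chr))
  if (any(one_parent))
    stop("individual '", id[one_parent][1L],
         "' has exactly one recorded parent; parents must be both known or both unknown")
  self_par <- !is.na(fa_chr) & (fa_chr == id | mo_chr == id)
  if (any(self_par))
    stop("individual '", id[self_par][1L], "' is recorded as its own parent")
  same_par <- !is.na(fa_chr) & fa_chr == mo_chr
  if (any(same_par))
    stop("individual '", id[same_par][1L],
         "' has the same individual as both parents")

  fa <- match(fa_chr, id)
  mo <- match(mo_chr, id)
  dangling <- (!is.na(fa_chr) & is.na(fa)) | (!is.na(mo_chr) & is.na(mo))
  if (any(dangling)) {
    bad <- c(fa_chr[!is.na(fa_chr) & is.na(fa)],
             mo_chr[!is.na(mo_chr) & is.na(mo)])
    stop("dangling parent reference: '", bad[1L], "' is not a pedigree member")
  }
  fa[is.na(fa)] <- 0L
  mo[is.na(mo)] <- 0L

  fsex <- members$sex[fa[fa > 0L]]
  if (any(fsex == "female"))
    stop("father of individual '", id[fa > 0L][fsex == "female"][1L],
         "' is recorded as female")
  msex <- members$sex[mo[mo > 0L]]
  if (any(msex == "male"))
    stop("mother of individual '", id[mo > 0L][msex == "male"][1L],
         "' is recorded as male")

  topo <- .topo_sort(fa, mo)
  if (is.null(topo))
    stop("cycle detected in parent-offspring graph")

  structure(list(members = members, fa = fa, mo = mo, topo = topo,
                 founders = id[fa == 0L], n = length(id)),
            class = "pedigree")
}

# Kahn's algorithm on the parent->offspring DAG; NULL if cyclic.
.topo_sort <- function(fa, mo) {
  n <- length(fa)
  indeg <- as.integer((fa > 0L) + (mo > 0L))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (fa[i] > 0L) children[[fa[i]]] <- c(children[[fa[i]]], i)
    if (mo[i] > 0L) children[[mo[i]]] <- c(children[[mo[i]]], i)
  }
  queue <- which(indeg == 0L)
  out <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) return(NULL)
  out
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", x$n, "members,", length(x$founders), "founders\n")
  nf <- sum(x$fa > 0L)
  cat("  non-founders:", nf, "\n")
  invisible(x)
}

.ped_index <- function(ped, ids) {
  idx <- match(as.character(ids), ped$members$id)
  if (anyNA(idx))
    stop("unknown individual id: '", as.character(ids)[is.na(idx)][1L], "'")
  idx
}

# Connected components of the family graph (parent links, undirected).
# Returns an integer component id per member.  Lets kinship-based
# operations exploit the block structure of multi-family study samples.
.ped_components <- function(ped) {
  parent <- seq_len(ped$n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  for (i in seq_len(ped$n)) {
    if (ped$fa[i] > 0L) union2(i, ped$fa[i])
    if (ped$mo[i] > 0L) union2(i, ped$mo[i])
  }
  roots <- vapply(seq_len(ped$n), find, integer(1))
  match(roots, unique(roots))
}

# Kinship matrix of one component, with member indices.
.component_kinship <- function(ped, idx) {
  sub <- validate_pedigree(ped$members[idx, , drop = FALSE])
  list(idx = idx, ped = sub, K = kinship_matrix(sub))
}
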