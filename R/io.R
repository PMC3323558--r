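# File formats: LINKAGE-style .ped (FID IID PAT MAT SEX PHENO + two
# allele columns per marker, 0 = missing), PLINK-style .map (chrom,
# marker, position in cM, optional bp), and headered TSV for everything
# else.  '#'-prefixed lines are comments everywhere.

#' Read a headered TSV file with '#' comments
#'
#' The generic reader behind the pipeline's tabular inputs (allele
#' frequencies, phenotypes, expected lifespans, demographic summaries).
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_table_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write a data frame as TSV with an optional '#' header comment
#'
#' @param df data frame.
#' @param path output path.
#' @param header optional character vector of comment lines (written
#'   with a leading `#`).
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(ifelse(startsWith(header, "#"), header,
                      paste("#", header)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

#' Read a genetic map (.map)
#'
#' Whitespace-separated, no header: chromosome, marker, position in cM,
#' optionally a physical position (bp; accepted but unused).
#'
#' @param path file path.
#' @return A [genetic_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(d) < 3L) stop("map file needs >= 3 columns: ", path)
  map <- data.frame(chrom = as.character(d[[1L]]),
                    marker = as.character(d[[2L]]),
                    position_cM = as.numeric(d[[3L]]),
                    stringsAsFactors = FALSE)
  if (ncol(d) >= 4L) map$position_bp <- d[[4L]]
  genetic_map(map)
}

#' @rdname read_map
#' @param map a [genetic_map()].
#' @param header optional '#' comment lines.
#' @export
write_map <- function(map, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(ifelse(startsWith(header, "#"), header,
                      paste("#", header)), con)
  utils::write.table(as.data.frame(map)[c("chrom", "marker",
                                          "position_cM")],
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
}

#' Read a LINKAGE-style pedigree + genotype file (.ped)
#'
#' Whitespace-separated, no header; columns are family id, individual
#' id, father, mother, sex (1 = male, 2 = female, 0 = unknown), a
#' phenotype placeholder, then two allele columns per marker in map
#' order; allele code 0 is missing.  Unordered genotypes are normalized
#' downstream; individual ids must be unique across families.
#'
#' @param path file path.
#' @param map the [genetic_map()] supplying marker names and order.
#' @return List with `fam` (data frame: fid, id, father, mother, sex)
#'   and `panel` (a [genotype_panel()]).
#' @export
read_ped <- function(path, map) {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(inherits(map, "genetic_map"))
  d <- utils::read.table(path, header = FALSE, comment.char = "#",
                         colClasses = "character",
                         stringsAsFactors = FALSE)
  m <- nrow(map)
  if (ncol(d) != 6L + 2L * m)
    stop("ped file has ", ncol(d), " columns; expected ", 6L + 2L * m,
         " for ", m, " markers (", path, ")")
  fam <- data.frame(fid = d[[1L]], id = d[[2L]], father = d[[3L]],
                    mother = d[[4L]], sex = .normalize_sex(d[[5L]]),
                    stringsAsFactors = FALSE)
  a1 <- as.matrix(d[, 6L + 2L * seq_len(m) - 1L, drop = FALSE])
  a2 <- as.matrix(d[, 6L + 2L * seq_len(m), drop = FALSE])
  panel <- genotype_panel(fam$id, map$marker, a1, a2)
  list(fam = fam, panel = panel)
}

#' Write a pedigree and its genotypes as a .ped file
#'
#' @param ped a [pedigree()]; a `fid` member column is used as the
#'   family id when present.
#' @param panel a [genotype_panel()] (ids must match the pedigree).
#' @param map a [genetic_map()] fixing the marker order.
#' @param path output path.
#' @param header optional '#' comment lines.
#' @export
write_ped <- function(ped, panel, map, path, header = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(panel, "genotype_panel"),
            inherits(map, "genetic_map"))
  ids <- ped$members$id
  ridx <- match(ids, panel$ids)
  if (anyNA(ridx)) stop("panel is missing genotyped rows for pedigree ids")
  cidx <- match(map$marker, panel$markers)
  if (anyNA(cidx)) stop("panel is missing markers present in the map")
  sexcode <- c(male = "1", female = "2", unknown = "0")[ped$members$sex]
  fid <- if ("fid" %in% names(ped$members)) ped$members$fid else "F1"
  na0 <- function(x) ifelse(is.na(x), "0", x)
  cols <- vector("list", 2L * nrow(map))
  for (j in seq_len(nrow(map))) {
    cols[[2L * j - 1L]] <- na0(panel$a1[ridx, cidx[j]])
    cols[[2L * j]] <- na0(panel$a2[ridx, cidx[j]])
  }
  out <- cbind(fid, ids, na0(ped$members$father), na0(ped$members$mother),
               sexcode, "0", do.call(cbind, cols))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(ifelse(startsWith(header, "#"), header,
                      paste("#", header)), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read an allele-frequency table (TSV: marker, allele, frequency)
#'
#' @param path file path.
#' @return An [allele_freq_table()].
#' @export
read_freq <- function(path) {
  d <- read_table_file(path)
  allele_freq_table(d)
}

#' @rdname read_freq
#' @param freqs an [allele_freq_table()].
#' @param header optional '#' comment lines.
#' @export
write_freq <- function(freqs, path, header = NULL) {
  stopifnot(inherits(freqs, "allele_freq_table"))
  d <- do.call(rbind, lapply(names(freqs), function(mk)
    data.frame(marker = mk, allele = names(freqs[[mk]]),
               frequency = unname(freqs[[mk]]),
               stringsAsFactors = FALSE)))
  write_tsv(d, path, header = header)
}

#' Read a phenotype table (TSV: id, sex, birth_year, death_year,
#' attained_age)
#'
#' @param path file path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  d <- read_table_file(path)
  need <- c("id", "sex")
  if (!all(need %in% names(d)))
    stop("phenotype table needs at least columns: ",
         paste(need, collapse = ", "))
  if (!any(c("attained_age", "death_year") %in% names(d)))
    stop("phenotype table needs attained_age or death_year")
  d$id <- as.character(d$id)
  d
}

#' Read an expected-lifespan table (TSV: sex, cohort_start, cohort_end,
#' expected_lifespan)
#'
#' @param path file path.
#' @return An [expected_lifespan_table()].
#' @export
read_expected_lifespan <- function(path) {
  expected_lifespan_table(read_table_file(path))
}
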