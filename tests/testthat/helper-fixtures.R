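# Hand-built pedigrees and small panels used across the test files.

# founder couple with two children
fix_trio <- function() {
  pedigree(id = c("f", "m", "c"),
           father = c(NA, NA, "f"), mother = c(NA, NA, "m"),
           sex = c("male", "female", "female"))
}

# three generations: grandparents -> (parent P, uncle U) -> children;
# covers parent-offspring, full sibs, grandparental, avuncular and
# first-cousin pairs
fix_threegen <- function() {
  pedigree(
    id     = c("G1", "G2", "P", "PS", "U", "US", "C1", "C2", "D1"),
    father = c(NA, NA, "G1", NA, "G1", NA, "P", "P", "U"),
    mother = c(NA, NA, "G2", NA, "G2", NA, "PS", "PS", "US"),
    sex    = c("male", "female", "male", "female", "male", "female",
               "female", "male", "female"))
}

# two brothers married to two sisters: their children K1 and K2 are
# double first cousins (phi = 1/8)
fix_double_cousins <- function() {
  pedigree(
    id     = c("X1", "X2", "Y1", "Y2", "B1", "B2", "S1", "S2", "K1", "K2"),
    father = c(NA, NA, NA, NA, "X1", "X1", "Y1", "Y1", "B1", "B2"),
    mother = c(NA, NA, NA, NA, "X2", "X2", "Y2", "Y2", "S1", "S2"),
    sex    = c("male", "female", "male", "female", "male", "male",
               "female", "female", "male", "female"))
}

# a forest fixture with every relative class used by the IBD-oracle
# comparisons: parent-offspring, full sibs, avuncular, first cousins,
# double first cousins
fix_pair_classes <- function() {
  a <- fix_threegen()$members
  b <- fix_double_cousins()$members
  validate_pedigree(rbind(a, b))
}

# uniform multiallelic frequency table for a set of markers
fix_freqs <- function(markers, n_alleles = 4) {
  q <- rep(1 / n_alleles, n_alleles)
  allele_freq_table(stats::setNames(
    lapply(markers, function(m) stats::setNames(q, as.character(seq_len(n_alleles)))),
    markers))
}

# complete genotype panel filled from a gene drop of the pedigree
fix_panel <- function(ped, freqs, map, seed = 1) {
  chroms <- unique(map$chrom)
  a1 <- NULL; a2 <- NULL
  set.seed(seed)
  for (cc in chroms) {
    d <- drop_linked_chromosome(ped, freqs, map, cc, n_reps = 1)
    rep1 <- drop_replicate(d, 1)
    a1 <- cbind(a1, rep1$paternal)
    a2 <- cbind(a2, rep1$maternal)
  }
  genotype_panel(ped$members$id, map$marker, a1, a2)
}

# default small study configuration used in pipeline tests
fix_cfg <- function(...) {
  sim_config(n_pedigrees = 8, chr_lengths_cM = c(40, 30),
             causal_chrom = 1, causal_pos_cM = 20, ...)
}
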