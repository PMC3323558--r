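test_that("Haldane map function matches its closed form", {
  expect_equal(haldane_theta(0), 0)
  expect_equal(haldane_theta(10), (1 - exp(-0.2)) / 2, tolerance = 1e-12)
  expect_equal(haldane_theta(10), 0.0906346234610091, tolerance = 1e-12)
  expect_lt(abs(haldane_theta(1000) - 0.5), 1e-8)
  expect_error(haldane_theta(-1), "non-negative")
  expect_equal(haldane_theta(c(0, 10)),
               c(0, 0.0906346234610091), tolerance = 1e-12)
})

test_that("map and frequency containers validate their invariants", {
  expect_error(genetic_map(data.frame(chrom = "1",
                                      marker = c("a", "a"),
                                      position_cM = c(1, 2))),
               "duplicate marker")
  expect_error(allele_freq_table(list(m = c(A = 1))), "fewer than 2")
  expect_error(allele_freq_table(list(m = c(A = 0.7, B = 0.2))), "sum to")
  expect_error(allele_freq_table(list(m = c(A = 1.2, B = -0.2))),
               "non-positive")
  ok <- allele_freq_table(data.frame(marker = "m", allele = c("A", "B"),
                                     frequency = c(0.25, 0.75)))
  expect_equal(ok$m, c(A = 0.25, B = 0.75))
})

test_that("founder genotypes under unlinked drops follow Hardy-Weinberg", {
  ped <- validate_pedigree(data.frame(id = "solo", father = NA, mother = NA))
  q <- allele_freq_table(list(mk = c(A = 0.2, B = 0.3, C = 0.5)))
  d <- drop_unlinked(ped, q, "mk", n_reps = 10000, seed = 91)
  g1 <- d$pat[1, 1, ]; g2 <- d$mat[1, 1, ]
  # unordered genotype counts vs HWE expectation
  key <- paste(pmin(g1, g2), pmax(g1, g2))
  p <- c(0.2, 0.3, 0.5)
  expect_geno <- c("1 1" = p[1]^2, "1 2" = 2 * p[1] * p[2],
                   "1 3" = 2 * p[1] * p[3], "2 2" = p[2]^2,
                   "2 3" = 2 * p[2] * p[3], "3 3" = p[3]^2)
  obs <- table(factor(key, levels = names(expect_geno)))
  pval <- stats::chisq.test(as.numeric(obs), p = expect_geno)$p.value
  expect_gt(pval, 0.01)
})

test_that("transmission is Mendelian in every replicate", {
  ped <- fix_threegen()
  q <- fix_freqs("mk", n_alleles = 6)
  d <- drop_unlinked(ped, q, "mk", n_reps = 200, seed = 5)
  fa <- ped$fa; mo <- ped$mo
  for (i in which(fa > 0)) {
    expect_true(all(d$pat[i, 1, ] == d$pat[fa[i], 1, ] |
                    d$pat[i, 1, ] == d$mat[fa[i], 1, ]))
    expect_true(all(d$mat[i, 1, ] == d$pat[mo[i], 1, ] |
                    d$mat[i, 1, ] == d$mat[mo[i], 1, ]))
  }
  # a parent and offspring always share at least one allele by state
  share <- d$pat[3, 1, ] == d$pat[7, 1, ] | d$pat[3, 1, ] == d$mat[7, 1, ] |
           d$mat[3, 1, ] == d$pat[7, 1, ] | d$mat[3, 1, ] == d$mat[7, 1, ]
  expect_true(all(share))
})

test_that("a near-monomorphic marker drops essentially one allele", {
  ped <- fix_trio()
  q <- allele_freq_table(list(mk = c(A = 1 - 1e-9, B = 1e-9)))
  d <- drop_unlinked(ped, q, "mk", n_reps = 50, seed = 3)
  expect_true(all(d$pat == 1L) && all(d$mat == 1L))
})

test_that("linked drops respect the map: cosegregation and recombination", {
  ped <- fix_trio()
  q <- allele_freq_table(list(L1 = c(a = .5, b = .5),
                              L2 = c(x = .5, y = .5)))
  map0 <- genetic_map(data.frame(chrom = "1", marker = c("L1", "L2"),
                                 position_cM = c(0, 0)))
  d0 <- drop_linked_chromosome(ped, q, map0, "1", n_reps = 3000, seed = 17)
  fh1 <- cbind(d0$pat[1, 1, ], d0$pat[1, 2, ])
  fh2 <- cbind(d0$mat[1, 1, ], d0$mat[1, 2, ])
  ch <- cbind(d0$pat[3, 1, ], d0$pat[3, 2, ])
  intact <- (ch[, 1] == fh1[, 1] & ch[, 2] == fh1[, 2]) |
            (ch[, 1] == fh2[, 1] & ch[, 2] == fh2[, 2])
  expect_true(all(intact))  # zero map distance: always co-transmitted

  map10 <- genetic_map(data.frame(chrom = "1", marker = c("L1", "L2"),
                                  position_cM = c(0, 10)))
  n <- 20000
  d1 <- drop_linked_chromosome(ped, q, map10, "1", n_reps = n, seed = 19)
  fh1 <- cbind(d1$pat[1, 1, ], d1$pat[1, 2, ])
  fh2 <- cbind(d1$mat[1, 1, ], d1$mat[1, 2, ])
  het <- fh1[, 1] != fh2[, 1] & fh1[, 2] != fh2[, 2]
  ch <- cbind(d1$pat[3, 1, ], d1$pat[3, 2, ])
  rec <- (ch[het, 1] == fh1[het, 1]) != (ch[het, 2] == fh1[het, 2])
  th <- haldane_theta(10)
  se <- sqrt(th * (1 - th) / sum(het))
  expect_lt(abs(mean(rec) - th), 3 * se)
})

test_that("linked and unlinked drops share the same per-marker marginals", {
  ped <- fix_trio()
  q <- allele_freq_table(list(L1 = c(a = .3, b = .7),
                              L2 = c(x = .6, y = .4)))
  map <- genetic_map(data.frame(chrom = "1", marker = c("L1", "L2"),
                                position_cM = c(0, 5)))
  dl <- drop_linked_chromosome(ped, q, map, "1", n_reps = 8000, seed = 7)
  du <- drop_unlinked(ped, q, "L2", n_reps = 8000, seed = 8)
  # child allele frequency at L2 under each scheme
  fl <- mean(c(dl$pat[3, 2, ], dl$mat[3, 2, ]) == 1L)
  fu <- mean(c(du$pat[3, 1, ], du$mat[3, 1, ]) == 1L)
  se <- sqrt(0.6 * 0.4 / 16000)
  expect_lt(abs(fl - 0.6), 3 * se)
  expect_lt(abs(fu - 0.6), 3 * se)
})

test_that("allele frequencies are conserved through transmission", {
  cfg <- sim_config(n_pedigrees = 1, n_founder_couples = 2,
                    n_generations = 4)
  ped <- simulate_pedigree(cfg, seed = 23)
  q <- allele_freq_table(list(mk = c(A = 0.2, B = 0.8)))
  d <- drop_unlinked(ped, q, "mk", n_reps = 500, seed = 29)
  fA <- mean(c(d$pat, d$mat) == 1L)
  # members are correlated, so allow generous Monte Carlo slack
  expect_lt(abs(fA - 0.2), 0.03)
})

test_that("identical seeds reproduce identical replicates", {
  ped <- fix_threegen()
  q <- fix_freqs(c("a", "b"), 5)
  map <- genetic_map(data.frame(chrom = "1", marker = c("a", "b"),
                                position_cM = c(0, 8)))
  d1 <- drop_linked_chromosome(ped, q, map, "1", n_reps = 20, seed = 99)
  d2 <- drop_linked_chromosome(ped, q, map, "1", n_reps = 20, seed = 99)
  expect_identical(d1$pat, d2$pat)
  expect_identical(d1$mat, d2$mat)
  d3 <- drop_linked_chromosome(ped, q, map, "1", n_reps = 20, seed = 100)
  expect_false(identical(d1$pat, d3$pat))
})

test_that("gene-drop IBD estimates recover 2*phi for all pair classes", {
  ped <- fix_pair_classes()
  cases <- list(c("P", "C1"),    # parent-offspring: exactly one shared
                c("C1", "C2"),   # full sibs
                c("U", "C1"),    # avuncular
                c("C1", "D1"),   # first cousins
                c("K1", "K2"))   # double first cousins
  for (k in seq_along(cases)) {
    pair <- cases[[k]]
    est <- estimate_ibd(ped, pair[1], pair[2], n_reps = 4000,
                        seed = 200 + k)
    target <- 2 * kinship_coefficient(ped, pair[1], pair[2])
    expect_lt(abs(est$ibd - target), max(3 * est$se, 1e-12))
  }
  # parent-offspring is deterministic: exactly half the alleles shared
  po <- estimate_ibd(ped, "P", "C1", n_reps = 50, seed = 1)
  expect_equal(po$ibd, 0.5)
  expect_equal(po$se, 0)
  # unrelated founders never share
  un <- estimate_ibd(ped, "G1", "X1", n_reps = 200, seed = 2)
  expect_equal(un$ibd, 0)
})

test_that("drop_replicate round-trips allele labels", {
  ped <- fix_trio()
  q <- allele_freq_table(list(mk = c(A = 0.5, B = 0.5)))
  d <- drop_unlinked(ped, q, "mk", n_reps = 3, seed = 4)
  r <- drop_replicate(d, 2)
  expect_equal(dim(r$paternal), c(3L, 1L))
  expect_true(all(r$paternal %in% c("A", "B")))
  expect_equal(r$paternal[, 1], setNames(c("A", "B")[d$pat[, 1, 2]],
                                         ped$members$id))
})
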