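test_that("the sharing statistic evaluates its four-term Kronecker sum", {
  q <- c(A = 0.25, B = 0.5, C = 0.25)
  expect_equal(sharing_statistic(c("A", "A"), c("B", "C"), q), 0)
  # (A,A) vs (A,A): four matching terms, each weighted 1/sqrt(0.25) = 2
  expect_equal(sharing_statistic(c("A", "A"), c("A", "A"), q), 2)
  # (A,A) vs (A,B): two matching terms
  expect_equal(sharing_statistic(c("A", "A"), c("A", "B"), q), 1)
  expect_equal(sharing_statistic(c("A", "B"), c("A", "B"), q,
                                 weight = "constant"), 0.5)
  expect_equal(sharing_statistic(c("A", "A"), c("A", "A"), q,
                                 weight = "inverse"), 4)
  expect_error(sharing_statistic(c("A", "Z"), c("A", "A"), q), "absent")
})

test_that("constant-weight sharing lies in [0, 1]", {
  set.seed(31)
  q <- c(a = .1, b = .2, c = .3, d = .4)
  for (k in 1:50) {
    gi <- sample(names(q), 2, replace = TRUE)
    gj <- sample(names(q), 2, replace = TRUE)
    s <- sharing_statistic(gi, gj, q, weight = "constant")
    expect_gte(s, 0)
    expect_lte(s, 1)
  }
})

test_that("observed APM sums match a naive per-pair recomputation", {
  cfg <- fix_cfg()
  st <- simulate_study(cfg, seed = 61)
  el <- excess_longevity(st$phen, st$expected)
  fel <- familial_excess_longevity(st$ped, el)
  rec <- data.frame(id = st$phen$id, EL = unname(el),
                    FEL = unname(fel[st$phen$id]))
  aff <- select_affected(rec, selection_rule("el_fel_quartile"))
  pairs <- enumerate_affected_pairs(st$ped, aff)
  expect_gt(nrow(pairs), 3)
  mk <- st$map$marker[5]
  got <- apm_observed(pairs, st$panel, mk, st$freqs)
  # independent oracle: explicit double loop over pairs
  q <- st$freqs[[mk]]
  naive <- 0; n_used <- 0L
  col <- match(mk, st$panel$markers)
  for (r in seq_len(nrow(pairs))) {
    ia <- match(pairs$id_a[r], st$panel$ids)
    ib <- match(pairs$id_b[r], st$panel$ids)
    gi <- c(st$panel$a1[ia, col], st$panel$a2[ia, col])
    gj <- c(st$panel$a1[ib, col], st$panel$a2[ib, col])
    if (anyNA(gi) || anyNA(gj)) next
    naive <- naive + sharing_statistic(gi, gj, q)
    n_used <- n_used + 1L
  }
  expect_equal(got$score, naive, tolerance = 1e-10)
  expect_equal(got$n_pairs, n_used)
})

test_that("pairs with a missing genotype are excluded from the sum", {
  ped <- fix_threegen()
  q <- fix_freqs("mk", 4)
  a1 <- matrix("1", ped$n, 1, dimnames = list(ped$members$id, "mk"))
  a2 <- a1
  a1["C2", 1] <- NA  # C2 untyped
  panel <- genotype_panel(ped$members$id, "mk", a1, a2)
  pairs <- enumerate_affected_pairs(ped, c("P", "C1", "C2"))
  got <- apm_observed(pairs, panel, "mk", q)
  expect_equal(got$n_pairs, 1L)  # only (P, C1) remains
  expect_equal(got$score, sharing_statistic(c("1", "1"), c("1", "1"),
                                            q$mk))
  a1[, 1] <- NA
  panel_none <- genotype_panel(ped$members$id, "mk", a1, a2)
  expect_error(apm_observed(pairs, panel_none, "mk", q), "no informative")
})

test_that("null mean matches exhaustive enumeration for a trio", {
  # parent-offspring pair at a biallelic marker, constant weight:
  # enumerate founder genotype assignments and transmissions exactly
  ped <- fix_trio()
  p <- 0.3
  q <- allele_freq_table(list(mk = c(A = p, B = 1 - p)))
  exp_s <- 0
  probs <- c(A = p, B = 1 - p)
  for (g1 in c("A", "B")) for (g2 in c("A", "B"))
    for (g3 in c("A", "B")) for (g4 in c("A", "B"))
      for (tp in 1:2) for (tm in 1:2) {
        pr <- probs[g1] * probs[g2] * probs[g3] * probs[g4] * 0.25
        child <- c(c(g1, g2)[tp], c(g3, g4)[tm])
        exp_s <- exp_s + pr *
          sharing_statistic(c(g1, g2), child, q$mk, weight = "constant")
      }
  panel <- genotype_panel(ped$members$id, "mk",
                          matrix("A", 3, 1), matrix("B", 3, 1))
  pairs <- data.frame(id_a = "f", id_b = "c")
  null <- null_distribution(ped, pairs, panel, q, "mk", n_reps = 4000,
                            mode = "unlinked", weight = "constant",
                            seed = 77)
  se <- stats::sd(null) / sqrt(length(null))
  expect_lt(abs(mean(null) - exp_s), 3 * se)
})

test_that("degenerate nulls raise an error state instead of a Z", {
  ped <- fix_trio()
  q <- allele_freq_table(list(mk = c(A = 1 - 1e-9, B = 1e-9)))
  panel <- genotype_panel(ped$members$id, "mk",
                          matrix("A", 3, 1), matrix("A", 3, 1))
  pairs <- data.frame(id_a = "f", id_b = "c")
  expect_error(
    null_distribution(ped, pairs, panel, q, "mk", n_reps = 100, seed = 5),
    class = "apmlink_degenerate_null")
  expect_error(z_and_pvalues(1, c(2, 2, 2)),
               class = "apmlink_degenerate_null")
})

test_that("null sequences are reproducible under a seed", {
  ped <- fix_threegen()
  q <- fix_freqs("mk", 5)
  panel <- fix_panel(ped, q,
                     genetic_map(data.frame(chrom = "1", marker = "mk",
                                            position_cM = 0)))
  pairs <- enumerate_affected_pairs(ped, c("P", "C1", "C2", "D1"))
  n1 <- null_distribution(ped, pairs, panel, q, "mk", n_reps = 50,
                          seed = 13)
  n2 <- null_distribution(ped, pairs, panel, q, "mk", n_reps = 50,
                          seed = 13)
  expect_identical(n1, n2)
})

test_that("z_and_pvalues implements the standardization conventions", {
  r <- z_and_pvalues(10, c(2, 4, 6))
  expect_equal(r$z, 3)  # (10 - 4) / 2
  expect_equal(r$p_asymptotic, stats::pnorm(3, lower.tail = FALSE))
  expect_equal(r$p_empirical, 0)  # observed exceeds every null value
  r0 <- z_and_pvalues(4, c(2, 4, 6))
  expect_equal(r0$z, 0)
  expect_equal(r0$p_asymptotic, 0.5)
  expect_equal(r0$p_empirical, 2 / 3)  # ties count as exceeding
  ra <- z_and_pvalues(10, c(2, 4, 6), empirical = "add_one")
  expect_equal(ra$p_empirical, 1 / 4)
})

test_that("grid weights follow the inverse-recombination rule", {
  expect_equal(grid_weights(0, 3), c(1, 0))
  expect_equal(grid_weights(3, 0), c(0, 1))
  expect_equal(grid_weights(2, 2), c(0.5, 0.5))
  # hand computation for the asymmetric 1 cM / 4 cM case
  th1 <- (1 - exp(-2 * 1 / 100)) / 2
  th4 <- (1 - exp(-2 * 4 / 100)) / 2
  wl <- (1 / th1) / (1 / th1 + 1 / th4)
  got <- grid_weights(1, 4)
  expect_lt(abs(got[1] - wl), 1e-9)
  expect_equal(sum(got), 1)
  expect_equal(round(got[1], 3), 0.795)
})

test_that("a size-1 window reduces to the singlepoint statistic", {
  ped <- fix_threegen()
  map <- genetic_map(data.frame(chrom = "1", marker = c("a", "b", "c"),
                                position_cM = c(0, 5, 12)))
  q <- fix_freqs(c("a", "b", "c"), 6)
  panel <- fix_panel(ped, q, map, seed = 3)
  pairs <- enumerate_affected_pairs(ped, c("P", "U", "C1", "C2", "D1"))
  one <- multipoint_window(ped, pairs, panel, q, map, "1", window = "b",
                           n_reps = 80, seed = 21)
  sp_obs <- apm_observed(pairs, panel, "b", q)
  expect_equal(one$observed, sp_obs$score)
  nb <- null_distribution(ped, pairs, panel, q, "b", map = map,
                          n_reps = 80, mode = "linked", seed = 21)
  expect_equal(one$null_mean, mean(nb))
  expect_equal(one$z, (sp_obs$score - mean(nb)) / stats::sd(nb))
})

test_that("two perfectly linked identical markers double the score, not Z", {
  ped <- fix_threegen()
  map <- genetic_map(data.frame(chrom = "1", marker = c("m1", "m2"),
                                position_cM = c(5, 5)))
  q <- fix_freqs(c("m1", "m2"), 4)
  set.seed(8)
  d <- drop_linked_chromosome(ped, q, map, "1", n_reps = 1)
  r <- drop_replicate(d, 1)
  # identical genotypes at both markers (theta = 0 co-transmission from
  # identical founder assignments is not guaranteed, so copy explicitly)
  a1 <- cbind(r$paternal[, 1], r$paternal[, 1])
  a2 <- cbind(r$maternal[, 1], r$maternal[, 1])
  panel <- genotype_panel(ped$members$id, c("m1", "m2"), a1, a2)
  pairs <- enumerate_affected_pairs(ped, c("P", "U", "C1", "C2", "D1"))
  both <- multipoint_window(ped, pairs, panel, q, map, "1",
                            window = c("m1", "m2"), n_reps = 400,
                            seed = 33)
  one <- multipoint_window(ped, pairs, panel, q, map, "1", window = "m1",
                           n_reps = 400, seed = 33)
  expect_equal(both$observed, 2 * one$observed)
  # under linkage-equilibrium founders the two markers' null scores are
  # exchangeable (identical IBD pattern, independent founder labels), so
  # the doubling of the null moments and the invariance of Z hold in
  # expectation, not replicate-by-replicate
  expect_equal(both$null_mean, 2 * one$null_mean, tolerance = 0.05)
  expect_equal(both$z, one$z, tolerance = 0.5)
})

test_that("a three-marker window equals its brute-force sum", {
  ped <- fix_threegen()
  map <- genetic_map(data.frame(chrom = "1", marker = c("a", "b", "c"),
                                position_cM = c(0, 4, 9)))
  q <- fix_freqs(c("a", "b", "c"), 5)
  panel <- fix_panel(ped, q, map, seed = 10)
  pairs <- enumerate_affected_pairs(ped, c("P", "U", "C1", "C2", "D1"))
  w <- multipoint_window(ped, pairs, panel, q, map, "1",
                         window = c("a", "b", "c"), n_reps = 60, seed = 2)
  brute <- sum(vapply(c("a", "b", "c"), function(mk)
    apm_observed(pairs, panel, mk, q)$score, numeric(1)))
  expect_equal(w$observed, brute, tolerance = 1e-10)
  expect_error(multipoint_window(ped, pairs, panel, q, map, "1",
                                 window = c("a", "c")), "adjacent")
})

test_that("grid scores interpolate between markers and hit markers exactly", {
  ped <- fix_threegen()
  map <- genetic_map(data.frame(chrom = "1", marker = c("a", "b"),
                                position_cM = c(0, 4)))
  q <- fix_freqs(c("a", "b"), 5)
  panel <- fix_panel(ped, q, map, seed = 11)
  pairs <- enumerate_affected_pairs(ped, c("P", "U", "C1", "C2", "D1"))
  g <- grid_multipoint(ped, pairs, panel, q, map, "1", step = 1,
                       n_reps = 60, seed = 41)
  expect_equal(g$position_cM, 0:4)
  sa <- apm_observed(pairs, panel, "a", q)$score
  sb <- apm_observed(pairs, panel, "b", q)$score
  expect_equal(g$observed[1], sa)
  expect_equal(g$observed[5], sb)
  w <- grid_weights(2, 2)
  expect_equal(g$observed[3], w[1] * sa + w[2] * sb, tolerance = 1e-10)
})

test_that("experiment-wise adjustment has its boundary and order properties", {
  set.seed(55)
  z_null <- matrix(rnorm(40 * 100), 40, 100)
  maxima <- apply(z_null, 2, max)
  expect_equal(genomewide_adjust(max(maxima) + 1, z_null), 0)
  expect_equal(genomewide_adjust(min(maxima) - 1, z_null), 1)
  z_obs <- seq(-3, 5, length.out = 9)
  adj <- genomewide_adjust(z_obs, z_null)
  expect_true(all(diff(adj) <= 0))  # monotone non-increasing in Z
  expect_true(is.na(genomewide_adjust(NA, z_null)))
  expect_warning(genomewide_adjust(0, z_null[, 1:10]), "unstable")
})

test_that("single-locus adjustment reduces to the empirical p", {
  set.seed(66)
  null <- rnorm(500)
  obs <- 1.3
  zz <- z_and_pvalues(obs, null)
  z_null <- matrix((null - mean(null)) / sd(null), 1)
  adj <- genomewide_adjust(zz$z, z_null)
  expect_equal(adj, zz$p_empirical)
})

test_that("adjusted p dominates empirical p on a full scan ensemble", {
  cfg <- fix_cfg()
  st <- simulate_study(cfg, seed = 71)
  ins <- list(ped = st$ped, panel = st$panel, map = st$map,
              freqs = st$freqs, phen = st$phen, expected = st$expected,
              config = scan_config(n_reps = 60, seed = 5,
                                   selection = selection_rule(
                                     "el_fel_quartile")))
  sc <- run_scan(ins)
  for (df in list(sc$singlepoint, sc$multipoint, sc$grid)) {
    ok <- !is.na(df$z)
    expect_true(all(df$p_adjusted[ok] >= df$p_empirical[ok] - 1e-12))
  }
})

test_that("meta-analysis combines Z curves by the weighted-mean rule", {
  a <- data.frame(position_cM = c(0, 10), z = c(2, 2))
  b <- data.frame(position_cM = c(0, 10), z = c(2, 2))
  m <- meta_combine(list(a, b))
  expect_equal(m$z_meta, rep(sqrt(2) * 2, nrow(m)), tolerance = 1e-12)
  m34 <- meta_combine(list(data.frame(position_cM = 0:1, z = c(3, 3)),
                           data.frame(position_cM = 0:1, z = c(4, 4))))
  expect_equal(m34$z_meta[1], 7 / sqrt(2), tolerance = 1e-12)
  expect_equal(m34$z_meta[1], 4.94974746830583, tolerance = 1e-9)
  # a vanishing weight recovers the other study's curve
  mw <- meta_combine(list(data.frame(position_cM = 0:1, z = c(3, 3)),
                          data.frame(position_cM = 0:1, z = c(-2, -2))),
                     weights = c(1, 1e-12))
  expect_equal(mw$z_meta[1], 3, tolerance = 1e-6)
  # curves are interpolated linearly onto the shared grid
  mi <- meta_combine(list(data.frame(position_cM = c(0, 4), z = c(0, 4)),
                          data.frame(position_cM = c(0, 4), z = c(4, 0))),
                     step = 2)
  expect_equal(mi$z_meta[2], (2 + 2) / sqrt(2))
  expect_error(meta_combine(list(data.frame(position_cM = 0:1, z = 1:2),
                                 data.frame(position_cM = 5:6, z = 1:2))),
               "overlap")
})
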