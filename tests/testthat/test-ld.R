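test_that("pair_ld reproduces closed-form D, D' and r2", {
  ## identical columns: perfect LD
  g <- two_locus_genotypes(60, 0, 0, 60)
  p <- pair_ld(g, 1, 2)
  expect_equal(p$Dprime, 1)
  expect_equal(p$r2, 1)
  expect_equal(p$classification, "strong_LD")

  ## hand calculation: freqs (0.4, 0.1, 0.1, 0.4)
  g <- two_locus_genotypes(40, 10, 10, 40)
  p <- pair_ld(g, 1, 2)
  expect_equal(p$D, 0.15)
  expect_equal(p$Dprime, 0.6)
  expect_equal(p$r2, 0.36)
  expect_equal(p$n_informative, 100L)

  ## independence: product of margins
  g <- two_locus_genotypes(25, 25, 25, 25)
  p <- pair_ld(g, 1, 2)
  expect_equal(p$D, 0)
  expect_false(identical(p$classification, "strong_LD"))
})

test_that("pair_ld excludes het/missing lines, is symmetric, flags degeneracy", {
  g <- two_locus_genotypes(30, 10, 10, 30)
  g$calls[1, 1] <- 1L            # het at locus 1
  g$calls[2, 2] <- NA_integer_   # missing at locus 2
  p12 <- pair_ld(g, 1, 2)
  expect_equal(p12$n_informative, 78L)
  p21 <- pair_ld(g, 2, 1)
  expect_equal(p21$Dprime, p12$Dprime)
  expect_equal(p21$r2, p12$r2)
  expect_equal(p21$ci_low, p12$ci_low)

  tiny <- genotype_matrix(cbind(c(0L, 2L, NA), c(0L, NA, 2L)),
                          map = data.frame(marker = c("a", "b"), chrom = "1",
                                           pos = c(1, 2)))
  expect_error(pair_ld(tiny, 1, 2), "insufficient data")

  mono <- genotype_matrix(cbind(rep(0L, 10), rep(c(0L, 2L), 5)),
                          map = data.frame(marker = c("a", "b"), chrom = "1",
                                           pos = c(1, 2)))
  p <- pair_ld(mono, 1, 2)
  expect_true(p$monomorphic)
  expect_true(is.na(p$classification))
})

test_that("dprime_ci concentrates correctly and matches a dense-grid oracle", {
  ## perfect LD at large n: likelihood mass at D' = 1
  ci <- dprime_ci(c(500, 0, 0, 500))
  expect_gte(ci[[1]], 0.6)
  expect_gte(ci[[2]], 0.95)
  expect_equal(classify_pair(ci[[1]], ci[[2]]), "strong_LD")

  ## independence at large n: mass near 0
  ci <- dprime_ci(c(250, 250, 250, 250))
  expect_lt(ci[[2]], 0.9)
  expect_equal(classify_pair(ci[[1]], ci[[2]]), "strong_recombination")

  expect_error(dprime_ci(c(10, 10, 0, 0)), "degenerate")
  expect_error(dprime_ci(c(1, 1, 1, 0)), "insufficient")

  ## grid refinement: step 0.001 within +/- 0.002 of a step 1e-4 oracle
  set.seed(41)
  for (k in 1:60) {
    n <- as.vector(stats::rmultinom(1, sample(20:400, 1),
                                    prob = stats::runif(4, 0.05, 1)))
    if (min(n[1] + n[2], n[3] + n[4], n[1] + n[3], n[2] + n[4]) == 0) next
    ci <- dprime_ci(n, grid_step = 0.001)
    or <- dense_ci_oracle(n, step = 1e-4)
    expect_lte(abs(ci[[1]] - or[1]), 0.002)
    expect_lte(abs(ci[[2]] - or[2]), 0.002)
  }
})

test_that("CI width shrinks as counts scale up at fixed frequencies", {
  base <- c(12, 5, 4, 9)
  ci1 <- dprime_ci(base)
  ci10 <- dprime_ci(base * 10)
  ci100 <- dprime_ci(base * 100)
  w <- c(ci1[2] - ci1[1], ci10[2] - ci10[1], ci100[2] - ci100[1])
  expect_true(all(diff(w) <= 0.002))   # within grid resolution
})

test_that("classify_pair applies the CI bounds and partitions completely", {
  expect_equal(classify_pair(0.60, 0.95), "strong_LD")
  expect_equal(classify_pair(0.20, 0.89), "strong_recombination")
  expect_equal(classify_pair(0.50, 0.97), "inconclusive")
  expect_equal(classify_pair(0.61, 0.94), "inconclusive")

  set.seed(7)
  for (k in 1:200) {
    ci <- sort(stats::runif(2))
    lab <- classify_pair(ci[1], ci[2])
    expect_true(lab %in% c("strong_LD", "strong_recombination", "inconclusive"))
    ## exactly one rule fires
    hits <- c(ci[1] >= 0.6 && ci[2] >= 0.95,
              !(ci[1] >= 0.6 && ci[2] >= 0.95) && ci[2] < 0.90,
              !(ci[1] >= 0.6 && ci[2] >= 0.95) && ci[2] >= 0.90)
    expect_equal(sum(hits), 1L)
  }
})

test_that("LOESS decay curve crosses an analytic exponential at -ln(0.1) Mb", {
  set.seed(5)
  d <- stats::runif(4000, 1e4, 10e6)
  r2 <- pmin(pmax(exp(-d / 1e6) + stats::rnorm(4000, 0, 0.03), 0), 1)
  dec <- fit_ld_decay(d, r2, baseline = 0.1)
  expect_false(is.na(dec$decay_distance_bp))
  expect_lt(abs(dec$decay_distance_bp - 2.302585e6) / 2.302585e6, 0.15)
  expect_true(all(dec$curve$r2 >= 0 & dec$curve$r2 <= 1))

  ## flat curve at r2 = 1 never crosses
  dec2 <- fit_ld_decay(d, rep(1, length(d)), baseline = 0.1)
  expect_true(is.na(dec2$decay_distance_bp))
})

test_that("ld_decay runs on a genotype matrix with block LD", {
  set.seed(9)
  spec <- simulation_spec(n_lines = 150, n_founders = 15,
                          chromosomes = data.frame(chrom = "1A",
                                                   length_bp = 5e7,
                                                   n_markers = 120),
                          generations = 6, missing_rate = 0.05, seed = 3)
  g <- simulate_genotypes(spec)$genotypes
  dec <- ld_decay(g, max_dist_bp = 4e7, seed = 1)
  expect_s3_class(dec, "ld_decay")
  expect_gte(dec$n_pairs, 100)
})
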