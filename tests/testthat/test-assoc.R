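test_that("VanRaden kinship matches hand algebra and conventions", {
  ## two identical fully homozygous lines: their cross-term equals both
  ## diagonals (identity of state)
  g <- genotype_matrix(rbind(c(0L, 2L, 0L, 2L), c(0L, 2L, 0L, 2L),
                             c(2L, 0L, 2L, 0L)),
                       map = data.frame(marker = paste0("m", 1:4),
                                        chrom = "1A", pos = 1:4 * 100))
  K <- vanraden_kinship(g)
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])

  ## 3-line, 4-marker toy vs Z Z' / (2 sum p q) computed by hand
  calls <- rbind(c(0L, 2L, 1L, 0L),
                 c(2L, 0L, 0L, 2L),
                 c(0L, 2L, 2L, 0L))
  g2 <- genotype_matrix(calls, map = data.frame(marker = paste0("m", 1:4),
                                                chrom = "1A", pos = 1:4 * 100))
  p <- colMeans(calls) / 2
  Z <- sweep(calls, 2, 2 * p)
  K_hand <- Z %*% t(Z) / (2 * sum(p * (1 - p)))
  expect_equal(unname(vanraden_kinship(g2)), unname(K_hand), tolerance = 1e-12)

  ## invariant to marker order
  g3 <- subset_genotypes(g2, markers = c(3, 1, 4, 2))
  expect_equal(vanraden_kinship(g3), vanraden_kinship(g2), tolerance = 1e-12)

  ## fully inbred random panel: mean diagonal near 1 + F = 2
  set.seed(51)
  p <- stats::runif(800, 0.1, 0.5)
  doses <- sapply(p, function(pk) 2L * stats::rbinom(150, 1, pk))
  g4 <- genotype_matrix(doses, map = data.frame(marker = paste0("m", 1:800),
                                                chrom = "1A", pos = 1:800))
  K4 <- vanraden_kinship(g4)
  expect_lt(abs(mean(diag(K4)) - 2), 0.15)

  expect_error(vanraden_kinship(genotype_matrix(matrix(0L, 5, 3),
    map = data.frame(marker = c("a", "b", "c"), chrom = "1", pos = 1:3))),
    "monomorphic")
})

test_that("BIC PC selection reacts to planted structure and not to noise", {
  set.seed(52)
  n <- 300
  pcs <- matrix(stats::rnorm(n * 10), n, 10)
  pcs <- sweep(pcs, 2, sqrt(colSums(pcs^2)), "/") * 20

  null_zero <- replicate(100, {
    select_pcs_bic(pcs, stats::rnorm(n)) == 0
  })
  expect_gte(mean(null_zero), 0.80)

  structured <- replicate(50, {
    select_pcs_bic(pcs, pcs[, 1] + stats::rnorm(n, 0, 0.2)) >= 1
  })
  expect_gte(mean(structured), 0.95)
})

test_that("GLS F-test reduces exactly to OLS when sigma2_g = 0", {
  set.seed(53)
  n <- 120
  hap <- sample(1:3, n, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  y <- stats::rnorm(n) + 0.5 * (hap == 2)
  K <- diag(n) * 0 + tcrossprod(matrix(stats::rnorm(n * 5), n, 5)) / 5

  ## OLS oracle
  p_ols <- stats::anova(stats::lm(y ~ factor(hap)))[["Pr(>F)"]][1]

  r_null <- mlm_assoc(hap, y, null_fit = NULL)
  expect_equal(r_null$p_value, p_ols, tolerance = 1e-10)

  fake_null <- structure(list(delta = Inf, sigma2_g = 0, sigma2_e = 1,
                              V = diag(n), cholV = diag(n), n = n),
                         class = "mlm_null")
  r_zero <- mlm_assoc(hap, y, null_fit = fake_null)
  expect_equal(r_zero$p_value, p_ols, tolerance = 1e-10)
})

test_that("mlm_assoc handles degenerate inputs and invariances", {
  set.seed(54)
  n <- 150
  hap <- sample(1:2, n, replace = TRUE)
  K <- diag(n)

  ## constant phenotype: zero F, p = 1
  r <- mlm_assoc(hap, rep(5, n))
  expect_equal(r$p_value, 1)
  expect_equal(r$F, 0)

  ## fewer than two allele classes after the size floor: NA p
  r2 <- mlm_assoc(c(rep(1L, n - 3), rep(2L, 3)), stats::rnorm(n))
  expect_true(is.na(r2$p_value))

  ## relabeling alleles and shifting y leave the p-value unchanged
  y <- stats::rnorm(n) + (hap == 2)
  nf <- mlm_null_reml(y, matrix(1, n, 1), K)
  pa <- mlm_assoc(hap, y, null_fit = nf)$p_value
  pb <- mlm_assoc(c(9L, 4L)[hap], y, null_fit = nf)$p_value
  expect_equal(pa, pb, tolerance = 1e-12)
  nf2 <- mlm_null_reml(y + 1000, matrix(1, n, 1), K)
  pc <- mlm_assoc(hap, y + 1000, null_fit = nf2)$p_value
  expect_equal(pa, pc, tolerance = 1e-6)
})

test_that("REML null fit recovers planted variance components", {
  set.seed(55)
  n <- 300
  ## structured kinship from two subpopulations
  sub <- rep(1:2, each = n / 2)
  M <- sapply(stats::runif(600, 0.1, 0.5), function(pk) {
    p_shift <- pmin(pmax(pk + c(-0.12, 0.12)[sub], 0.02), 0.98)
    2 * stats::rbinom(n, 1, p_shift)
  })
  g <- genotype_matrix(M, map = data.frame(marker = paste0("m", 1:600),
                                           chrom = "1A", pos = 1:600))
  K <- vanraden_kinship(g)
  u <- drop(crossprod(chol(K + diag(1e-6, n)), stats::rnorm(n)))
  y <- 2 * u + stats::rnorm(n, 0, sqrt(2))   # sigma2_g = 4, sigma2_e = 2
  nf <- mlm_null_reml(y, matrix(1, n, 1), K)
  expect_gt(nf$sigma2_g, 0)
  expect_lt(abs(nf$delta - 0.5) / 0.5, 1)    # delta = 2/4, loose bound
})

test_that("allelic effects are with/without mean differences", {
  ## equal means
  eff <- allelic_effect(rep(c("A", "B"), each = 10), rep(c(1, 1), each = 10))
  expect_equal(eff$effect, 0)

  ## toy arithmetic: 5200 vs 5000
  hap <- c(rep("A", 30), rep("B", 50), rep("C", 20))
  y <- c(rep(5200, 30), rep(5000, 50), rep(5000, 20))
  eff2 <- allelic_effect(hap, y)
  expect_equal(eff2$favorable[1], "A")
  expect_equal(eff2$effect, 200)

  ## a clear second favorable allele is reported after the primary
  set.seed(56)
  hap3 <- c(rep("A", 80), rep("B", 80), rep("C", 140))
  y3 <- c(stats::rnorm(80, 300, 10), stats::rnorm(80, 290, 10),
          stats::rnorm(140, 0, 10))
  eff3 <- allelic_effect(hap3, y3)
  expect_equal(eff3$favorable[1], "A")
  expect_true("B" %in% eff3$favorable)

  ## recovery of a planted +300 kg/ha allele at frequency 0.3
  set.seed(57)
  est <- replicate(25, {
    hap <- stats::rbinom(1000, 1, 0.3)
    y <- 5000 + 300 * hap + stats::rnorm(1000, 0, 650)
    allelic_effect(hap, y)$effect
  })
  expect_lt(abs(mean(est) - 300) / 300, 0.15)
})

test_that("assoc_scan aligns named phenotypes and reports per block", {
  set.seed(58)
  spec <- simulation_spec(n_lines = 150, n_founders = 10,
                          chromosomes = data.frame(chrom = "1A",
                                                   length_bp = 2e7,
                                                   n_markers = 60),
                          generations = 4, missing_rate = 0.05,
                          cohorts = 1, seed = 6)
  sim <- simulate_genotypes(spec)
  gf <- filter_markers(sim$genotypes)$genotypes
  blocks <- find_blocks(gf)
  expect_gt(length(blocks), 0)
  hg <- build_haplotype_genotypes(gf, blocks)
  K <- vanraden_kinship(gf)
  y <- stats::setNames(stats::rnorm(150, 5000, 300), rownames(gf$calls))
  res <- assoc_scan(hg, sample(y), K = K, trial = "T1", env = "I")
  expect_equal(nrow(res), length(blocks))
  expect_true(all(res$p_value > 0 & res$p_value <= 1, na.rm = TRUE))
  expect_equal(res$trial[1], "T1")
})
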