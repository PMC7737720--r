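small_spec <- function(seed, ...) {
  args <- list(n_lines = 150L, n_founders = 12L,
               chromosomes = data.frame(chrom = c("1A", "2B"),
                                        length_bp = 4e7,
                                        n_markers = c(70L, 70L)),
               generations = 5L, selfing = 6L, missing_rate = 0.1,
               cohorts = 2L, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simulation_spec, args)
}

test_that("the generator is deterministic under a fixed seed", {
  s1 <- simulate_genotypes(small_spec(101))
  s2 <- simulate_genotypes(small_spec(101))
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$true_calls, s2$true_calls)
  p1 <- simulate_phenotypes(s1, small_spec(101))
  p2 <- simulate_phenotypes(s2, small_spec(101))
  expect_identical(p1$pheno, p2$pheno)

  s3 <- simulate_genotypes(small_spec(102))
  expect_false(identical(s1$genotypes$calls, s3$genotypes$calls))

  expect_error(simulation_spec(), "seed is mandatory")
})

test_that("zero recombination from two founders gives complete LD", {
  spec <- small_spec(103, rec_rate = 0, n_founders = 2L, missing_rate = 0,
                     het_rate = 0)
  g <- simulate_genotypes(spec)$genotypes
  poly <- which(marker_maf(g) > 0.05)
  set.seed(1)
  for (k in 1:25) {
    ij <- sample(poly, 2)
    same_chrom <- g$map$chrom[ij[1]] == g$map$chrom[ij[2]]
    if (!same_chrom) next
    p <- pair_ld(g, ij[1], ij[2])
    expect_equal(p$Dprime, 1)
  }
})

test_that("selfing drives heterozygosity to the expected residual", {
  spec <- small_spec(104, selfing = 6L, het_rate = 0, missing_rate = 0)
  sim <- simulate_genotypes(spec)
  het <- mean(sim$true_calls == 1L)
  expect_lte(het, 0.02 + 0.005)        # (1/2)^6 ~ 1.6%

  spec2 <- small_spec(105, selfing = 2L, het_rate = 0, missing_rate = 0)
  het2 <- mean(simulate_genotypes(spec2)$true_calls == 1L)
  expect_gt(het2, het)                 # fewer selfing rounds, more hets
})

test_that("LD decays with physical distance in the default architecture", {
  spec <- simulation_spec(seed = 106)   # the default study conditions
  g <- simulate_genotypes(spec)$genotypes
  ## bins span the range where founder LD exceeds the flat drift floor
  sc <- ld_pair_scatter(g, max_dist_bp = 2.5e7, sample_pairs = 20000L, seed = 2)
  bins <- cut(sc$distance_bp, breaks = 20)
  bin_mean <- tapply(sc$r2, bins, mean)
  bin_mid <- tapply(sc$distance_bp, bins, mean)
  ok <- !is.na(bin_mean)
  rho <- stats::cor(bin_mid[ok], bin_mean[ok], method = "spearman")
  expect_lt(rho, -0.9)
})

test_that("markers common among founders usually stay common in the sample", {
  spec <- small_spec(107, n_lines = 400L)
  sim <- simulate_genotypes(spec)
  common <- sim$founder_maf >= 0.2
  retained <- marker_maf(sim$genotypes)[common] >= 0.15
  expect_gte(mean(retained), 0.90)
})

test_that("phenotypes hit the heritability target and recover planted effects", {
  ## entry-mean H2 band of +/- 0.05 calibrates at ~1,000 entries
  mk <- function(seed) small_spec(seed, n_lines = 1000L, cohorts = 1L,
                                  environments = "I", env_means = c(I = 5000),
                                  gxe_scale = c(I = 1),
                                  dh_coupling = c(I = 0.3),
                                  block_sd = 0, rep_sd = 0, h2 = 0.5,
                                  polygenic_sd = 300)
  sim <- simulate_genotypes(mk(108))
  hits <- vapply(1:10, function(k) {
    ph <- simulate_phenotypes(sim, mk(108 + 1000 * k))
    d <- ph$pheno[!ph$pheno$is_check, ]   # checks replicate across experiments
    df <- data.frame(entry = d$entry, env = d$env, value = d$GY)
    abs(anova_gxe(df)$H2 - 0.5) <= 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)

  ## target 0: pure noise, genotype P uniform
  mk0 <- function(seed) small_spec(seed, n_lines = 60L, cohorts = 1L,
                                   environments = "I", env_means = c(I = 5000),
                                   gxe_scale = c(I = 1),
                                   dh_coupling = c(I = 0.3),
                                   block_sd = 0, rep_sd = 0, h2 = 0,
                                   polygenic_sd = 0)
  sim0 <- simulate_genotypes(mk0(109))
  ps <- vapply(1:100, function(k) {
    ph <- simulate_phenotypes(sim0, mk0(109 + 1000 * k))
    d <- ph$pheno[!ph$pheno$is_check, ]
    anova_gxe(data.frame(entry = d$entry, env = d$env,
                         value = d$GY))$p_values["genotype"]
  }, 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)

  ## zero genetic variance with a positive target errors
  sp_bad <- small_spec(110, polygenic_sd = 0, h2 = 0.5)
  sim_uniform <- list(true_calls = matrix(0L, 10, 4),
                      genotypes = genotype_matrix(matrix(0L, 10, 4),
                        map = data.frame(marker = paste0("m", 1:4),
                                         chrom = "1A", pos = 1:4)))
  class(sim_uniform) <- "sim_genotypes"
  sim_uniform$genotypes$map <- sim_uniform$genotypes$map
  expect_error(suppressWarnings(simulate_phenotypes(sim_uniform, sp_bad)))
})

test_that("planted QTL effects propagate into the phenotype", {
  mk <- function(q) small_spec(111, n_lines = 400L, cohorts = 1L,
                               environments = "I", env_means = c(I = 5000),
                               gxe_scale = c(I = 1), dh_coupling = c(I = 0.3),
                               qtl = q, polygenic_sd = 150, h2 = 0.6,
                               block_sd = 0, rep_sd = 0)
  sim <- simulate_genotypes(mk(NULL))
  ## plant at a common variant: the marker closest to carrier frequency 0.3
  cf <- colMeans(sim$true_calls == 2L)
  qm <- which.min(abs(cf - 0.3))
  expect_gt(cf[qm], 0.1)
  ## one polygenic draw confounds a single estimate (lines are related), so
  ## average the recovered effect over redrawn phenotypes
  est <- vapply(0:7, function(k) {
    mk2 <- function(q) small_spec(111 + 1000 * k, n_lines = 400L, cohorts = 1L,
                                  environments = "I", env_means = c(I = 5000),
                                  gxe_scale = c(I = 1),
                                  dh_coupling = c(I = 0.3), qtl = q,
                                  polygenic_sd = 150, h2 = 0.6,
                                  block_sd = 0, rep_sd = 0)
    ph <- simulate_phenotypes(sim, mk2(data.frame(marker = qm, effect = 300)))
    em <- tapply(ph$pheno$GY, ph$pheno$entry, mean)
    hap <- ifelse(sim$true_calls[names(em), qm] == 2L, "carrier", "other")
    eff <- allelic_effect(hap, as.numeric(em))
    if (eff$favorable[1] == "carrier") eff$effect else -eff$effect
  }, 0)
  expect_lt(abs(mean(est) - 300) / 300, 0.25)
})

test_that("fixture suite is reproducible, loadable, and oracle-consistent", {
  d1 <- tempfile("fx1")
  d2 <- tempfile("fx2")
  m1 <- fixture_suite(9, d1)
  m2 <- fixture_suite(9, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  g <- expect_silent(read_genotypes(file.path(d1, "perfect_ld_pair.csv"),
                                    "matrix-csv"))
  p <- pair_ld(g, 1, 2)
  expect_equal(p$Dprime, m1$perfect_ld_pair$Dprime)
  expect_equal(p$classification, m1$perfect_ld_pair$classification)

  gi <- read_genotypes(file.path(d1, "independence_pair.csv"), "matrix-csv")
  pi_ <- pair_ld(gi, 1, 2)
  expect_equal(pi_$D, m1$independence_pair$D)
  expect_equal(pi_$classification, m1$independence_pair$classification)

  gb <- read_genotypes(file.path(d1, "block_oracle.csv"), "matrix-csv")
  blocks <- find_blocks(gb)
  expect_length(blocks, m1$block_oracle$n_blocks)
  expect_equal(blocks[[1]]$markers, m1$block_oracle$members)
  expect_identical(block_signature(blocks), block_signature(bf_find_blocks(gb)))
})
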