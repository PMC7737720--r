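test_that("check-based adjustment follows the printed formula", {
  expect_equal(check_adjusted_means(100, 90, 90), 100)
  expect_equal(check_adjusted_means(100, 95, 90), 95)

  ## three trials with hand-set check means, spreadsheet style
  tbl <- data.frame(
    trial = rep(c("T1", "T2", "T3"), each = 4),
    env = "I",
    entry = paste0("e", 1:12),
    is_check = rep(c(TRUE, TRUE, FALSE, FALSE), 3),
    DH = c(70, 80, 72, 90,    # T1: check mean 75
           60, 70, 66, 77,    # T2: check mean 65
           80, 90, 95, 71))   # T3: check mean 85
  y_all <- mean(c(70, 80, 60, 70, 80, 90))  # 75
  out <- check_adjust_table(tbl, "DH")
  got <- out$value[match(paste0("e", 1:12), out$entry)]
  want <- c((c(70, 80, 72, 90) - 75) + y_all,
            (c(60, 70, 66, 77) - 65) + y_all,
            (c(80, 90, 95, 71) - 85) + y_all)
  expect_equal(got, want)

  ## within-trial rank order is preserved
  for (tr in c("T1", "T2", "T3")) {
    raw <- tbl$DH[tbl$trial == tr]
    adj <- out$value[match(tbl$entry[tbl$trial == tr], out$entry)]
    expect_equal(order(raw), order(adj))
  }

  expect_error(check_adjust_table(transform(tbl, is_check = FALSE), "DH"),
               "no checks")
})

test_that("block adjustment is a no-op without block effects and helps with them", {
  set.seed(21)
  n_e <- 24
  gval <- stats::rnorm(n_e, 5000, 300)
  base <- expand.grid(entry = paste0("e", seq_len(n_e)), rep = 1:3,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base$trial <- "T1"
  base$env <- "I"
  base$block <- paste0("b", (match(base$entry, paste0("e", 1:n_e)) - 1) %/% 6 + 1)

  ## no block effects: adjusted means equal raw entry means
  d0 <- base
  d0$GY <- gval[match(d0$entry, paste0("e", 1:n_e))] + stats::rnorm(nrow(d0), 0, 1)
  adj0 <- adjust_block_effects(d0)
  raw0 <- tapply(d0$GY, d0$entry, mean)
  expect_equal(adj0$value[match(names(raw0), adj0$entry)], as.numeric(raw0),
               tolerance = 0.02)

  ## planted +250 kg/ha in half the blocks, entries shuffled across blocks
  ## per replicate: adjusted means track truth better than raw means
  d1 <- do.call(rbind, lapply(1:3, function(r) {
    d <- base[base$rep == r, ]
    d$block <- paste0("b", sample(rep(1:4, each = 6)))
    d
  }))
  beff <- c(b1 = 250, b2 = 250, b3 = 0, b4 = 0)
  d1$GY <- gval[match(d1$entry, paste0("e", 1:n_e))] +
    beff[d1$block] + stats::rnorm(nrow(d1), 0, 60)
  adj1 <- adjust_block_effects(d1)
  raw1 <- tapply(d1$GY, d1$entry, mean)
  ord <- match(paste0("e", 1:n_e), adj1$entry)
  expect_gt(stats::cor(adj1$value[ord], gval),
            stats::cor(unname(raw1[paste0("e", 1:n_e)]), gval))

  ## degenerate single-entry table: the entry mean comes back
  d2 <- data.frame(trial = "T", env = "I", rep = 1:3, block = "b1",
                   entry = "only", GY = c(10, 12, 14))
  adj2 <- adjust_block_effects(d2)
  expect_equal(adj2$value, 12)
})

test_that("anova_gxe recovers the closed-form heritability at e = 1, r = 3", {
  set.seed(31)
  h2 <- replicate(40, {
    tt <- toy_trial_table(n_entries = 120, envs = "I", reps = 3,
                          sigma_g = 1, sigma_e = 1, seed = sample.int(1e6, 1))
    anova_gxe(tt$df)$H2
  })
  ## closed form: 1 / (1 + 1/3) = 0.75
  expect_lt(abs(mean(h2) - 0.75), 0.05)
  expect_true(all(abs(h2 - 0.75) < 0.12))
})

test_that("anova_gxe genotype P is uniform under the null", {
  set.seed(32)
  ps <- replicate(200, {
    tt <- toy_trial_table(n_entries = 25, envs = c("I", "SD"), reps = 2,
                          sigma_g = 0, sigma_e = 1, seed = sample.int(1e6, 1))
    anova_gxe(tt$df)$p_values["genotype"]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("anova_gxe clamps the genotype component under environment-only effects", {
  set.seed(33)
  df <- expand.grid(entry = paste0("e", 1:40), env = c("I", "MD", "SD"),
                    rep = 1:2, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$value <- c(I = 0, MD = 500, SD = 1500)[df$env] + stats::rnorm(nrow(df), 0, 1)
  fit <- anova_gxe(df)
  expect_lt(fit$varcomp["sigma2_g"], 0.05)
  expect_gte(fit$varcomp["sigma2_g"], 0)
  expect_lt(fit$p_values["environment"], 1e-10)
  expect_true(fit$H2 >= 0 && fit$H2 <= 1)
})

test_that("H2 estimates track the closed form over a variance grid", {
  set.seed(34)
  for (sg in c(0.5, 2)) {
    h2 <- replicate(15, {
      tt <- toy_trial_table(n_entries = 500, envs = c("I", "SD"), reps = 2,
                            sigma_g = sqrt(sg), sigma_e = 1,
                            seed = sample.int(1e6, 1))
      anova_gxe(tt$df)$H2
    })
    want <- sg / (sg + 1 / 4)     # e = 2, r = 2, no GxE
    expect_lt(abs(mean(h2) - want), 0.05)
  }
})

test_that("unbalanced tables take the REML path", {
  set.seed(35)
  tt <- toy_trial_table(n_entries = 60, envs = c("I", "SD"), reps = 2,
                        sigma_g = 1, sigma_e = 1)
  df <- tt$df[-sample.int(nrow(tt$df), 20), ]   # knock out cells
  expect_message(fit <- anova_gxe(df), "REML")
  expect_equal(fit$method, "reml")
  expect_true(fit$H2 > 0 && fit$H2 <= 1)
  expect_lt(fit$p_values["genotype"], 0.01)
})

test_that("trait correlations behave on exact, null and GxE-flipped traits", {
  d <- data.frame(trial = "T1", env = "I", entry = paste0("e", 1:50),
                  GY = 1:50, DH = 1:50, PH = rep(5, 50))
  out <- trait_correlations(d, c("GY", "DH", "PH"))
  r_gy_dh <- out$r[out$trait_a == "GY" & out$trait_b == "DH"]
  expect_equal(r_gy_dh, 1)
  expect_lt(out$p[out$trait_a == "GY" & out$trait_b == "DH"], 1e-20)
  ## constant trait: undefined
  expect_true(all(is.na(out$r[out$trait_b == "PH"])))

  ## independent traits at n = 500: |r| < 0.12 in the vast majority of draws
  set.seed(36)
  rs <- replicate(40, {
    d2 <- data.frame(trial = "T", env = "I", entry = 1:500,
                     GY = stats::rnorm(500), DH = stats::rnorm(500))
    trait_correlations(d2, c("GY", "DH"))$r
  })
  expect_gte(mean(abs(rs) < 0.12), 0.90)

  ## planted anti-correlation under stress, positive under irrigation
  set.seed(37)
  g <- stats::rnorm(300)
  d3 <- rbind(
    data.frame(trial = "T", env = "I", entry = 1:300,
               GY = g + stats::rnorm(300, 0, 0.5),
               DH = g + stats::rnorm(300, 0, 0.5)),
    data.frame(trial = "T", env = "HS", entry = 1:300,
               GY = g + stats::rnorm(300, 0, 0.5),
               DH = -g + stats::rnorm(300, 0, 0.5)))
  out3 <- trait_correlations(d3, c("GY", "DH"))
  expect_gt(out3$r[out3$env == "I"], 0.5)
  expect_lt(out3$r[out3$env == "HS"], -0.5)
})
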