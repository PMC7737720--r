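## Trial-design-aware phenotype handling: incomplete-block (alpha-lattice)
## adjustment of grain yield, check-based adjusted means for developmental
## traits, genotype x environment ANOVA with variance components and
## broad-sense heritability, and trait correlations.

#' Adjust plot values for incomplete-block effects
#'
#' Per trial x environment (x experiment, when an \code{experiment} column is
#' present), fits trait = replicate (fixed) + entry (fixed) + block within
#' replicate (random, shrunken/BLUP) and returns per-entry means of the
#' block- and replicate-corrected plot values, on the raw trait scale. A
#' replicate containing a single block gets block effect 0 (it is aliased
#' with the replicate effect). Groups where the mixed fit fails or is
#' degenerate fall back to block effect 0.
#'
#' @param tbl phenotype data.frame with columns \code{trial}, \code{env},
#'   \code{rep}, \code{block}, \code{entry}, the trait column, and optionally
#'   \code{experiment}.
#' @param trait name of the trait column (default \code{"GY"}).
#' @return data.frame(entry, trial, env, value): one adjusted mean per entry
#'   x trial x environment.
#' @export
adjust_block_effects <- function(tbl, trait = "GY") {
  need <- c("trial", "env", "rep", "block", "entry", trait)
  if (!all(need %in% names(tbl)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  tbl <- tbl[!is.na(tbl[[trait]]), , drop = FALSE]
  grp <- if ("experiment" %in% names(tbl))
    interaction(tbl$trial, tbl$env, tbl$experiment, drop = TRUE)
  else interaction(tbl$trial, tbl$env, drop = TRUE)
  parts <- lapply(split(tbl, grp), adjust_one_group, trait = trait)
  adj <- do.call(rbind, parts)
  out <- stats::aggregate(value ~ entry + trial + env, data = adj, FUN = mean)
  rownames(out) <- NULL
  out
}

adjust_one_group <- function(d, trait) {
  y <- d[[trait]]
  corrected <- y
  if (length(unique(d$entry)) > 1L) {
    rep_f <- factor(d$rep)
    blk_f <- factor(paste(d$rep, d$block, sep = ":"))
    ## block effects identifiable only when some replicate has >= 2 blocks
    blocks_per_rep <- tapply(d$block, rep_f, function(b) length(unique(b)))
    b_hat <- rep(0, length(y))
    if (any(blocks_per_rep > 1)) {
      fit <- tryCatch(
        suppressWarnings(suppressMessages(
          lme4::lmer(y ~ rep_f + entry_f + (1 | blk_f),
                     data = data.frame(y = y, rep_f = rep_f,
                                       entry_f = factor(d$entry), blk_f = blk_f),
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore")))),
        error = function(e) NULL)
      if (!is.null(fit)) {
        re <- lme4::ranef(fit)$blk_f
        b_hat <- re[match(as.character(blk_f), rownames(re)), 1]
        b_hat[is.na(b_hat)] <- 0
        ## zero out block effects inside single-block replicates
        single <- names(blocks_per_rep)[blocks_per_rep == 1]
        b_hat[as.character(rep_f) %in% single] <- 0
      }
    }
    ## replicate correction as deviation from the group mean replicate level
    rep_means <- tapply(y - b_hat, rep_f, mean)
    r_hat <- rep_means[as.character(rep_f)] - mean(rep_means)
    corrected <- y - b_hat - r_hat
  }
  data.frame(entry = d$entry, trial = d$trial, env = d$env, value = corrected)
}

#' Check-based adjusted mean
#'
#' The adjusted value of an entry is \code{(y_ij - y_i) + y_all}: its raw
#' trial value, centered on the mean of the checks of that trial and
#' re-expressed around the grand check mean over all trials. Vectorized.
#'
#' @param y_ij entry value(s) in a trial.
#' @param y_i check mean of that trial.
#' @param y_all grand check mean over all trials.
#' @return adjusted value(s), same units as \code{y_ij}.
#' @export
check_adjusted_means <- function(y_ij, y_i, y_all) {
  stopifnot(all(is.finite(y_i)), all(is.finite(y_all)))
  (y_ij - y_i) + y_all
}

#' Check-adjust a trait across a phenotype table
#'
#' Applies \code{\link{check_adjusted_means}} per (trial, env): the trial
#' check mean is the mean of the trait over plots flagged \code{is_check},
#' the grand check mean pools checks over all trials of the same
#' environment-free table. Intended for developmental traits (DH, PH).
#'
#' @param tbl phenotype data.frame with columns \code{trial}, \code{env},
#'   \code{entry}, \code{is_check} and the trait column.
#' @param trait trait column name.
#' @return data.frame(entry, trial, env, value) of adjusted entry means.
#' @export
check_adjust_table <- function(tbl, trait) {
  need <- c("trial", "env", "entry", "is_check", trait)
  if (!all(need %in% names(tbl)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  tbl <- tbl[!is.na(tbl[[trait]]), , drop = FALSE]
  if (!any(tbl$is_check)) stop("no checks in table; cannot check-adjust")
  y_all <- mean(tbl[[trait]][tbl$is_check])
  grp <- interaction(tbl$trial, tbl$env, drop = TRUE)
  parts <- lapply(split(tbl, grp), function(d) {
    if (!any(d$is_check))
      stop("no checks in trial ", d$trial[1], " env ", d$env[1])
    y_i <- mean(d[[trait]][d$is_check])
    em <- tapply(d[[trait]], d$entry, mean)
    data.frame(entry = names(em), trial = d$trial[1], env = d$env[1],
               value = check_adjusted_means(as.numeric(em), y_i, y_all))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Genotype x environment ANOVA, variance components and heritability
#'
#' Two-way genotype + environment + interaction analysis. For balanced data
#' the variance components come from expected mean squares (entries random):
#' sigma2_err = MS_error, sigma2_gxe = (MS_GxE - MS_error)/r, sigma2_g =
#' (MS_G - MS_GxE)/(e r); genotype and environment F-tests use the
#' interaction mean square as denominator, the interaction is tested against
#' error. Unbalanced data (unequal cell counts) switch to an lme4 REML fit
#' (logged via a message). Broad-sense heritability on an entry-mean basis:
#' H2 = sigma2_g / (sigma2_g + sigma2_gxe/e + sigma2_err/(e r)). Components
#' are clamped at 0.
#'
#' @param df data.frame with columns \code{entry}, \code{env}, \code{value},
#'   and optionally \code{rep}. One environment is allowed (no G x E term).
#' @return list of class \code{trial_summary}: \code{varcomp} (sigma2_g,
#'   sigma2_gxe, sigma2_err), \code{p_values} (genotype, environment, gxe),
#'   \code{H2}, \code{n_env}, \code{n_rep}, \code{trait_range},
#'   \code{method} ("ems" or "reml").
#' @export
anova_gxe <- function(df) {
  stopifnot(all(c("entry", "env", "value") %in% names(df)))
  df <- df[!is.na(df$value), , drop = FALSE]
  df$entry <- factor(df$entry)
  df$env <- factor(df$env)
  e <- nlevels(df$env)
  if (nlevels(df$entry) < 2) stop("need >= 2 entries")
  cell <- table(df$entry, df$env)
  r <- max(cell)
  balanced <- length(unique(as.vector(cell))) == 1L && min(cell) >= 1L
  if (balanced) {
    out <- anova_gxe_ems(df, e, r)
  } else {
    message("unbalanced genotype x environment table: using REML variance components")
    out <- anova_gxe_reml(df, e)
  }
  out$trait_range <- range(df$value)
  out$n_env <- e
  structure(out, class = "trial_summary")
}

## balanced two-way ANOVA by direct sums of squares over cell means
## (identical to the lm/aov decomposition, but linear in the data size,
## which matters with thousands of entries)
anova_gxe_ems <- function(df, e, r) {
  y <- df$value
  n_g <- nlevels(df$entry)
  ybar <- mean(y)
  m_g <- tapply(y, df$entry, mean)
  ss_g <- e * r * sum((m_g - ybar)^2)
  df_g <- n_g - 1L
  ss_t <- sum((y - ybar)^2)
  if (e > 1) {
    m_e <- tapply(y, df$env, mean)
    m_ge <- tapply(y, list(df$entry, df$env), mean)
    ss_e <- n_g * r * sum((m_e - ybar)^2)
    ss_ge <- r * sum((m_ge - outer(m_g, rep(1, e)) -
                        outer(rep(1, n_g), m_e) + ybar)^2)
    df_e <- e - 1L
    df_ge <- (n_g - 1L) * (e - 1L)
  } else {
    ss_e <- 0; ss_ge <- 0; df_e <- 0L; df_ge <- 0L
  }
  ss_err <- max(ss_t - ss_g - ss_e - ss_ge, 0)
  df_err <- n_g * e * (r - 1L)

  ms_g <- ss_g / df_g
  if (e > 1 && r > 1) {
    ms_e <- ss_e / df_e
    ms_ge <- ss_ge / df_ge
    ms_err <- ss_err / df_err
    s_err <- ms_err
    s_gxe <- max(0, (ms_ge - ms_err) / r)
    s_g <- max(0, (ms_g - ms_ge) / (e * r))
    p_g <- stats::pf(ms_g / ms_ge, df_g, df_ge, lower.tail = FALSE)
    p_e <- stats::pf(ms_e / ms_ge, df_e, df_ge, lower.tail = FALSE)
    p_ge <- stats::pf(ms_ge / ms_err, df_ge, df_err, lower.tail = FALSE)
  } else if (e > 1) {               # one observation per cell: GxE = residual
    ms_e <- ss_e / df_e
    ms_ge <- ss_ge / df_ge
    s_err <- 0
    s_gxe <- ms_ge                  # interaction + error, inseparable
    s_g <- max(0, (ms_g - ms_ge) / e)
    p_g <- stats::pf(ms_g / ms_ge, df_g, df_ge, lower.tail = FALSE)
    p_e <- stats::pf(ms_e / ms_ge, df_e, df_ge, lower.tail = FALSE)
    p_ge <- NA_real_
  } else {                          # single environment with replicates
    ms_err <- ss_err / df_err
    s_err <- ms_err
    s_gxe <- 0
    s_g <- max(0, (ms_g - ms_err) / r)
    p_g <- stats::pf(ms_g / ms_err, df_g, df_err, lower.tail = FALSE)
    p_e <- NA_real_
    p_ge <- NA_real_
  }
  H2 <- h2_entry_mean(s_g, s_gxe, s_err, e, r)
  list(varcomp = c(sigma2_g = unname(s_g), sigma2_gxe = unname(s_gxe),
                   sigma2_err = unname(s_err)),
       p_values = c(genotype = unname(p_g), environment = unname(p_e),
                    gxe = unname(p_ge)),
       H2 = H2, n_rep = r, method = "ems")
}

anova_gxe_reml <- function(df, e) {
  r <- mean(table(df$entry, df$env)[table(df$entry, df$env) > 0])
  has_rep <- e > 1 && any(table(df$entry, df$env) > 1)
  form <- if (has_rep) value ~ env + (1 | entry) + (1 | entry:env)
          else if (e > 1) value ~ env + (1 | entry)
          else value ~ (1 | entry)
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = df,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s_g <- max(0, vc$vcov[vc$grp == "entry"])
  s_gxe <- if (has_rep) max(0, vc$vcov[vc$grp == "entry:env"]) else 0
  s_err <- vc$vcov[vc$grp == "Residual"]
  if (e == 1 || !has_rep) { s_gxe <- if (e > 1) s_err else 0 }
  ## genotype LRT against the model without the entry term (ML refits)
  fit_ml <- stats::update(fit, REML = FALSE)
  fit0 <- if (has_rep)
    suppressWarnings(suppressMessages(
      lme4::lmer(value ~ env + (1 | entry:env), data = df, REML = FALSE,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore"))))
  else if (e > 1) stats::lm(value ~ env, data = df)
  else stats::lm(value ~ 1, data = df)
  lrt <- 2 * (as.numeric(stats::logLik(fit_ml)) - as.numeric(stats::logLik(fit0)))
  p_g <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE) / 2  # boundary
  H2 <- h2_entry_mean(s_g, s_gxe, s_err, e, r)
  list(varcomp = c(sigma2_g = s_g, sigma2_gxe = s_gxe, sigma2_err = s_err),
       p_values = c(genotype = p_g, environment = NA_real_, gxe = NA_real_),
       H2 = H2, n_rep = r, method = "reml")
}

h2_entry_mean <- function(s_g, s_gxe, s_err, e, r) {
  den <- s_g + s_gxe / e + s_err / (e * r)
  if (den <= 0) return(0)
  min(max(s_g / den, 0), 1)
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("G x E summary (%s): H2 = %.3f over %d env x %s rep\n",
              x$method, x$H2, x$n_env, format(x$n_rep)))
  cat(sprintf("  sigma2_g = %.3g, sigma2_gxe = %.3g, sigma2_err = %.3g\n",
              x$varcomp[1], x$varcomp[2], x$varcomp[3]))
  cat(sprintf("  P: genotype = %.3g, environment = %.3g, GxE = %.3g\n",
              x$p_values[1], x$p_values[2], x$p_values[3]))
  invisible(x)
}

#' Pairwise trait correlations
#'
#' Pearson correlations with two-sided P-values between traits, per
#' (trial, env), on complete cases. Constant traits give \code{NA}.
#'
#' @param means data.frame with columns \code{entry}, \code{trial},
#'   \code{env} and one column per trait.
#' @param traits character vector of trait column names.
#' @return data.frame(trial, env, trait_a, trait_b, r, p, n).
#' @export
trait_correlations <- function(means, traits = c("GY", "DH", "PH")) {
  stopifnot(length(traits) >= 2, all(traits %in% names(means)))
  grp <- interaction(means$trial, means$env, drop = TRUE)
  combs <- utils::combn(traits, 2)
  parts <- lapply(split(means, grp), function(d) {
    do.call(rbind, lapply(seq_len(ncol(combs)), function(k) {
      a <- d[[combs[1, k]]]; b <- d[[combs[2, k]]]
      ok <- stats::complete.cases(a, b)
      res <- data.frame(trial = d$trial[1], env = d$env[1],
                        trait_a = combs[1, k], trait_b = combs[2, k],
                        r = NA_real_, p = NA_real_, n = sum(ok))
      if (sum(ok) >= 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
        ct <- stats::cor.test(a[ok], b[ok], method = "pearson")
        res$r <- unname(ct$estimate)
        res$p <- ct$p.value
      }
      res
    }))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
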