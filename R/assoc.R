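## Mixed-linear-model association of multiallelic haplotype blocks:
## VanRaden genomic relationship matrix, BIC-guided choice of principal
## components, one REML variance-component fit per trait x trial x
## environment (EMMAX-style), and per-block generalized-least-squares F-tests
## on the allele dummies. Allelic effects are descriptive with/without-mean
## differences on the raw trait scale.

#' VanRaden genomic relationship matrix (method 1)
#'
#' K = Z Z' / (2 sum p_k (1 - p_k)) where Z holds allele doses (0/1/2 minor
#' alleles) centered by twice the allele frequency. Missing calls are
#' mean-imputed for this computation only.
#'
#' @param g a \code{\link{genotype_matrix}} (markers already filtered).
#' @return n x n numeric matrix with line ids as dimnames.
#' @export
vanraden_kinship <- function(g) {
  Z <- g$calls
  storage.mode(Z) <- "double"
  p <- colMeans(Z, na.rm = TRUE) / 2
  poly <- which(!is.nan(p) & p > 0 & p < 1)
  if (!length(poly)) stop("all markers monomorphic; kinship undefined")
  Z <- Z[, poly, drop = FALSE]
  p <- p[poly]
  for (k in seq_along(p)) {          # mean-impute missing doses
    miss <- is.na(Z[, k])
    if (any(miss)) Z[miss, k] <- 2 * p[k]
  }
  Z <- sweep(Z, 2, 2 * p)
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(g$calls), rownames(g$calls))
  K
}

#' Principal components of the genotype matrix
#'
#' PCs of the centered, mean-imputed allele-dose matrix; the fixed-effect
#' structure covariates of the mixed model.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param n_pcs number of components to return.
#' @return n x n_pcs matrix of PC scores.
#' @export
genotype_pcs <- function(g, n_pcs = 10L) {
  Z <- g$calls
  storage.mode(Z) <- "double"
  p <- colMeans(Z, na.rm = TRUE) / 2
  keep <- which(!is.nan(p) & p > 0 & p < 1)
  Z <- Z[, keep, drop = FALSE]
  for (k in seq_len(ncol(Z))) {
    miss <- is.na(Z[, k])
    if (any(miss)) Z[miss, k] <- 2 * p[keep[k]]
  }
  n_pcs <- min(n_pcs, nrow(Z) - 1L, ncol(Z))
  pr <- stats::prcomp(Z, center = TRUE, scale. = FALSE, rank. = n_pcs)
  scores <- pr$x[, seq_len(n_pcs), drop = FALSE]
  rownames(scores) <- rownames(g$calls)
  scores
}

#' Choose the number of structure PCs by BIC
#'
#' Fits fixed-effect-only regressions of the phenotype on 0..max_pcs leading
#' PCs and returns the count minimizing BIC; ties go to the smaller count.
#'
#' @param pcs matrix of PC scores (columns ordered by variance explained).
#' @param y phenotype vector aligned to rows of \code{pcs}.
#' @param max_pcs largest count considered.
#' @return integer in 0..max_pcs.
#' @export
select_pcs_bic <- function(pcs, y, max_pcs = 10L) {
  ok <- stats::complete.cases(y, pcs)
  y <- y[ok]
  pcs <- pcs[ok, , drop = FALSE]
  n <- length(y)
  kmax <- min(max_pcs, ncol(pcs))
  bic <- numeric(kmax + 1L)
  for (k in 0:kmax) {
    X <- cbind(1, pcs[, seq_len(k), drop = FALSE])
    rss <- sum(stats::lm.fit(X, y)$residuals^2)
    bic[k + 1L] <- n * log(rss / n) + (k + 1L) * log(n)
  }
  which.min(bic) - 1L   # which.min takes the first minimum: fewer PCs on ties
}

#' REML null-model fit for the mixed linear model (EMMAX-style)
#'
#' Fits y = X beta + u + e with u ~ N(0, sigma2_g K), e ~ N(0, sigma2_e I) by
#' restricted maximum likelihood, profiling the variance ratio
#' delta = sigma2_e / sigma2_g on a log grid refined by golden-section
#' search, after a single spectral decomposition of K. The fitted variance
#' components are then held fixed for all per-block tests of that trait x
#' trial x environment (one REML per phenotype, not per marker).
#'
#' @param y phenotype vector (no NAs).
#' @param X fixed-effect design (intercept + PCs + covariates).
#' @param K kinship matrix aligned to \code{y}.
#' @param delta_range log10 search range for delta.
#' @param eig optional precomputed \code{eigen(K, symmetric = TRUE)}, reused
#'   across phenotypes sharing one kinship matrix.
#' @return list of class \code{mlm_null}: \code{delta}, \code{sigma2_g},
#'   \code{sigma2_e}, \code{V} (fitted covariance), \code{cholV} (upper
#'   Cholesky factor), \code{n}, \code{logREML}.
#' @export
mlm_null_reml <- function(y, X, K, delta_range = c(-5, 5), eig = NULL) {
  stopifnot(!anyNA(y), nrow(K) == length(y))
  n <- length(y)
  X <- as.matrix(X)
  eg <- if (is.null(eig)) eigen(K, symmetric = TRUE) else eig
  xi <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  p <- qr(X)$rank
  reml_ll <- function(log10d) {
    d <- 10^log10d
    w <- xi + d
    sw <- 1 / sqrt(w)
    Xw <- Xt * sw
    yw <- yt * sw
    fit <- stats::lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    s2 <- rss / (n - p)
    XtX <- crossprod(Xw)
    ld_xtx <- determinant(XtX, logarithm = TRUE)$modulus
    -0.5 * ((n - p) * log(s2) + sum(log(w)) + ld_xtx + (n - p))
  }
  grid <- seq(delta_range[1], delta_range[2], length.out = 64)
  ll <- vapply(grid, reml_ll, 0)
  k <- which.max(ll)
  lo <- grid[max(1, k - 1)]
  hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(reml_ll, c(lo, hi), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  delta <- 10^opt$maximum
  w <- xi + delta
  sw <- 1 / sqrt(w)
  fit <- stats::lm.fit(Xt * sw, yt * sw)
  sigma2_g <- sum(fit$residuals^2) / (n - p)
  sigma2_e <- delta * sigma2_g
  ## boundary: effectively no genetic variance
  if (opt$maximum >= delta_range[2] - 1e-8) {
    sigma2_g <- 0
    sigma2_e <- stats::var(y) * (n - 1) / n
  }
  V <- if (sigma2_g > 0) sigma2_g * K + diag(sigma2_e, n) else diag(1, n)
  V <- V + diag(1e-8 * mean(diag(V)), n)   # PSD jitter for the Cholesky
  structure(list(delta = delta, sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 V = V, cholV = chol(V), n = n, logREML = opt$objective),
            class = "mlm_null")
}

## allele dummy matrix: k-1 indicators, reference = most frequent allele
allele_dummies <- function(hap) {
  tab <- table(hap)
  lev <- names(tab)[order(-as.integer(tab), names(tab))]
  f <- factor(as.character(hap), levels = lev)
  if (nlevels(f) < 2) return(NULL)
  stats::model.matrix(~f)[, -1, drop = FALSE]
}

## merge allele classes smaller than min_class into missing
floor_classes <- function(hap, min_class) {
  tab <- table(hap)
  small <- names(tab)[tab < min_class]
  hap[as.character(hap) %in% small] <- NA
  hap
}

#' Mixed-model association test for one multiallelic haplotype block
#'
#' Tests the k-1 allele dummies (reference = most frequent allele) of one
#' block with a generalized-least-squares F-test under the covariance
#' sigma2_g K + sigma2_e I fitted once by \code{\link{mlm_null_reml}}. Lines
#' with a missing haplotype call are dropped for that block; allele classes
#' with fewer than \code{min_class} lines are recoded missing. With
#' \code{null_fit = NULL} (or zero genetic variance) the test reduces exactly
#' to the ordinary-least-squares F-test.
#'
#' @param hap integer/character vector of block allele calls (NA = missing).
#' @param y phenotype vector aligned to \code{hap}.
#' @param null_fit a \code{mlm_null} object from \code{\link{mlm_null_reml}},
#'   or NULL for the OLS path.
#' @param pcs optional matrix of structure PCs (fixed covariates).
#' @param covariates optional matrix/data.frame of further fixed covariates
#'   (e.g. DH, PH).
#' @param min_class minimum lines per tested allele class.
#' @param block_id,trial,env labels carried into the result.
#' @return list of class \code{assoc_result}: \code{block_id}, \code{trial},
#'   \code{env}, \code{p_value}, \code{df}, \code{F}, \code{n_lines},
#'   \code{allele_means}, \code{favorable}, \code{effect} (with/without mean
#'   difference, trait units). \code{p_value} is NA when fewer than two
#'   allele classes survive.
#' @export
mlm_assoc <- function(hap, y, null_fit = NULL, pcs = NULL, covariates = NULL,
                      min_class = 10L, block_id = NA_character_,
                      trial = NA_character_, env = NA_character_) {
  n_all <- length(y)
  hap <- floor_classes(hap, min_class)
  X0 <- cbind(`(Intercept)` = rep(1, n_all))
  if (!is.null(pcs)) X0 <- cbind(X0, as.matrix(pcs))
  if (!is.null(covariates)) X0 <- cbind(X0, as.matrix(covariates))
  ok <- !is.na(hap) & !is.na(y) & stats::complete.cases(X0)
  res <- list(block_id = block_id, trial = trial, env = env,
              p_value = NA_real_, df = NA_integer_, F = NA_real_,
              n_lines = sum(ok), allele_means = NULL,
              favorable = NA_character_, effect = NA_real_)
  D <- allele_dummies(hap[ok])
  if (is.null(D)) {
    return(structure(res, class = "assoc_result"))
  }
  X0s <- X0[ok, , drop = FALSE]
  X1s <- cbind(X0s, D)
  ys <- y[ok]
  if (!is.null(null_fit) && null_fit$sigma2_g > 0) {
    R <- if (all(ok) && !is.null(null_fit$cholV)) null_fit$cholV
         else chol(null_fit$V[ok, ok])
    yt <- backsolve(R, ys, transpose = TRUE)
    X0t <- backsolve(R, X0s, transpose = TRUE)
    X1t <- backsolve(R, X1s, transpose = TRUE)
  } else {
    yt <- ys; X0t <- X0s; X1t <- X1s
  }
  f0 <- stats::lm.fit(X0t, yt)
  f1 <- stats::lm.fit(X1t, yt)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  df1 <- f1$rank - f0$rank          # aliased dummy columns drop out here
  df2 <- length(ys) - f1$rank
  if (df1 < 1 || df2 < 1) {
    return(structure(res, class = "assoc_result"))
  }
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  ## constant (or perfectly fitted) phenotype: no variance left to test
  if (!is.finite(Fstat) || Fstat < 0 ||
      rss0 <= 1e-12 * max(sum(yt^2), 1)) Fstat <- 0
  eff <- allelic_effect(hap[ok], ys)
  res$p_value <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  res$df <- df1
  res$F <- Fstat
  res$allele_means <- eff$allele_means
  res$favorable <- eff$favorable
  res$effect <- eff$effect
  structure(res, class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("%s [%s, %s]: F = %.3f (df %s), P = %.3g, favorable = %s, effect = %.1f (n = %d)\n",
              x$block_id, x$trial, x$env, x$F, format(x$df), x$p_value,
              paste(x$favorable, collapse = "+"), x$effect, x$n_lines))
  invisible(x)
}

#' Descriptive allelic effect of a haplotype block
#'
#' Per-allele phenotype means; the favorable allele is the one with the
#' highest mean, and its effect is mean(lines with it) - mean(lines without
#' it). Additional alleles are reported as favorable when their mean also
#' exceeds the without-group mean by more than the standard error of that
#' allele's mean (the printed two-favorable-allele cases motivate this rule).
#'
#' @param hap allele calls (NA dropped with the paired y).
#' @param y phenotype vector aligned to \code{hap}.
#' @return list: \code{allele_means} (named, frequency-ordered),
#'   \code{favorable} (character vector, primary first), \code{effect}
#'   (primary with/without difference, trait units).
#' @export
allelic_effect <- function(hap, y) {
  ok <- !is.na(hap) & !is.na(y)
  hap <- as.character(hap[ok])
  y <- y[ok]
  tab <- table(hap)
  lev <- names(tab)[order(-as.integer(tab), names(tab))]
  mns <- vapply(lev, function(a) mean(y[hap == a]), 0)
  fav <- lev[which.max(mns)]
  without <- y[hap != fav]
  effect <- if (length(without)) mean(y[hap == fav]) - mean(without) else 0
  secondary <- character()
  if (length(lev) > 2 && length(without)) {
    m_wo <- mean(without)
    for (a in setdiff(lev, fav)) {
      ya <- y[hap == a]
      se <- stats::sd(ya) / sqrt(length(ya))
      if (is.finite(se) && mean(ya) - m_wo > se) secondary <- c(secondary, a)
    }
  }
  list(allele_means = mns, favorable = c(fav, secondary), effect = effect)
}

#' Scan all haplotype blocks in one trial x environment
#'
#' Runs \code{\link{mlm_assoc}} for every block column against one adjusted
#' phenotype, with a single REML variance fit shared across blocks.
#'
#' @param hg a \code{haplotype_genotypes} object.
#' @param y named phenotype vector (names = line ids) or vector aligned to
#'   the lines of \code{hg}.
#' @param K kinship matrix over the same lines, or NULL for plain OLS.
#' @param n_pcs number of structure PCs ("auto" selects 0..10 by BIC against
#'   \code{y}; requires \code{pcs}).
#' @param pcs precomputed PC matrix (needed for \code{n_pcs > 0} or "auto").
#' @param covariates optional fixed covariates (e.g. DH, PH).
#' @param min_class minimum lines per allele class.
#' @param trial,env labels carried into the results.
#' @return data.frame, one row per block: block_id, trial, env, df, F,
#'   p_value, favorable, effect, n_lines.
#' @export
assoc_scan <- function(hg, y, K = NULL, n_pcs = 0L, pcs = NULL,
                       covariates = NULL, min_class = 10L,
                       trial = NA_character_, env = NA_character_) {
  if (!is.null(names(y))) {
    y <- y[match(rownames(hg$calls), names(y))]
  }
  ok <- !is.na(y)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(as.matrix(covariates))
  if (identical(n_pcs, "auto")) {
    if (is.null(pcs)) stop("n_pcs = 'auto' requires a pcs matrix")
    n_pcs <- select_pcs_bic(pcs[ok, , drop = FALSE], y[ok])
  }
  Xpcs <- if (n_pcs > 0) pcs[, seq_len(n_pcs), drop = FALSE] else NULL
  covs <- if (!is.null(covariates)) as.matrix(covariates) else NULL
  null_fit <- NULL
  if (!is.null(K)) {
    X <- cbind(rep(1, sum(ok)),
               if (!is.null(Xpcs)) Xpcs[ok, , drop = FALSE],
               if (!is.null(covs)) covs[ok, , drop = FALSE])
    null_fit_sub <- mlm_null_reml(y[ok], X, K[ok, ok])
    ## expand V back to full line set so per-block subsetting stays aligned
    null_fit <- null_fit_sub
    if (!all(ok)) {
      V <- matrix(NA_real_, length(y), length(y))
      V[ok, ok] <- null_fit_sub$V
      null_fit$V <- V
      null_fit$cholV <- NULL
    }
  }
  rows <- lapply(seq_len(ncol(hg$calls)), function(k) {
    hap <- hg$calls[, k]
    hap[!ok] <- NA
    r <- mlm_assoc(hap, y, null_fit = null_fit, pcs = Xpcs,
                   covariates = covs, min_class = min_class,
                   block_id = hg$block_ids[k], trial = trial, env = env)
    data.frame(block_id = r$block_id, trial = r$trial, env = r$env,
               df = r$df, F = r$F, p_value = r$p_value,
               favorable = paste(r$favorable, collapse = "+"),
               effect = r$effect, n_lines = r$n_lines)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic-control inflation factor
#'
#' lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1): 1 under a calibrated
#' null, > 1 under residual structure confounding.
#'
#' @param p vector of association P-values.
#' @return numeric lambda.
#' @export
genomic_lambda <- function(p) {
  p <- p[is.finite(p) & p > 0 & p <= 1]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
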