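## Pairwise linkage disequilibrium for inbred lines: r2, D, D' with a
## likelihood confidence interval over |D'|, Gabriel-style pair
## classification, and LOESS LD-decay estimation.

#' LD classification parameters
#'
#' Bounds of the confidence-interval method: a pair is in strong LD when the
#' 95\% CI of |D'| has lower bound >= \code{ci_strong_low} and upper bound >=
#' \code{ci_strong_high}; it shows strong historical recombination when the
#' upper bound is below \code{ci_recomb_high}; otherwise it is inconclusive.
#'
#' @param ci_strong_low,ci_strong_high,ci_recomb_high numeric bounds in [0,1].
#' @param grid_step grid resolution for the |D'| likelihood.
#' @return list of class \code{ld_params}.
#' @export
ld_params <- function(ci_strong_low = 0.6, ci_strong_high = 0.95,
                      ci_recomb_high = 0.90, grid_step = 0.001) {
  stopifnot(ci_strong_low <= ci_strong_high, grid_step > 0)
  structure(list(ci_strong_low = ci_strong_low,
                 ci_strong_high = ci_strong_high,
                 ci_recomb_high = ci_recomb_high,
                 grid_step = grid_step),
            class = "ld_params")
}

## two-locus haplotype counts from homozygous calls of inbred lines;
## heterozygous or missing calls at either locus are excluded.
hap_counts <- function(ci, cj) {
  use <- which((ci == 0L | ci == 2L) & (cj == 0L | cj == 2L))
  ci <- ci[use]
  cj <- cj[use]
  c(n_AB = sum(ci == 0L & cj == 0L),
    n_Ab = sum(ci == 0L & cj == 2L),
    n_aB = sum(ci == 2L & cj == 0L),
    n_ab = sum(ci == 2L & cj == 2L))
}

## D and D' from 4 haplotype frequencies (pAB, pAb, paB, pab)
dprime_from_freqs <- function(p) {
  p <- unname(p)
  pA <- p[1] + p[2]; pB <- p[1] + p[3]
  D <- p[1] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (dmax <= 0) NA_real_ else abs(D) / dmax
  r2 <- {
    den <- pA * (1 - pA) * pB * (1 - pB)
    if (den <= 0) NA_real_ else D^2 / den
  }
  list(D = D, Dprime = dp, r2 = r2, pA = pA, pB = pB)
}

#' Pairwise LD statistics for two markers
#'
#' Haplotype frequencies are read directly from two-locus homozygous calls
#' (inbred assumption; heterozygous or missing calls are excluded), then
#' D = p_AB - p_A p_B, D' = |D|/D_max and r2 = D^2/(p_A p_a p_B p_b). The
#' 95\% likelihood CI of |D'| and the strong-LD / strong-recombination /
#' inconclusive classification follow the confidence-interval block method.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param i,j marker indices (or marker ids).
#' @param params an \code{\link{ld_params}} object.
#' @return list of class \code{ld_pair} with haplotype frequencies, D,
#'   Dprime, r2, ci_low, ci_high, classification and n_informative. When the
#'   pair is monomorphic after exclusions the LD statistics are \code{NA} and
#'   \code{classification} is \code{NA} (flagged undefined).
#' @export
pair_ld <- function(g, i, j, params = ld_params()) {
  if (is.character(i)) i <- match(i, g$map$marker)
  if (is.character(j)) j <- match(j, g$map$marker)
  n <- hap_counts(g$calls[, i], g$calls[, j])
  nt <- sum(n)
  if (nt < 4) stop("insufficient data: only ", nt, " informative lines")
  out <- list(marker_i = g$map$marker[i], marker_j = g$map$marker[j],
              distance_bp = if (g$map$chrom[i] == g$map$chrom[j])
                abs(g$map$pos[j] - g$map$pos[i]) else NA_real_,
              hap_freqs = n / nt, n_informative = nt)
  pA <- (n[1] + n[2]) / nt
  pB <- (n[1] + n[3]) / nt
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) {
    out <- c(out, list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                       ci_low = NA_real_, ci_high = NA_real_,
                       classification = NA_character_, monomorphic = TRUE))
    return(structure(out, class = "ld_pair"))
  }
  st <- dprime_from_freqs(n / nt)
  ci <- dprime_ci(n, grid_step = params$grid_step)
  out <- c(out, list(D = st$D, Dprime = st$Dprime, r2 = st$r2,
                     ci_low = ci[1], ci_high = ci[2],
                     classification = classify_pair(ci[1], ci[2], params),
                     monomorphic = FALSE))
  structure(out, class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("%s - %s: D'=%.3f r2=%.3f CI=[%.3f, %.3f] %s (n=%d)\n",
              x$marker_i, x$marker_j, x$Dprime, x$r2, x$ci_low, x$ci_high,
              ifelse(is.na(x$classification), "undefined", x$classification),
              x$n_informative))
  invisible(x)
}

#' Likelihood confidence interval for |D'|
#'
#' Evaluates the multinomial likelihood of the four haplotype counts on a
#' grid of |D'| values in [0, 1] (allele frequencies fixed at their MLEs, D
#' taking the observed sign), normalizes it to total mass 1, and returns the
#' one-sided 5\%/95\% cumulative bounds: \code{ci_low} is the smallest grid
#' value with cumulative mass >= 0.05 and \code{ci_high} the smallest with
#' mass >= 0.95.
#'
#' @param counts 4 non-negative haplotype counts (n_AB, n_Ab, n_aB, n_ab),
#'   total >= 4.
#' @param grid_step grid resolution (default 0.001).
#' @return numeric vector \code{c(ci_low, ci_high)}.
#' @export
dprime_ci <- function(counts, grid_step = 0.001) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 4, all(counts >= 0))
  nt <- sum(counts)
  if (nt < 4) stop("insufficient data: total count ", nt)
  pA <- (counts[1] + counts[2]) / nt
  pB <- (counts[1] + counts[3]) / nt
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("degenerate margins: a locus is monomorphic")
  D_obs <- counts[1] / nt - pA * pB
  s <- if (D_obs >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = grid_step)
  D <- s * grid * dmax
  p1 <- pA * pB + D
  p2 <- pA * (1 - pB) - D
  p3 <- (1 - pA) * pB - D
  p4 <- (1 - pA) * (1 - pB) + D
  ## multinomial log likelihood with the 0 * log(0) = 0 convention; a
  ## frequency pushed below 0 by numerical noise at the grid edge counts as 0
  P <- cbind(p1, p2, p3, p4)
  P[P < 0 & P > -1e-12] <- 0
  ll <- numeric(length(grid))
  for (k in 1:4) {
    if (counts[k] == 0) next
    term <- counts[k] * log(P[, k])
    term[P[, k] <= 0] <- -Inf
    ll <- ll + term
  }
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  c(ci_low = grid[which(cum >= 0.05)[1]],
    ci_high = grid[which(cum >= 0.95)[1]])
}

#' Classify a marker pair from its |D'| confidence interval
#'
#' @param ci_low,ci_high CI bounds in [0,1], \code{ci_low <= ci_high}.
#' @param params an \code{\link{ld_params}}.
#' @return one of \code{"strong_LD"}, \code{"strong_recombination"},
#'   \code{"inconclusive"}.
#' @export
classify_pair <- function(ci_low, ci_high, params = ld_params()) {
  stopifnot(ci_low >= 0, ci_high <= 1, ci_low <= ci_high)
  if (ci_low >= params$ci_strong_low && ci_high >= params$ci_strong_high)
    "strong_LD"
  else if (ci_high < params$ci_recomb_high)
    "strong_recombination"
  else
    "inconclusive"
}

#' All pairwise r2 values within a distance window
#'
#' Intrachromosomal marker pairs within \code{max_dist_bp}, optionally
#' down-sampled, with distance and r2 per pair. Used by
#' \code{\link{ld_decay}}; exported for plotting.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param max_dist_bp maximum pair distance (default 10 Mb).
#' @param sample_pairs optional cap on the number of pairs (random sample).
#' @param seed RNG seed for the down-sampling.
#' @param min_lines minimum informative lines per pair.
#' @return data.frame(distance_bp, r2).
#' @export
ld_pair_scatter <- function(g, max_dist_bp = 10e6, sample_pairs = NULL,
                            seed = 1L, min_lines = 4L) {
  pairs <- intra_pairs(g$map, max_dist_bp)
  if (!is.null(sample_pairs) && nrow(pairs) > sample_pairs) {
    set.seed(seed)
    pairs <- pairs[sample.int(nrow(pairs), sample_pairs), , drop = FALSE]
  }
  r2 <- numeric(nrow(pairs))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    n <- hap_counts(g$calls[, pairs[k, 1]], g$calls[, pairs[k, 2]])
    if (sum(n) < min_lines) next
    st <- dprime_from_freqs(n / sum(n))
    if (is.na(st$r2)) next
    r2[k] <- st$r2
    keep[k] <- TRUE
  }
  data.frame(distance_bp = pairs[keep, 3], r2 = r2[keep])
}

intra_pairs <- function(map, max_dist_bp) {
  out <- vector("list", length(unique(map$chrom)))
  z <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    pos <- map$pos[idx]
    for (a in seq_along(idx)[-length(idx)]) {
      b <- which(pos > pos[a] & pos - pos[a] <= max_dist_bp)
      b <- b[b > a]
      if (!length(b)) next
      z <- z + 1L
      out[[z]] <- cbind(idx[a], idx[b], pos[b] - pos[a])
    }
  }
  m <- do.call(rbind, out[seq_len(z)])
  if (is.null(m)) m <- matrix(numeric(0), 0, 3)
  colnames(m) <- c("i", "j", "dist")
  m
}

#' LOESS LD-decay curve and decay distance
#'
#' Fits a degree-2 LOESS of r2 on physical distance over pooled
#' intrachromosomal pairs, evaluates it on a log-spaced grid, and reports the
#' distance where the fitted curve first crosses the baseline r2 (default
#' 0.1), linearly interpolated. \code{fit_ld_decay} does the same from a
#' precomputed (distance, r2) scatter.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param max_dist_bp maximum pair distance considered.
#' @param sample_pairs optional cap on pairs used.
#' @param seed RNG seed for pair down-sampling.
#' @param baseline baseline r2 whose first crossing defines LD decay.
#' @param span LOESS span.
#' @param grid_n number of log-spaced evaluation points.
#' @return list of class \code{ld_decay}: \code{curve} (data.frame
#'   distance_bp, r2), \code{decay_distance_bp} (NA when the curve never
#'   crosses the baseline), \code{baseline}, \code{n_pairs}.
#' @export
ld_decay <- function(g, max_dist_bp = 10e6, sample_pairs = 50000L, seed = 1L,
                     baseline = 0.1, span = 0.5, grid_n = 512L) {
  sc <- ld_pair_scatter(g, max_dist_bp, sample_pairs, seed)
  if (nrow(sc) < 100) stop("need >= 100 intrachromosomal pairs, got ", nrow(sc))
  fit_ld_decay(sc$distance_bp, sc$r2, baseline = baseline, span = span,
               grid_n = grid_n)
}

#' @rdname ld_decay
#' @param distance_bp,r2 the pair scatter.
#' @export
fit_ld_decay <- function(distance_bp, r2, baseline = 0.1, span = 0.5,
                         grid_n = 512L) {
  ok <- is.finite(distance_bp) & is.finite(r2) & distance_bp > 0
  distance_bp <- distance_bp[ok]
  r2 <- r2[ok]
  fit <- stats::loess(r2 ~ distance_bp, degree = 2, span = span,
                      family = "gaussian",
                      control = stats::loess.control(surface = "interpolate"))
  grid <- exp(seq(log(max(min(distance_bp), 1) * (1 + 1e-9)),
                  log(max(distance_bp) * (1 - 1e-9)), length.out = grid_n))
  yhat <- pmin(pmax(stats::predict(fit, newdata = data.frame(distance_bp = grid)), 0), 1)
  if (anyNA(yhat)) {       # boundary points the surface cannot interpolate
    keep <- !is.na(yhat)
    grid <- grid[keep]
    yhat <- yhat[keep]
  }
  below <- which(yhat < baseline)
  decay <- NA_real_
  if (length(below)) {
    k <- below[1]
    if (k == 1L) {
      decay <- grid[1]
    } else {
      ## linear interpolation between the bracketing grid points
      x0 <- grid[k - 1]; x1 <- grid[k]
      y0 <- yhat[k - 1]; y1 <- yhat[k]
      decay <- x0 + (baseline - y0) * (x1 - x0) / (y1 - y0)
    }
  }
  structure(list(curve = data.frame(distance_bp = grid, r2 = unname(yhat)),
                 decay_distance_bp = unname(decay), baseline = baseline,
                 n_pairs = length(r2)),
            class = "ld_decay")
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay over", x$n_pairs, "pairs: ")
  if (is.na(x$decay_distance_bp)) {
    cat("curve never crosses baseline r2 =", x$baseline, "\n")
  } else {
    cat(sprintf("crosses r2 = %.2f at %.2f Mb\n", x$baseline,
                x$decay_distance_bp / 1e6))
  }
  invisible(x)
}
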