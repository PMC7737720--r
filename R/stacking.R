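## Favorable-haplotype stacking: per-line carrier matrices (heat-map input),
## additive grain-yield trend over the number of favorable haplotypes
## carried, and favorable-allele frequency trajectories across trial cohorts.

#' Favorable-haplotype indicator matrix
#'
#' Lines x stable-blocks matrix: 1 when the line carries the primary
#' favorable allele, 2 when it carries a secondary favorable allele, 0
#' otherwise, NA when the haplotype call is missing. This is the heat-map
#' matrix (dark green / light green / yellow).
#'
#' @param hg a \code{haplotype_genotypes} object (or lines x blocks matrix of
#'   allele pattern strings / indices).
#' @param stable data.frame with columns \code{block_id} and
#'   \code{favorable}; \code{favorable} holds allele labels, "+"-separated
#'   when secondary favorable alleles exist (primary first), as produced by
#'   \code{\link{assoc_scan}}.
#' @return integer matrix, lines x stable blocks.
#' @export
favorable_matrix <- function(hg, stable) {
  calls <- if (inherits(hg, "haplotype_genotypes")) hg$calls else as.matrix(hg)
  stopifnot(all(c("block_id", "favorable") %in% names(stable)))
  miss <- setdiff(stable$block_id, colnames(calls))
  if (length(miss)) stop("blocks not in haplotype genotypes: ",
                         paste(miss, collapse = ", "))
  out <- matrix(NA_integer_, nrow(calls), nrow(stable),
                dimnames = list(rownames(calls), stable$block_id))
  for (k in seq_len(nrow(stable))) {
    fav <- strsplit(as.character(stable$favorable[k]), "+", fixed = TRUE)[[1]]
    v <- as.character(calls[, stable$block_id[k]])
    ind <- rep(NA_integer_, length(v))
    ok <- !is.na(v)
    ind[ok] <- 0L
    ind[ok & v %in% fav[-1]] <- 2L
    ind[ok & v == fav[1]] <- 1L
    out[, k] <- ind
  }
  out
}

#' Stacking profile: favorable-haplotype counts per line
#'
#' Counts, per line, the stable blocks at which it carries a favorable allele
#' (primary or secondary). Missing calls contribute neither 0 nor 1; lines
#' with fewer than \code{min_called_frac} of blocks called get count NA.
#'
#' @param fav matrix from \code{\link{favorable_matrix}}.
#' @param min_called_frac completeness filter (0 disables it).
#' @return integer vector of counts, NA for filtered lines.
#' @export
stacking_counts <- function(fav, min_called_frac = 0) {
  counts <- rowSums(fav > 0, na.rm = TRUE)
  called <- rowMeans(!is.na(fav))
  counts[called < min_called_frac] <- NA_integer_
  as.integer(counts)
}

#' Additive trend of yield over favorable-haplotype count
#'
#' Mean trait value per count class, the percent increase from the lowest to
#' the highest populated class, and the ordinary-least-squares slope of trait
#' on count with its P-value. With fewer than 3 populated count classes the
#' trend is undefined (NA) and only class means are returned.
#'
#' @param counts favorable-haplotype counts (\code{\link{stacking_counts}}).
#' @param y trait vector aligned to \code{counts} (e.g. adjusted GY, kg/ha).
#' @return list of class \code{stacking_trend}: \code{class_means}
#'   (data.frame count, mean, n), \code{pct_increase}, \code{slope},
#'   \code{slope_p}, \code{n}.
#' @export
additive_trend <- function(counts, y) {
  ok <- !is.na(counts) & !is.na(y)
  counts <- counts[ok]
  y <- y[ok]
  cm <- stats::aggregate(y, by = list(count = counts), FUN = mean)
  names(cm)[2] <- "mean"
  cm$n <- as.integer(table(counts)[as.character(cm$count)])
  cm <- cm[order(cm$count), ]
  rownames(cm) <- NULL
  out <- list(class_means = cm, pct_increase = NA_real_, slope = NA_real_,
              slope_p = NA_real_, n = length(y))
  if (nrow(cm) >= 3) {
    lo <- cm$mean[1]
    hi <- cm$mean[nrow(cm)]
    out$pct_increase <- 100 * (hi - lo) / lo
    fit <- stats::lm(y ~ counts)
    sm <- summary(fit)$coefficients
    out$slope <- sm["counts", "Estimate"]
    out$slope_p <- sm["counts", "Pr(>|t|)"]
  }
  structure(out, class = "stacking_trend")
}

#' @export
print.stacking_trend <- function(x, ...) {
  cat("additive stacking trend over", nrow(x$class_means), "count classes:\n")
  if (is.na(x$slope)) {
    cat("  undefined (< 3 populated classes)\n")
  } else {
    cat(sprintf("  slope = %.1f per haplotype (P = %.3g), %.1f%% increase low -> high\n",
                x$slope, x$slope_p, x$pct_increase))
  }
  invisible(x)
}

#' Favorable-allele frequency trajectories across cohorts
#'
#' Frequency of each stable block's favorable allele among non-missing calls,
#' per cohort (EYT), with a flag for blocks whose frequency declines
#' monotonically by more than \code{delta} from first to last cohort.
#'
#' @param hg a \code{haplotype_genotypes} object or allele-call matrix.
#' @param stable data.frame(block_id, favorable) as in
#'   \code{\link{favorable_matrix}}.
#' @param cohort cohort label per line (coerced to factor; level order =
#'   cohort order).
#' @param delta decline magnitude that triggers the flag.
#' @param tol tolerated per-step increase when judging monotonicity.
#' @return list: \code{freq} (blocks x cohorts matrix), \code{declining}
#'   (named logical).
#' @export
haplotype_frequency_trajectory <- function(hg, stable, cohort, delta = 0.10,
                                           tol = 0) {
  fav <- favorable_matrix(hg, stable)
  cohort <- factor(cohort)
  freq <- sapply(levels(cohort), function(ch) {
    colMeans(fav[cohort == ch, , drop = FALSE] > 0, na.rm = TRUE)
  })
  freq <- matrix(freq, nrow = ncol(fav),
                 dimnames = list(colnames(fav), levels(cohort)))
  declining <- apply(freq, 1, function(f) {
    f <- f[is.finite(f)]
    if (length(f) < 2) return(FALSE)
    all(diff(f) <= tol) && (f[1] - f[length(f)]) > delta
  })
  list(freq = freq, declining = declining)
}
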