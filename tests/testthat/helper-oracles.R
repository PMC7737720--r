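## Shared fixtures and independent oracles used across the suite.

## genotype matrix with exact two-locus haplotype counts (inbred coding)
two_locus_genotypes <- function(n_AB, n_Ab, n_aB, n_ab, pos = c(1e6, 2e6),
                                chrom = "1A") {
  calls <- cbind(c(rep(0L, n_AB + n_Ab), rep(2L, n_aB + n_ab)),
                 c(rep(0L, n_AB), rep(2L, n_Ab), rep(0L, n_aB), rep(2L, n_ab)))
  genotype_matrix(calls, map = data.frame(marker = c("mA", "mB"),
                                          chrom = chrom, pos = pos))
}

## independent dense-grid oracle for the |D'| likelihood CI, written straight
## from the multinomial definition (loop form, no shared code path)
dense_ci_oracle <- function(counts, step = 1e-4) {
  nt <- sum(counts)
  pA <- (counts[1] + counts[2]) / nt
  pB <- (counts[1] + counts[3]) / nt
  D_obs <- counts[1] / nt - pA * pB
  s <- if (D_obs >= 0) 1 else -1
  dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  grid <- seq(0, 1, by = step)
  ll <- sapply(grid, function(d) {
    pr <- c(pA * pB + s * d * dmax,
            pA * (1 - pB) - s * d * dmax,
            (1 - pA) * pB - s * d * dmax,
            (1 - pA) * (1 - pB) + s * d * dmax)
    pr[pr < 0 & pr > -1e-12] <- 0
    tot <- 0
    for (k in 1:4) {
      if (counts[k] == 0) next
      if (pr[k] <= 0) return(-Inf)
      tot <- tot + counts[k] * log(pr[k])
    }
    tot
  })
  lik <- exp(ll - max(ll))
  cum <- cumsum(lik) / sum(lik)
  c(grid[which(cum >= 0.05)[1]], grid[which(cum >= 0.95)[1]])
}

## exhaustive block-finder oracle: enumerate every contiguous interval,
## apply rules (i) outer pair strong LD and (ii) >= strong_frac of
## informative comparisons strong, then the same deterministic greedy
## selection. Classification of pairs is delegated to pair_ld (tested
## separately); the interval logic here is independent of find_blocks.
bf_find_blocks <- function(g, params = ld_params(), max_span_bp = 10e6,
                           strong_frac = 0.95, min_informative = 1L,
                           min_lines = 4L) {
  out <- list()
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    m <- length(idx)
    if (m < 2) next
    pos <- g$map$pos[idx]
    cls <- matrix(NA_character_, m, m)
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        if (pos[b] - pos[a] > max_span_bp) next
        p <- tryCatch(pair_ld(g, idx[a], idx[b], params),
                      error = function(e) NULL)
        if (!is.null(p) && !is.na(p$classification))
          cls[a, b] <- p$classification
      }
    }
    cand <- list()
    for (a in seq_len(m - 1)) {
      for (b in (a + 1):m) {
        if (pos[b] - pos[a] > max_span_bp) next
        if (is.na(cls[a, b]) || cls[a, b] != "strong_LD") next
        n_strong <- 0L
        n_inf <- 0L
        for (i in a:(b - 1)) {
          for (j in (i + 1):b) {
            if (is.na(cls[i, j])) next
            if (cls[i, j] == "strong_LD") {
              n_strong <- n_strong + 1L
              n_inf <- n_inf + 1L
            } else if (cls[i, j] == "strong_recombination") {
              n_inf <- n_inf + 1L
            }
          }
        }
        if (n_inf >= min_informative && n_strong / n_inf >= strong_frac)
          cand[[length(cand) + 1L]] <- c(a, b)
      }
    }
    if (length(cand)) {
      cm <- do.call(rbind, cand)
      nsnp <- cm[, 2] - cm[, 1] + 1L
      span <- pos[cm[, 2]] - pos[cm[, 1]]
      ord <- order(-nsnp, -span, cm[, 1])
      cm <- cm[ord, , drop = FALSE]
      used <- rep(FALSE, m)
      for (k in seq_len(nrow(cm))) {
        rng <- cm[k, 1]:cm[k, 2]
        if (!any(used[rng])) {
          used[rng] <- TRUE
          out[[length(out) + 1L]] <- list(chrom = ch, a = cm[k, 1],
                                          b = cm[k, 2],
                                          markers = g$map$marker[idx[rng]])
        }
      }
    }
  }
  out
}

## compact signature of a block list for equality comparison
block_signature <- function(blocks) {
  sig <- vapply(blocks, function(b) paste(b$markers, collapse = ","), "")
  sort(sig)
}

## random small genotype instance with mixed LD structure: a handful of
## founder haplotypes plus independent mutation noise
random_block_instance <- function(seed, max_snps = 8L) {
  set.seed(seed)
  m <- sample(2:max_snps, 1)
  n <- sample(c(40L, 60L, 80L), 1)
  nf <- sample(2:5, 1)
  founders <- matrix(sample(c(0L, 2L), nf * m, replace = TRUE), nf, m)
  calls <- founders[sample.int(nf, n, replace = TRUE), , drop = FALSE]
  noise <- matrix(stats::runif(n * m) < stats::runif(1, 0, 0.4), n, m)
  calls[noise] <- sample(c(0L, 2L), sum(noise), replace = TRUE)
  if (stats::runif(1) < 0.3) {
    calls[stats::runif(length(calls)) < 0.05] <- NA_integer_
  }
  pos <- sort(sample.int(5e6, m))
  genotype_matrix(calls, map = data.frame(
    marker = paste0("s", seq_len(m)), chrom = "1A", pos = pos))
}

## small multi-environment trial table with known entry effects
toy_trial_table <- function(n_entries = 30, envs = c("I", "SD"), reps = 2,
                            sigma_g = 1, sigma_e = 1, seed = 1) {
  set.seed(seed)
  gval <- stats::rnorm(n_entries, 0, sigma_g)
  df <- expand.grid(entry = paste0("E", seq_len(n_entries)), env = envs,
                    rep = seq_len(reps), KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  df$value <- gval[match(df$entry, paste0("E", seq_len(n_entries)))] +
    stats::rnorm(nrow(df), 0, sigma_e)
  list(df = df, gval = gval)
}
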