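## Confidence-interval haplotype block construction (Gabriel-style) and
## recoding of blocks as multiallelic markers.

## pair classification codes used internally by the block finder
CLS_STRONG <- 1L
CLS_RECOMB <- 2L
CLS_INCONC <- 3L

## classification matrix for one chromosome: m x m, upper triangle filled for
## pairs within max_span_bp; NA = out of window or unusable (too few
## informative lines / monomorphic after exclusions).
classify_chrom_pairs <- function(calls, pos, params, max_span_bp,
                                 min_lines = 4L) {
  m <- length(pos)
  cls <- matrix(NA_integer_, m, m)
  if (m < 2) return(cls)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      if (pos[b] - pos[a] > max_span_bp) break
      n <- hap_counts(calls[, a], calls[, b])
      nt <- sum(n)
      if (nt < min_lines) next
      pA <- (n[1] + n[2]) / nt
      pB <- (n[1] + n[3]) / nt
      if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) next
      ci <- dprime_ci(n, grid_step = params$grid_step)
      cls[a, b] <- switch(classify_pair(ci[1], ci[2], params),
                          strong_LD = CLS_STRONG,
                          strong_recombination = CLS_RECOMB,
                          inconclusive = CLS_INCONC)
    }
  }
  cls
}

#' Find haplotype blocks by the D' confidence-interval method
#'
#' A contiguous marker interval [a, b] is a candidate block when (i) its
#' outermost pair is in strong LD and (ii) at least \code{strong_frac} (95\%
#' by default) of the informative pairwise comparisons inside it are in
#' strong LD. Informative comparisons are those classified strong LD or
#' strong recombination; inconclusive pairs are excluded from the denominator
#' (set \code{informative_only = FALSE} to count them). Candidates are then
#' accepted greedily — most SNPs first, then widest span, then leftmost start
#' — discarding any candidate overlapping an accepted block.
#'
#' @param g a \code{\link{genotype_matrix}} (markers sorted by position;
#'   typically already filtered).
#' @param params an \code{\link{ld_params}} with the CI classification bounds.
#' @param max_span_bp maximum block span considered (default 10 Mb).
#' @param strong_frac required fraction of strong-LD comparisons.
#' @param min_informative minimum informative comparisons per candidate.
#' @param informative_only exclude inconclusive pairs from the denominator.
#' @param min_lines minimum informative lines per pair.
#' @return object of class \code{haplotype_blocks}: a list of blocks, each
#'   with \code{block_id} ("HB<chrom>.<ordinal>"), \code{chrom},
#'   \code{marker_idx} (indices into \code{g}), \code{markers},
#'   \code{start_bp}, \code{end_bp}, \code{span_bp}, \code{n_snps}.
#'   Chromosomes with < 2 markers contribute no blocks.
#' @export
find_blocks <- function(g, params = ld_params(), max_span_bp = 10e6,
                        strong_frac = 0.95, min_informative = 1L,
                        informative_only = TRUE, min_lines = 4L) {
  blocks <- list()
  for (ch in unique(g$map$chrom)) {
    idx <- which(g$map$chrom == ch)
    if (length(idx) < 2) next
    pos <- g$map$pos[idx]
    cls <- classify_chrom_pairs(g$calls[, idx, drop = FALSE], pos, params,
                                max_span_bp, min_lines)
    cand <- enumerate_candidates(cls, pos, max_span_bp, strong_frac,
                                 min_informative, informative_only)
    sel <- greedy_select(cand)
    if (nrow(sel)) {
      sel <- sel[order(sel[, 1]), , drop = FALSE]
      for (k in seq_len(nrow(sel))) {
        a <- unname(sel[k, 1]); b <- unname(sel[k, 2])
        blocks[[length(blocks) + 1L]] <- list(
          block_id = paste0("HB", ch, ".", k),
          chrom = ch,
          marker_idx = idx[a:b],
          markers = g$map$marker[idx[a:b]],
          start_bp = pos[a], end_bp = pos[b],
          span_bp = pos[b] - pos[a],
          n_snps = b - a + 1L)
      }
    }
  }
  structure(blocks, class = "haplotype_blocks")
}

## all candidate intervals under rules (i) + (ii), as a matrix
## (a, b, n_snps, span); counts maintained incrementally while b grows.
enumerate_candidates <- function(cls, pos, max_span_bp, strong_frac,
                                 min_informative, informative_only) {
  m <- length(pos)
  out <- vector("list", m)
  for (a in seq_len(max(m - 1L, 0L))) {
    n_strong <- 0L
    n_denom <- 0L
    rows <- list()
    for (b in (a + 1L):m) {
      if (b > m || pos[b] - pos[a] > max_span_bp) break
      new <- cls[a:(b - 1L), b]
      n_strong <- n_strong + sum(new == CLS_STRONG, na.rm = TRUE)
      n_denom <- n_denom + if (informative_only)
        sum(new == CLS_STRONG | new == CLS_RECOMB, na.rm = TRUE)
      else sum(!is.na(new))
      if (!is.na(cls[a, b]) && cls[a, b] == CLS_STRONG &&
          n_denom >= min_informative &&
          n_strong / n_denom >= strong_frac) {
        rows[[length(rows) + 1L]] <- c(a, b, b - a + 1L, pos[b] - pos[a])
      }
    }
    if (length(rows)) out[[a]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- matrix(numeric(0), 0, 4)
  colnames(res) <- c("a", "b", "n_snps", "span")
  res
}

## greedy, deterministic: n_snps desc, span desc, leftmost start; no shared
## markers between accepted blocks.
greedy_select <- function(cand) {
  if (nrow(cand) == 0) return(cand)
  ord <- order(-cand[, "n_snps"], -cand[, "span"], cand[, "a"])
  cand <- cand[ord, , drop = FALSE]
  used <- logical(max(cand[, "b"]))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    rng <- cand[k, "a"]:cand[k, "b"]
    if (!any(used[rng])) {
      keep[k] <- TRUE
      used[rng] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  cat("haplotype_blocks:", length(x), "block(s)\n")
  if (length(x)) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @export
as.data.frame.haplotype_blocks <- function(x, ...) {
  if (!length(x)) {
    return(data.frame(block_id = character(), chrom = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      span_bp = numeric(), n_snps = integer(),
                      markers = character()))
  }
  data.frame(block_id = vapply(x, `[[`, "", "block_id"),
             chrom = vapply(x, `[[`, "", "chrom"),
             start_bp = vapply(x, `[[`, 0, "start_bp"),
             end_bp = vapply(x, `[[`, 0, "end_bp"),
             span_bp = vapply(x, `[[`, 0, "span_bp"),
             n_snps = vapply(x, function(b) as.integer(b$n_snps), 0L),
             markers = vapply(x, function(b) paste(b$markers, collapse = ","), ""))
}

#' Call multiallelic haplotype alleles for one block
#'
#' Each line's haplotype allele is the concatenation of its homozygous calls
#' across the member SNPs ("A" = major homozygote, "B" = minor homozygote);
#' a heterozygous or missing call at any member SNP makes the whole haplotype
#' missing. Alleles with frequency below \code{min_allele_freq} (among called
#' lines) are recoded missing and excluded from the catalogue.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param block one block from \code{\link{find_blocks}}.
#' @param min_allele_freq minimum allele frequency to catalogue.
#' @return list: \code{calls} (integer allele index per line, NA = missing),
#'   \code{alleles} (pattern strings, frequency-sorted), \code{freqs}
#'   (frequency among called lines, before rare-allele drop), \code{counts},
#'   \code{n_called}.
#' @export
call_haplotype_alleles <- function(g, block, min_allele_freq = 0.05) {
  sub <- g$calls[, block$marker_idx, drop = FALSE]
  ok <- rowSums(sub == 0L | sub == 2L, na.rm = TRUE) == ncol(sub)
  pat <- rep(NA_character_, nrow(sub))
  if (any(ok)) {
    letters_ <- matrix("A", sum(ok), ncol(sub))
    letters_[sub[ok, , drop = FALSE] == 2L] <- "B"
    pat[ok] <- apply(letters_, 1, paste, collapse = "")
  } else {
    warning("block ", block$block_id, ": no line has a complete haplotype call")
    return(list(calls = rep(NA_integer_, nrow(sub)), alleles = character(),
                freqs = numeric(), counts = integer(), n_called = 0L))
  }
  n_called <- sum(ok)
  tab <- sort(table(pat[ok]), decreasing = TRUE)
  ## deterministic tie-break: frequency desc, then pattern lexicographic
  tab <- tab[order(-as.integer(tab), names(tab))]
  freqs <- as.numeric(tab) / max(n_called, 1L)
  keep <- freqs >= min_allele_freq
  alleles <- names(tab)[keep]
  calls <- match(pat, alleles)
  list(calls = as.integer(calls), alleles = alleles,
       freqs = freqs[keep], counts = as.integer(tab)[keep],
       n_called = n_called)
}

#' Recode all blocks as multiallelic markers
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param blocks a \code{haplotype_blocks} object.
#' @param min_allele_freq minimum allele frequency to catalogue.
#' @return object of class \code{haplotype_genotypes}: \code{calls} (lines x
#'   blocks integer matrix of allele indices, NA = missing), \code{blocks}
#'   (block list with \code{alleles}/\code{freqs} attached),
#'   \code{block_ids}.
#' @export
build_haplotype_genotypes <- function(g, blocks, min_allele_freq = 0.05) {
  ids <- vapply(blocks, `[[`, "", "block_id")
  calls <- matrix(NA_integer_, n_lines(g), length(blocks),
                  dimnames = list(rownames(g$calls), ids))
  blk <- unclass(blocks)
  for (k in seq_along(blocks)) {
    hc <- call_haplotype_alleles(g, blocks[[k]], min_allele_freq)
    calls[, k] <- hc$calls
    blk[[k]]$alleles <- hc$alleles
    blk[[k]]$allele_freqs <- hc$freqs
    blk[[k]]$allele_counts <- hc$counts
    blk[[k]]$n_called <- hc$n_called
  }
  structure(list(calls = calls, blocks = structure(blk, class = "haplotype_blocks"),
                 block_ids = ids),
            class = "haplotype_genotypes")
}

#' @export
print.haplotype_genotypes <- function(x, ...) {
  cat("haplotype_genotypes:", nrow(x$calls), "lines x", ncol(x$calls),
      "blocks\n")
  invisible(x)
}

#' Genome coverage spanned by the marker map
#'
#' Span per chromosome = position of last SNP minus position of first SNP,
#' reported in Mb, with subgenome subtotals (by trailing A/B/D letter of the
#' chromosome label, when present) and a genome total.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @return list: \code{per_chrom} (chrom, n_markers, first_bp, last_bp,
#'   span_mb), \code{per_subgenome} (subgenome, span_mb), \code{total_mb}.
#' @export
genome_coverage <- function(g) {
  chroms <- unique(g$map$chrom)
  per <- do.call(rbind, lapply(chroms, function(ch) {
    pos <- g$map$pos[g$map$chrom == ch]
    data.frame(chrom = ch, n_markers = length(pos),
               first_bp = min(pos), last_bp = max(pos),
               span_mb = if (length(pos) >= 2) (max(pos) - min(pos)) / 1e6 else 0)
  }))
  sg <- toupper(substring(per$chrom, nchar(per$chrom)))
  sg[!sg %in% c("A", "B", "D")] <- NA_character_
  per_sub <- if (all(is.na(sg))) {
    data.frame(subgenome = character(), span_mb = numeric())
  } else {
    stats::aggregate(span_mb ~ subgenome,
                     data = data.frame(subgenome = sg, span_mb = per$span_mb),
                     FUN = sum)
  }
  list(per_chrom = per, per_subgenome = per_sub, total_mb = sum(per$span_mb))
}
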