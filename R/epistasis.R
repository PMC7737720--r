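## Two- and three-locus epistasis scans over multiallelic haplotype blocks,
## by ordinary linear regression: the interaction term group is F-tested
## beyond all lower-order terms and its incremental (partial) R2 is the
## variance it explains over the total sum of squares.

## pool interaction cells with fewer than min_cell lines into one level;
## returns NULL when fewer than 2 usable cells remain
pool_cells <- function(f, min_cell) {
  tab <- table(f)
  usable <- names(tab)[tab >= min_cell]
  if (length(usable) < 2) return(NULL)
  lev <- as.character(f)
  lev[!lev %in% usable] <- ".pooled"
  factor(lev)
}

## rank-aware F-test of the columns of X_extra beyond X_base
fit_increment <- function(X_base, X_extra, y) {
  f0 <- stats::lm.fit(X_base, y)
  f1 <- stats::lm.fit(cbind(X_base, X_extra), y)
  df1 <- f1$rank - f0$rank
  df2 <- length(y) - f1$rank
  if (df1 < 1 || df2 < 1) return(NULL)
  rss0 <- sum(f0$residuals^2)
  rss1 <- sum(f1$residuals^2)
  tss <- sum((y - mean(y))^2)
  Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  if (!is.finite(Fstat) || Fstat < 0) Fstat <- 0
  list(p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       partial_r2 = if (tss > 0) max(0, (rss0 - rss1) / tss) else 0,
       F = Fstat, df1 = df1, df2 = df2)
}

## marginal allele factor after class-size floor; NULL if < 2 classes
block_factor <- function(hap, min_class) {
  hap <- floor_classes(hap, min_class)
  f <- factor(hap)
  if (nlevels(f) < 2) return(NULL)
  f
}

#' Pairwise epistasis scan
#'
#' For each block pair, fits the main-effects model (allele dummies of both
#' blocks) and the full model adding all pairwise interaction dummies, and
#' reports the interaction-group F-test P-value and partial R2 =
#' (RSS_main - RSS_full)/TSS (percentage scale). Interaction cells with fewer
#' than \code{min_cell} lines are pooled into one level; pairs with fewer
#' than 2 usable cells, or whose interaction columns are fully aliased with
#' the main effects, are skipped. Complete cases per pair.
#'
#' @param hg a \code{haplotype_genotypes} object (or a plain lines x blocks
#'   matrix of allele calls).
#' @param y phenotype vector aligned to lines (adjusted trait values for one
#'   trial x environment).
#' @param pairs optional 2-column matrix of block indices or ids; default all
#'   pairs.
#' @param alpha report only interactions with P < alpha (default 1e-4); NULL
#'   returns every tested pair.
#' @param min_class minimum lines per marginal allele class.
#' @param min_cell minimum lines per interaction cell.
#' @param min_n minimum complete-case lines per pair.
#' @param trial,env labels carried into the result.
#' @return data.frame(block_a, block_b, trial, env, partial_r2_pct, p_value,
#'   n_lines).
#' @export
pairwise_scan <- function(hg, y, pairs = NULL, alpha = 1e-4, min_class = 10L,
                          min_cell = 5L, min_n = 30L,
                          trial = NA_character_, env = NA_character_) {
  calls <- if (inherits(hg, "haplotype_genotypes")) hg$calls else as.matrix(hg)
  ids <- colnames(calls)
  if (is.null(ids)) ids <- paste0("B", seq_len(ncol(calls)))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ncol(calls), 2))
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) pairs <- matrix(match(pairs, ids), ncol = 2)
  }
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ok <- !is.na(calls[, i]) & !is.na(calls[, j]) & !is.na(y)
    if (sum(ok) < min_n) next
    fa <- block_factor(calls[ok, i], min_class)
    fb <- block_factor(calls[ok, j], min_class)
    if (is.null(fa) || is.null(fb)) next
    use <- !is.na(fa) & !is.na(fb)
    fa <- droplevels(fa[use]); fb <- droplevels(fb[use])
    if (nlevels(fa) < 2 || nlevels(fb) < 2) next
    yk <- y[ok][use]
    fab <- pool_cells(interaction(fa, fb, drop = TRUE), min_cell)
    if (is.null(fab)) next
    X_main <- stats::model.matrix(~ fa + fb)
    X_int <- stats::model.matrix(~fab)[, -1, drop = FALSE]
    ft <- fit_increment(X_main, X_int, yk)
    if (is.null(ft)) next
    rows[[k]] <- data.frame(block_a = ids[i], block_b = ids[j],
                            trial = trial, env = env,
                            partial_r2_pct = 100 * ft$partial_r2,
                            p_value = ft$p, n_lines = length(yk))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(block_a = character(), block_b = character(),
                      trial = character(), env = character(),
                      partial_r2_pct = numeric(), p_value = numeric(),
                      n_lines = integer())
  }
  if (!is.null(alpha)) out <- out[out$p_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Three-locus epistasis scan over candidate triples
#'
#' The reduced model carries all main effects and all two-way interaction
#' dummies of the three blocks; the full model adds the three-way interaction
#' cells (pooled below \code{min_cell} lines). Reported P and partial R2 are
#' for the three-way group beyond all lower-order terms.
#'
#' @param hg a \code{haplotype_genotypes} object or allele-call matrix.
#' @param y phenotype vector aligned to lines.
#' @param triples 3-column matrix of block indices or ids (candidate set;
#'   exhaustive three-way scans are deliberately not offered).
#' @param alpha report threshold (NULL = all tested triples).
#' @inheritParams pairwise_scan
#' @return data.frame(block_a, block_b, block_c, trial, env, partial_r2_pct,
#'   p_value, n_lines).
#' @export
threeway_scan <- function(hg, y, triples, alpha = 1e-4, min_class = 10L,
                          min_cell = 5L, min_n = 30L,
                          trial = NA_character_, env = NA_character_) {
  calls <- if (inherits(hg, "haplotype_genotypes")) hg$calls else as.matrix(hg)
  ids <- colnames(calls)
  if (is.null(ids)) ids <- paste0("B", seq_len(ncol(calls)))
  triples <- as.matrix(triples)
  if (is.character(triples)) triples <- matrix(match(triples, ids), ncol = 3)
  rows <- vector("list", nrow(triples))
  for (k in seq_len(nrow(triples))) {
    idx <- triples[k, ]
    ok <- !is.na(y) & rowSums(is.na(calls[, idx, drop = FALSE])) == 0
    if (sum(ok) < min_n) next
    fs <- lapply(idx, function(i) block_factor(calls[ok, i], min_class))
    if (any(vapply(fs, is.null, TRUE))) next
    use <- !is.na(fs[[1]]) & !is.na(fs[[2]]) & !is.na(fs[[3]])
    fs <- lapply(fs, function(f) droplevels(f[use]))
    if (any(vapply(fs, nlevels, 0L) < 2)) next
    yk <- y[ok][use]
    fabc <- pool_cells(interaction(fs[[1]], fs[[2]], fs[[3]], drop = TRUE),
                       min_cell)
    if (is.null(fabc)) next
    d <- data.frame(fa = fs[[1]], fb = fs[[2]], fc = fs[[3]])
    X_red <- stats::model.matrix(~ fa * fb + fa * fc + fb * fc, data = d)
    X_full <- stats::model.matrix(~fabc)[, -1, drop = FALSE]
    ft <- fit_increment(X_red, X_full, yk)
    if (is.null(ft)) next
    rows[[k]] <- data.frame(block_a = ids[idx[1]], block_b = ids[idx[2]],
                            block_c = ids[idx[3]], trial = trial, env = env,
                            partial_r2_pct = 100 * ft$partial_r2,
                            p_value = ft$p, n_lines = length(yk))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(block_a = character(), block_b = character(),
                      block_c = character(), trial = character(),
                      env = character(), partial_r2_pct = numeric(),
                      p_value = numeric(), n_lines = integer())
  }
  if (!is.null(alpha)) out <- out[out$p_value < alpha, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate triples for the three-way scan
#'
#' Triples among blocks that either pass a marginal association threshold or
#' belong to a significant pair — the cost-control set for
#' \code{\link{threeway_scan}}.
#'
#' @param assoc association data.frame (block_id, p_value) for the same
#'   trial x environment.
#' @param pairs significant pair data.frame from \code{\link{pairwise_scan}}.
#' @param marginal_p marginal inclusion threshold (default 0.01).
#' @param max_triples hard cap on the number of triples returned.
#' @return character matrix with 3 columns of block ids (0 rows when fewer
#'   than 3 candidate blocks exist).
#' @export
candidate_triples <- function(assoc, pairs = NULL, marginal_p = 0.01,
                              max_triples = 1e5) {
  cand <- unique(assoc$block_id[!is.na(assoc$p_value) &
                                  assoc$p_value < marginal_p])
  if (!is.null(pairs) && nrow(pairs)) {
    cand <- unique(c(cand, pairs$block_a, pairs$block_b))
  }
  if (length(cand) < 3) return(matrix(character(0), 0, 3))
  tri <- t(utils::combn(sort(cand), 3))
  if (nrow(tri) > max_triples) tri <- tri[seq_len(max_triples), , drop = FALSE]
  tri
}
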