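#' Construct a genotype matrix for inbred lines
#'
#' The central genotype container: a lines x markers matrix of allele-dose
#' codes together with a physical marker map. Codes are 0 (major-allele
#' homozygote), 2 (minor-allele homozygote), 1 (heterozygote) and \code{NA}
#' (missing). Lines are assumed to be advanced inbreds, so heterozygotes are
#' rare; they count as half a minor allele towards MAF and are treated as
#' missing when haplotype alleles are called.
#'
#' Markers are sorted by (chromosome, position). Markers sharing an identical
#' (chromosome, position) are deduplicated, keeping the copy with the lower
#' missing fraction.
#'
#' @param calls integer/numeric matrix, lines x markers, values in
#'   \{0, 1, 2, NA\}. Row names (line ids) and column names (marker ids) are
#'   used when \code{line_ids}/\code{map} are absent.
#' @param map data.frame with columns \code{marker}, \code{chrom}, \code{pos}
#'   (1-based bp), one row per column of \code{calls}.
#' @param line_ids character vector of unique line identifiers.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{calls} (integer matrix) and \code{map}.
#' @export
genotype_matrix <- function(calls, map, line_ids = rownames(calls)) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(calls)))
  line_ids <- as.character(line_ids)
  if (anyDuplicated(line_ids)) stop("duplicated line ids")
  if (missing(map) || is.null(map)) {
    mk <- colnames(calls)
    if (is.null(mk)) mk <- paste0("M", seq_len(ncol(calls)))
    map <- data.frame(marker = mk, chrom = "1", pos = seq_len(ncol(calls)))
  }
  map <- as.data.frame(map)
  need <- c("marker", "chrom", "pos")
  if (!all(need %in% names(map))) stop("map must have columns marker, chrom, pos")
  map <- map[need]
  map$marker <- as.character(map$marker)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (nrow(map) != ncol(calls)) stop("map rows must match calls columns")
  if (anyDuplicated(map$marker)) {
    stop("validation error: duplicated marker id(s): ",
         paste(unique(map$marker[duplicated(map$marker)])[1:3], collapse = ", "))
  }
  bad <- !(calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad, na.rm = TRUE)) stop("calls must be coded 0/1/2/NA")

  ## sort by chromosome then position
  ord <- order(map$chrom, map$pos)
  map <- map[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]

  ## dedup identical (chrom, pos): keep lowest missingness
  key <- paste(map$chrom, map$pos, sep = ":")
  if (anyDuplicated(key)) {
    miss <- colMeans(is.na(calls))
    keep <- rep(TRUE, length(key))
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      keep[idx] <- FALSE
      keep[idx[which.min(miss[idx])]] <- TRUE
    }
    message(sum(!keep), " duplicate-position marker(s) removed (kept lowest missingness)")
    map <- map[keep, , drop = FALSE]
    calls <- calls[, keep, drop = FALSE]
  }
  rownames(map) <- NULL
  dimnames(calls) <- list(line_ids, map$marker)
  structure(list(calls = calls, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "lines x", ncol(x$calls), "markers on",
      length(unique(x$map$chrom)), "chromosome(s)\n")
  cat(sprintf("  missing: %.1f%%  het: %.2f%%\n",
              100 * mean(is.na(x$calls)),
              100 * mean(x$calls == 1L, na.rm = TRUE)))
  invisible(x)
}

#' Number of lines / markers
#' @param g a \code{genotype_matrix}.
#' @return integer count.
#' @export
n_lines <- function(g) nrow(g$calls)

#' @rdname n_lines
#' @export
n_markers <- function(g) ncol(g$calls)

#' Per-marker minor allele frequency
#'
#' Allele-frequency convention: each homozygous minor call contributes two
#' minor alleles, each heterozygote one. Computed on non-missing calls only,
#' then folded so the result lies in [0, 0.5].
#'
#' @param g a \code{genotype_matrix}.
#' @return numeric vector, one MAF per marker (NaN for all-missing markers).
#' @export
marker_maf <- function(g) {
  f <- colMeans(g$calls, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Per-marker and per-line missing fractions
#' @param g a \code{genotype_matrix}.
#' @return numeric vector of missing-call fractions.
#' @export
marker_missing <- function(g) colMeans(is.na(g$calls))

#' @rdname marker_missing
#' @export
line_missing <- function(g) rowMeans(is.na(g$calls))

#' Subset a genotype matrix
#' @param g a \code{genotype_matrix}.
#' @param lines,markers logical/integer/character index into lines or markers.
#' @return a \code{genotype_matrix}.
#' @export
subset_genotypes <- function(g, lines = NULL, markers = NULL) {
  calls <- g$calls
  map <- g$map
  if (!is.null(markers)) {
    if (is.character(markers)) markers <- match(markers, map$marker)
    calls <- calls[, markers, drop = FALSE]
    map <- map[markers, , drop = FALSE]
    rownames(map) <- NULL
  }
  if (!is.null(lines)) calls <- calls[lines, , drop = FALSE]
  structure(list(calls = calls, map = map), class = "genotype_matrix")
}
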