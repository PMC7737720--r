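## Genotype file readers/writers and the marker / line filters.

IUPAC_HET <- c("R", "Y", "S", "W", "K", "M")
HAPMAP_META <- c("strand", "assembly#", "center", "protLSID", "assayLSID",
                 "panelLSID", "QCcode")

#' Read a genotype matrix
#'
#' Supported formats: HapMap tab-delimited (\code{rs#, alleles, chrom, pos},
#' optional standard metadata columns, then one column per line with IUPAC
#' single-letter or AA/AB/BB calls), VCF v4.x (diploid biallelic SNP records;
#' multiallelic records are skipped with a message), and the package's own
#' \code{matrix-csv} layout (columns \code{marker, chrom, pos} then one column
#' of 0/1/2/NA codes per line; \code{\link{write_genotypes_csv}} mirrors it).
#'
#' Calls are oriented per marker so that code 0 is the major-allele
#' homozygote (ties: the first-observed allele is called major).
#'
#' @param path file path.
#' @param format one of \code{"hapmap"}, \code{"vcf"}, \code{"matrix-csv"}.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("hapmap", "vcf", "matrix-csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         "hapmap" = read_hapmap(path),
         "vcf" = read_vcf_genotypes(path),
         "matrix-csv" = read_matrix_csv(path))
}

read_matrix_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                 error = function(e) stop("format error reading ", path, ": ",
                                          conditionMessage(e)))
  if (nrow(df) == 0) stop("format error: no records in ", path)
  if (!all(c("marker", "chrom", "pos") %in% names(df)[1:3]))
    stop("format error: first line must name columns marker, chrom, pos")
  calls <- t(as.matrix(df[, -(1:3), drop = FALSE]))
  genotype_matrix(calls,
                  map = data.frame(marker = df$marker, chrom = df$chrom,
                                   pos = df$pos),
                  line_ids = colnames(df)[-(1:3)])
}

#' Write a genotype matrix as matrix-csv
#' @param g a \code{genotype_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes_csv <- function(g, path) {
  df <- cbind(g$map, as.data.frame(t(g$calls), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

read_hapmap <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("format error: no records in ", path)
  header <- strsplit(first, "\t")[[1]]
  if (length(header) < 5 || header[1] != "rs#")
    stop("format error: line 1 is not a HapMap header (expected first column 'rs#')")
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", "N", "NN", "--", "-"))
  if (nrow(df) == 0) stop("format error: no records in ", path)
  skip <- 4 + sum(names(df)[5:min(11, ncol(df))] %in% HAPMAP_META)
  line_ids <- names(df)[-seq_len(skip)]
  if (length(line_ids) == 0) stop("format error: no sample columns in ", path)
  raw <- as.matrix(df[, -seq_len(skip), drop = FALSE])
  calls <- matrix(NA_integer_, nrow(raw), ncol(raw))
  alleles <- strsplit(as.character(df$alleles), "/", fixed = TRUE)
  for (m in seq_len(nrow(raw))) {
    al <- alleles[[m]]
    if (length(al) != 2) {
      stop("format error at line ", m + 1L,
           ": non-biallelic alleles field '", df$alleles[m], "'")
    }
    v <- raw[m, ]
    code <- rep(NA_integer_, length(v))
    two <- !is.na(v) & nchar(v) == 2L           # AA/AB/BB style
    one <- !is.na(v) & nchar(v) == 1L           # IUPAC style
    code[two & v == paste0(al[1], al[1])] <- 0L
    code[two & v == paste0(al[2], al[2])] <- 2L
    code[two & (v == paste0(al[1], al[2]) | v == paste0(al[2], al[1]))] <- 1L
    code[one & v == al[1]] <- 0L
    code[one & v == al[2]] <- 2L
    code[one & v %in% IUPAC_HET] <- 1L
    unknown <- !is.na(v) & is.na(code) & !(v %in% c("N", "NN"))
    if (any(unknown)) {
      stop("format error at line ", m + 1L, ": unrecognized call '",
           v[unknown][1], "' for marker ", df$`rs#`[m])
    }
    calls[m, ] <- code
  }
  g <- genotype_matrix(t(calls),
                       map = data.frame(marker = df$`rs#`, chrom = df$chrom,
                                        pos = df$pos),
                       line_ids = line_ids)
  orient_major(g)
}

read_vcf_genotypes <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("format error reading ", path, ": ",
                                         conditionMessage(e)))
  if (nrow(v@fix) == 0) stop("format error: no records in ", path)
  alt <- v@fix[, "ALT"]
  ref <- v@fix[, "REF"]
  biallelic <- !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L
  if (any(!biallelic)) {
    message(sum(!biallelic), " multiallelic/non-SNP record(s) skipped")
  }
  if (!any(biallelic)) stop("format error: no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow(gt), ncol(gt))
  calls[gt == "0/0"] <- 0L
  calls[gt %in% c("0/1", "1/0")] <- 1L
  calls[gt == "1/1"] <- 2L
  ids <- v@fix[biallelic, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0("S", v@fix[biallelic, "CHROM"], "_",
                      v@fix[biallelic, "POS"])[noid]
  g <- genotype_matrix(t(calls),
                       map = data.frame(marker = ids,
                                        chrom = v@fix[biallelic, "CHROM"],
                                        pos = as.numeric(v@fix[biallelic, "POS"])),
                       line_ids = colnames(gt))
  orient_major(g)
}

## flip marker codes so 0 = major homozygote (ties keep current orientation)
orient_major <- function(g) {
  f <- colMeans(g$calls, na.rm = TRUE) / 2   # frequency of the '2' allele
  flip <- which(!is.nan(f) & f > 0.5)
  if (length(flip)) g$calls[, flip] <- 2L - g$calls[, flip]
  g
}

#' Filter markers on missingness and minor allele frequency
#'
#' Markers are removed first if their missing-call fraction exceeds
#' \code{max_missing}, then if their MAF (allele-frequency convention,
#' heterozygotes contributing one minor allele) falls below \code{min_maf}.
#' A marker failing both rules is counted once, under the missing rule.
#'
#' @param g a \code{genotype_matrix}.
#' @param max_missing maximum tolerated missing fraction, in (0,1).
#' @param min_maf minimum minor allele frequency, in (0,1).
#' @return list with elements \code{genotypes} (filtered matrix, marker order
#'   preserved) and \code{report} (a \code{marker_filter_report} with counts
#'   \code{n_input = n_output + n_removed_missing + n_removed_maf}).
#' @export
filter_markers <- function(g, max_missing = 0.30, min_maf = 0.15) {
  stopifnot(max_missing > 0, max_missing < 1, min_maf > 0, min_maf < 1)
  miss <- marker_missing(g)
  maf <- marker_maf(g)
  fail_miss <- miss > max_missing
  fail_maf <- !fail_miss & (is.nan(maf) | maf < min_maf)
  keep <- !fail_miss & !fail_maf
  if (!any(keep)) warning("marker filter produced an empty marker set")
  report <- structure(list(n_input = n_markers(g),
                           n_removed_missing = sum(fail_miss),
                           n_removed_maf = sum(fail_maf),
                           n_output = sum(keep),
                           thresholds = c(max_missing = max_missing,
                                          min_maf = min_maf)),
                      class = "marker_filter_report")
  list(genotypes = subset_genotypes(g, markers = which(keep)), report = report)
}

#' @export
print.marker_filter_report <- function(x, ...) {
  cat(sprintf(paste0("marker filter: %d in -> %d removed (missing > %.2f), ",
                     "%d removed (MAF < %.2f) -> %d retained\n"),
              x$n_input, x$n_removed_missing, x$thresholds["max_missing"],
              x$n_removed_maf, x$thresholds["min_maf"], x$n_output))
  invisible(x)
}

#' Filter lines on missingness
#'
#' Applied after marker filtering (so line missing fractions are computed on
#' the retained marker set, matching the published processing order).
#'
#' @param g a \code{genotype_matrix}.
#' @param max_missing maximum tolerated per-line missing fraction, in (0,1).
#' @return a \code{genotype_matrix} with offending lines removed.
#' @export
filter_lines <- function(g, max_missing = 0.60) {
  stopifnot(max_missing > 0, max_missing < 1)
  keep <- line_missing(g) <= max_missing
  subset_genotypes(g, lines = which(keep))
}
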