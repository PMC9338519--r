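# File interfaces: tab-separated summary statistics, results output, and
# BED-based binary annotation.

#' Read a summary-statistics table
#'
#' Reads a tab-separated file with a header row and required columns `snp`,
#' `p`, `q` (any number of covariate columns named `q`, `q1`, `q2`, ... is
#' accepted) and `group`; optional columns `chrom` and `pos` (1-based) are
#' carried through. All validation errors name the offending rows.
#'
#' @param path Path to a tab-separated text file.
#' @param allow_p_clamp If `TRUE`, p-values of exactly 0 are clamped to the
#'   smallest positive double instead of raising an error.
#' @return A validated data.frame (p in (0, 1], covariates in \{0, 1\},
#'   at least 2 groups).
#' @export
read_sumstats <- function(path, allow_p_clamp = FALSE) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  qcols <- grep("^q[0-9]*$", names(d), value = TRUE)
  miss <- setdiff(c("snp", "p", "group"), names(d))
  if (!length(qcols)) miss <- c(miss, "q")
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  d$p <- validate_p(d$p, allow_p_clamp)
  for (qc in qcols) d[[qc]] <- validate_q(d[[qc]])
  if (length(unique(d$group)) < 2L)
    stop("at least 2 distinct groups are required", call. = FALSE)
  d
}

#' Write iterative cFDR results
#'
#' Writes the input columns plus per-iteration `v_iterK` and `fdr_iterK`
#' columns as tab-separated text. Numeric columns are printed with 17
#' significant digits so that reading the file back reproduces the values
#' bit-for-bit.
#'
#' @param result A [binary_cfdr()] or [iterate_cfdr()] fit.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  d <- if (inherits(result, "bin_cfdr_iter")) {
    qmat <- result$q
    colnames(qmat) <- paste0("q", seq_len(ncol(qmat)))
    data.frame(snp = paste0("snp", seq_along(result$p)), p = result$p,
               group = result$group, qmat, result$v, result$fdr,
               check.names = FALSE)
  } else if (inherits(result, "bin_cfdr")) {
    data.frame(snp = if (is.null(result$snp))
                 paste0("snp", seq_along(result$p)) else result$snp,
               p = result$p, q = result$q, group = result$group,
               v_iter1 = result$v, fdr_iter1 = result$fdr)
  } else if (is.data.frame(result)) {
    result
  } else stop("unsupported result object", call. = FALSE)
  num <- vapply(d, is.numeric, logical(1)) &
    !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], function(x) sprintf("%.17g", x))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binary annotation of SNPs from a BED track
#'
#' Marks each SNP with 1 if its position overlaps any interval of a BED
#' track (union semantics), 0 otherwise. SNP positions are 1-based (GWAS
#' convention); BED intervals are 0-based half-open, and the conversion is
#' handled here (a BED interval `start end` covers 1-based positions
#' `start+1 .. end`). Annotations are strand-agnostic.
#'
#' @param chrom Chromosome per SNP (e.g. `"chr1"`; must match the track's
#'   naming).
#' @param pos 1-based SNP positions.
#' @param track Path to a BED file, or a `GRanges` (already 1-based, as
#'   returned by [rtracklayer::import()]).
#' @return Integer 0/1 vector, one entry per SNP.
#' @examples
#' \dontrun{
#' q <- annotate_with_bed(snps$chrom, snps$pos, "dgf_regions.bed")
#' }
#' @export
annotate_with_bed <- function(chrom, pos, track) {
  stopifnot(length(chrom) == length(pos))
  if (any(!is.finite(pos) | pos < 1))
    stop("SNP positions must be 1-based positive integers", call. = FALSE)
  if (is.character(track)) {
    if (!file.exists(track))
      stop("BED file not found: ", track, call. = FALSE)
    track <- rtracklayer::import(track, format = "bed")
  }
  if (length(track) == 0L)
    return(integer(length(pos)))
  snps <- GenomicRanges::GRanges(as.character(chrom),
                                 IRanges::IRanges(start = pos, width = 1L))
  # chromosomes absent from the track simply have no overlaps; silence the
  # disjoint-seqlevels warning that would otherwise fire for them
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(snps, track, ignore.strand = TRUE))
  as.integer(hits > 0L)
}
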