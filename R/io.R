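#' Read a barcode-level MPRA count table
#'
#' Expects a tab-separated file with header columns `variant_id`, `allele`,
#' `barcode`, followed by one integer count column per sequencing sample.
#' Sample types are taken from `sampleTypes` (a named `"DNA"`/`"RNA"`
#' vector, or a path to a two-column TSV `sample_id<TAB>DNA|RNA`); when
#' `NULL`, column names containing "dna"/"rna" (case-insensitive) are used.
#'
#' Variants lacking barcodes for one of the two alleles are dropped with a
#' warning; the number of excluded rows is stored in
#' `metadata(x)$n_excluded_rows`.
#'
#' @param path TSV file path.
#' @param sampleTypes sample-type map (see above) or `NULL`.
#' @return An [MpraExperiment-class].
#' @export
readCountTable <- function(path, sampleTypes = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("variant_id", "allele", "barcode")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop(sprintf("count table format error: missing column(s) %s",
                 paste(miss, collapse = ", ")))
  sampleCols <- setdiff(colnames(df), need)
  if (!length(sampleCols)) stop("count table has no sample columns")
  cts <- matrix(NA_real_, nrow(df), length(sampleCols),
                dimnames = list(NULL, sampleCols))
  for (j in sampleCols) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop(sprintf(
        "validation error: non-integer or negative count '%s' at row %d, column '%s'",
        df[[j]][bad[1L]], bad[1L], j))
    cts[, j] <- v
  }
  if (is.character(sampleTypes) && length(sampleTypes) == 1L &&
      file.exists(sampleTypes)) {
    m <- read.delim(sampleTypes, header = FALSE, stringsAsFactors = FALSE)
    sampleTypes <- setNames(m[[2L]], m[[1L]])
  }
  if (is.null(sampleTypes)) {
    st <- ifelse(grepl("dna", sampleCols, ignore.case = TRUE), "DNA",
                 ifelse(grepl("rna", sampleCols, ignore.case = TRUE),
                        "RNA", NA))
    if (anyNA(st))
      stop("cannot infer sample types from column names; supply sampleTypes")
  } else {
    if (!all(sampleCols %in% names(sampleTypes)))
      stop("sampleTypes does not cover all sample columns")
    st <- unname(sampleTypes[sampleCols])
  }
  MpraExperiment(cts, variant_id = df$variant_id, allele = df$allele,
                 barcode = df$barcode, sample_id = sampleCols,
                 sample_type = st)
}

#' Write an MpraExperiment back to the TSV layout read by [readCountTable()]
#'
#' @param x an [MpraExperiment-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path) {
  rd <- SummarizedExperiment::rowData(x)
  cts <- SummarizedExperiment::assay(x, "counts")
  out <- data.frame(variant_id = rd$variant_id, allele = rd$allele,
                    barcode = rd$barcode, check.names = FALSE)
  out <- cbind(out, as.data.frame(cts, check.names = FALSE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-variant annotation table
#'
#' First column must be `variant_id`. A single non-numeric value column
#' yields a categorical (grouping) annotation; otherwise all value columns
#' must be finite numerics (continuous annotations).
#'
#' @param path TSV file path.
#' @return data.frame with attribute `"annotation_type"` set to
#'   `"categorical"` or `"continuous"`.
#' @export
readAnnotations <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"variant_id" %in% colnames(df))
    stop("annotation format error: missing 'variant_id' column")
  if (ncol(df) < 2L) stop("annotation table needs at least one value column")
  if (anyDuplicated(df$variant_id))
    stop(sprintf("validation error: duplicated variant_id '%s'",
                 df$variant_id[duplicated(df$variant_id)][1L]))
  vals <- df[setdiff(colnames(df), "variant_id")]
  numeric_cols <- vapply(vals, is.numeric, logical(1L))
  if (all(numeric_cols)) {
    if (!all(vapply(vals, function(v) all(is.finite(v) | is.na(v)),
                    logical(1L))))
      stop("validation error: non-finite continuous annotation")
    attr(df, "annotation_type") <- "continuous"
  } else if (ncol(vals) == 1L) {
    attr(df, "annotation_type") <- "categorical"
  } else {
    stop("mixed annotation columns: use one categorical column or all-numeric")
  }
  df
}

#' Compute per-sample depth factors
#'
#' The depth factor of sample s is its column total divided by the geometric
#' mean of the column totals of samples of the same type, so factors have
#' geometric mean 1 within each of DNA and RNA. Every negative-binomial mean
#' in sample s is multiplied by this factor.
#'
#' @param x an [MpraExperiment-class].
#' @return Named positive numeric vector, one entry per sample.
#' @export
computeDepthFactors <- function(x) {
  cts <- SummarizedExperiment::assay(x, "counts")
  st <- SummarizedExperiment::colData(x)$sample_type
  totals <- colSums(cts)
  if (any(totals == 0))
    stop(sprintf("sample(s) with zero total counts: %s",
                 paste(colnames(cts)[totals == 0], collapse = ", ")))
  d <- totals
  for (ty in unique(st)) {
    i <- st == ty
    d[i] <- totals[i] / geometricMean(totals[i])
  }
  setNames(d, SummarizedExperiment::colData(x)$sample_id)
}

#' Count exact barcode matches in a FASTQ file
#'
#' Extracts the subsequence at a fixed, 0-based half-open position
#' `[offset, offset + width)` of every read and tallies exact matches
#' against a known barcode set. Reads shorter than `offset + width` are
#' skipped and counted separately; no mismatch tolerance is applied.
#'
#' @param fastq path to a FASTQ file (plain or gzip).
#' @param barcodes character vector of expected barcode sequences.
#' @param offset 0-based start of the barcode within the read.
#' @param width barcode length; defaults to the (common) barcode width.
#' @return list with `counts` (named integer vector over `barcodes`),
#'   `unmatched` and `skipped` read tallies.
#' @export
countBarcodes <- function(fastq, barcodes, offset = 0L, width = NULL) {
  if (is.null(width)) {
    width <- unique(nchar(barcodes))
    if (length(width) != 1L)
      stop("barcodes have differing lengths; supply width explicitly")
  }
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  counts <- setNames(integer(length(barcodes)), barcodes)
  if (!length(reads))
    return(list(counts = counts, unmatched = 0L, skipped = 0L))
  long <- Biostrings::width(reads) >= offset + width
  skipped <- sum(!long)
  obs <- as.character(Biostrings::subseq(reads[long], start = offset + 1L,
                                         width = width))
  hit <- match(obs, barcodes)
  tab <- table(hit[!is.na(hit)])
  counts[as.integer(names(tab))] <- as.integer(tab)
  list(counts = counts, unmatched = sum(is.na(hit)), skipped = skipped)
}

# Pre-extract every variant's data in one pass (avoids per-variant S4
# subsetting in assay-wide loops).
allVariantData <- function(x, depths = NULL) {
  rd <- SummarizedExperiment::rowData(x)
  if (is.null(depths)) depths <- depthFactors(x)
  st <- SummarizedExperiment::colData(x)$sample_type
  cts <- SummarizedExperiment::assay(x, "counts")
  dnaC <- cts[, st == "DNA", drop = FALSE]
  rnaC <- cts[, st == "RNA", drop = FALSE]
  dD <- unname(depths[st == "DNA"])
  dR <- unname(depths[st == "RNA"])
  vid <- rd$variant_id
  idx <- split(seq_along(vid), factor(vid, levels = unique(vid)))
  lapply(names(idx), function(v) {
    i <- idx[[v]]
    list(variant_id = v,
         dna = dnaC[i, , drop = FALSE], rna = rnaC[i, , drop = FALSE],
         dDna = dD, dRna = dR,
         allele = as.integer(rd$allele[i] == "alt"),
         barcode = rd$barcode[i])
  })
}

# Extract one variant's data in the layout the samplers expect.
variantData <- function(x, variant_id, depths = NULL) {
  rd <- SummarizedExperiment::rowData(x)
  i <- which(rd$variant_id == variant_id)
  if (!length(i)) stop(sprintf("unknown variant '%s'", variant_id))
  if (is.null(depths)) depths <- depthFactors(x)
  st <- SummarizedExperiment::colData(x)$sample_type
  cts <- SummarizedExperiment::assay(x, "counts")
  list(variant_id = variant_id,
       dna = cts[i, st == "DNA", drop = FALSE],
       rna = cts[i, st == "RNA", drop = FALSE],
       dDna = unname(depths[st == "DNA"]),
       dRna = unname(depths[st == "RNA"]),
       allele = as.integer(rd$allele[i] == "alt"),
       barcode = rd$barcode[i])
}
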