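#' Read a gene-by-sample FPKM matrix
#'
#' Parses an expression matrix from delimited text into the numeric matrix
#' (genes in rows, samples in columns) consumed by [zfpkm()] and friends.
#' Three dialects are supported: plain TSV and CSV with gene identifiers in
#' the first column and one sample per remaining column, and the Cufflinks
#' `genes.fpkm_tracking` dialect (tab-delimited, one sample per file, gene
#' identifiers in `tracking_id`, expression in `FPKM`).
#'
#' Empty cells and `NA` in the plain dialects are kept as missing values,
#' not coerced to zero: an FPKM of 0 is a meaningful observation (no reads)
#' whereas a missing cell is not. Negative values and duplicated gene
#' identifiers are parse errors, never silently repaired.
#'
#' @param path Path to the input file.
#' @param dialect One of `"plain_tsv"`, `"plain_csv"`, `"cufflinks_tracking"`.
#' @param sample_id Sample name to use for the single column of a
#'   `cufflinks_tracking` file. Defaults to the file name without extension.
#'
#' @return A numeric matrix of linear-scale FPKM values with gene identifiers
#'   as row names and sample identifiers as column names. For the Cufflinks
#'   dialect, a `gene_short_name` column (if present) is attached as the
#'   `"gene_short_name"` attribute, named by gene.
#' @seealso [write_matrix()] for the inverse operation.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\ts1\ts2", "g1\t0\t1.5", "g2\t12.5\t0.3"), tf)
#' read_fpkm_matrix(tf, "plain_tsv")
read_fpkm_matrix <- function(path,
                             dialect = c("plain_tsv", "plain_csv",
                                         "cufflinks_tracking"),
                             sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path)
  }
  if (dialect == "cufflinks_tracking") {
    return(read_cufflinks_tracking(path, sample_id))
  }
  sep <- if (dialect == "plain_tsv") "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = NA, na.strings = c("NA", ""),
                           quote = "\"", comment.char = "")
  if (ncol(tab) < 2) {
    stop("expected a gene identifier column plus at least one sample column")
  }
  gene_ids <- as.character(tab[[1]])
  check_gene_ids(gene_ids)
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    storage.mode(values) <- "double"
  }
  rownames(values) <- gene_ids
  validate_fpkm_matrix(values, allow_missing = TRUE)
  values
}

read_cufflinks_tracking <- function(path, sample_id = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", ""), quote = "\"",
                           comment.char = "")
  if (!"tracking_id" %in% names(tab)) {
    stop("cufflinks_tracking dialect requires a 'tracking_id' column")
  }
  if (!"FPKM" %in% names(tab)) {
    stop("cufflinks_tracking dialect requires an 'FPKM' column")
  }
  gene_ids <- as.character(tab$tracking_id)
  check_gene_ids(gene_ids)
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  values <- matrix(as.numeric(tab$FPKM), ncol = 1,
                   dimnames = list(gene_ids, sample_id))
  validate_fpkm_matrix(values, allow_missing = TRUE)
  if ("gene_short_name" %in% names(tab)) {
    attr(values, "gene_short_name") <-
      stats::setNames(as.character(tab$gene_short_name), gene_ids)
  }
  values
}

check_gene_ids <- function(gene_ids) {
  if (anyNA(gene_ids) || any(gene_ids == "")) {
    bad <- which(is.na(gene_ids) | gene_ids == "")
    stop("missing gene identifier at row ", bad[1])
  }
  if (anyDuplicated(gene_ids)) {
    dup <- gene_ids[duplicated(gene_ids)][1]
    stop("duplicated gene identifier: '", dup, "'")
  }
  invisible(gene_ids)
}

validate_fpkm_matrix <- function(values, allow_missing = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression values must form a numeric matrix")
  }
  if (is.null(rownames(values))) {
    stop("expression matrix must carry gene identifiers as row names")
  }
  if (!allow_missing && anyNA(values)) {
    stop("expression matrix contains missing values")
  }
  neg <- which(values < 0)
  if (length(neg)) {
    idx <- arrayInd(neg[1], dim(values))
    stop("negative FPKM value ", values[neg[1]], " for gene '",
         rownames(values)[idx[1]], "'")
  }
  invisible(values)
}

#' Write an expression or zFPKM matrix as delimited text
#'
#' Writes a numeric gene-by-sample matrix as TSV (or CSV) with a header row
#' and gene identifiers in the first column. Values are printed with 15
#' significant digits so that a write/read round trip is lossless for
#' practical purposes.
#'
#' @param matrix Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @param id_column Name of the identifier column in the header.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, sep = "\t", id_column = "gene_id") {
  if (!is.matrix(matrix) || nrow(matrix) == 0L || ncol(matrix) == 0L) {
    stop("cannot write an empty matrix")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("matrix must have gene row names and sample column names")
  }
  formatted <- format(matrix, digits = 15, trim = TRUE, scientific = FALSE)
  formatted[is.na(matrix)] <- "NA"
  out <- cbind(rownames(matrix), formatted)
  colnames(out) <- c(id_column, colnames(matrix))
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
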