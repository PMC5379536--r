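#' Validate and normalise an expression matrix
#'
#' Coerces `x` to a numeric genes-by-samples matrix and enforces the input
#' contract of the scoring and signature-derivation functions: unique gene
#' identifiers as row names, at least two genes, at least one sample, and no
#' missing values. Rows containing any missing value are dropped (a rank-based
#' test cannot use partial rows consistently across gene sets); the number of
#' dropped rows is reported via `message()`.
#'
#' @param x numeric matrix (genes in rows, samples in columns) with row names.
#'   Values may be linear-scale intensities, CPM, RPKM or log intensities; the
#'   downstream test is rank-based and therefore unit-agnostic.
#' @param drop_na drop rows with missing values (default) instead of erroring.
#' @return the validated numeric matrix.
#' @export
as_expression_matrix <- function(x, drop_na = TRUE) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression input must be a numeric matrix")
  }
  if (is.null(rownames(x))) stop("expression matrix must have gene identifiers as row names")
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop("duplicate gene identifiers in expression matrix: ",
         paste(utils::head(dup, 5L), collapse = ", "),
         if (length(dup) > 5L) ", ..." else "")
  }
  if (anyNA(x)) {
    if (!drop_na) stop("expression matrix contains missing values")
    bad <- rowSums(is.na(x)) > 0L
    message("dropping ", sum(bad), " gene row(s) with missing values")
    x <- x[!bad, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("degenerate profile: need at least 2 genes")
  if (ncol(x) < 1L) stop("need at least 1 sample")
  if (is.null(colnames(x))) colnames(x) <- paste0("sample_", seq_len(ncol(x)))
  x
}

#' Read an expression matrix from TSV or GCT 1.2
#'
#' Two dialects are recognised. A plain TSV has gene identifiers in the first
#' column and sample identifiers in the header row. A GCT 1.2 file starts with
#' the magic line `#1.2`, followed by a dimensions line and a header with
#' `Name` and `Description` columns preceding the sample columns.
#'
#' @param path file path.
#' @param drop_na passed to [as_expression_matrix()].
#' @return numeric genes-by-samples matrix.
#' @export
read_expression <- function(path, drop_na = TRUE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  first <- readLines(path, n = 1L)
  if (identical(trimws(first), "#1.2")) {
    return(read_gct(path, drop_na = drop_na))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(tab) < 2L) stop("malformed expression TSV (", path, "): need gene-ID column plus >=1 sample column")
  ids <- trimws(as.character(tab[[1L]]))
  vals <- tab[, -1L, drop = FALSE]
  num <- vapply(vals, is.numeric, logical(1L))
  if (!all(num)) {
    stop("malformed expression TSV (", path, "): non-numeric sample column(s): ",
         paste(colnames(vals)[!num], collapse = ", "))
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  as_expression_matrix(m, drop_na = drop_na)
}

read_gct <- function(path, drop_na = TRUE) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("malformed GCT (", path, "): fewer than 3 lines")
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]]))
  if (length(dims) < 2L || anyNA(dims[1:2])) {
    stop("malformed GCT (", path, "), line 2: expected '<genes>\t<samples>'")
  }
  tab <- utils::read.delim(text = lines[-(1:2)], header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("malformed GCT (", path, "): need Name, Description and sample columns")
  if (nrow(tab) != dims[1L] || ncol(tab) - 2L != dims[2L]) {
    stop("malformed GCT (", path, "): dimensions line says ", dims[1L], " x ", dims[2L],
         " but body has ", nrow(tab), " x ", ncol(tab) - 2L)
  }
  m <- as.matrix(tab[, -(1:2), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- trimws(as.character(tab[[1L]]))
  as_expression_matrix(m, drop_na = drop_na)
}

#' Write an expression matrix as TSV
#'
#' First column `gene_id`, one column per sample. Inverse of the TSV dialect
#' accepted by [read_expression()].
#'
#' @param x numeric genes-by-samples matrix.
#' @param path output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
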