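#' Validate a gene-expression time-series matrix
#'
#' Checks that `x` is a numeric matrix of p genes (rows) by m ordered time
#' points (columns) suitable for network inference: at least 2 genes, at
#' least 3 time points, no missing values, and unique gene names. Missing
#' dimnames are filled in (`g1..gp`, `t1..tm`).
#'
#' @param x numeric matrix, genes in rows, time points in columns.
#' @return the validated matrix with complete dimnames.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression data must be a numeric matrix (genes x time points)")
  if (nrow(x) < 2L)
    stop("need at least 2 genes, got ", nrow(x))
  if (ncol(x) < 3L)
    stop("need at least 3 time points, got ", ncol(x))
  if (anyNA(x))
    stop("expression matrix contains missing values")
  if (is.null(rownames(x)))
    rownames(x) <- paste0("g", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene names: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (is.null(colnames(x)))
    colnames(x) <- paste0("t", seq_len(ncol(x)))
  x
}

#' Standardize each gene to mean zero, unit variance
#'
#' Per-gene affine standardization using the sample (n-1) standard
#' deviation. Genes with zero variance are set to all-zero and flagged in
#' the `"zero_variance"` attribute; downstream estimators drop them.
#'
#' @param x expression matrix (genes x time points).
#' @param warn warn when zero-variance genes are found.
#' @return standardized matrix with a logical `"zero_variance"` attribute.
#' @export
standardize_expression <- function(x, warn = TRUE) {
  x <- validate_expression(x)
  mu <- rowMeans(x)
  centered <- x - mu
  sds <- sqrt(rowSums(centered^2) / (ncol(x) - 1L))
  flat <- sds < .Machine$double.eps^0.5
  out <- centered / ifelse(flat, 1, sds)
  out[flat, ] <- 0
  if (warn && any(flat))
    warning("zero-variance gene(s) set to zero: ",
            paste(rownames(x)[flat], collapse = ", "))
  attr(out, "zero_variance") <- stats::setNames(flat, rownames(x))
  out
}

#' Read an expression table from delimited text
#'
#' Strict reader for the canonical exchange format: first column gene
#' identifiers, first row time labels, tab-separated by default (a comma
#' dialect is detected automatically). Duplicate gene identifiers and
#' non-numeric cells are rejected with the offending row/column named.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) sniffs tab vs comma from
#'   the header line.
#' @return validated numeric expression matrix.
#' @export
read_expression <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           row.names = NULL, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop("expression table needs >= 3 time point columns, got ", ncol(tab) - 1L)
  genes <- tab[[1L]]
  if (anyDuplicated(genes))
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at gene '", genes[bad[1L]], "', column '",
         colnames(vals)[bad[2L]], "'")
  }
  dimnames(num) <- list(genes, colnames(vals))
  validate_expression(num)
}

#' Write an expression matrix as delimited text
#'
#' Tab-separated, gene identifiers in the first column, time labels in the
#' header; round-trips through [read_expression()] at full precision.
#'
#' @param x expression matrix.
#' @param path output file path.
#' @param sep field separator (tab by default; never mixed).
#' @export
write_expression <- function(x, path, sep = "\t") {
  x <- validate_expression(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = sep,
                     quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}
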