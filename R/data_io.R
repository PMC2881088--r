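#' Read a gene expression matrix from tab-delimited text
#'
#' The expected layout is genes as rows and samples as columns: the first row
#' holds sample identifiers, the first column gene identifiers. Empty cells
#' and the tokens `NA`/`NaN` (case-insensitive) are parsed as missing values.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter, tab by default.
#' @return A numeric matrix (genes x samples) with gene ids as row names and
#'   sample ids as column names. May contain `NA` entries prior to
#'   [knn_impute()].
#' @seealso [read_survival()], [knn_impute()], [standardize_expression()]
#' @export
read_expression <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop("expression file not found: ", path, call. = FALSE)
  }
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = character(),
                    colClasses = "character")
  if (ncol(raw) < 2L) stop("expression file needs a gene id column and at least one sample column", call. = FALSE)
  gene_ids <- as.character(raw[[1L]])
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene identifiers: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  vals[is_missing_token(vals)] <- NA_character_
  suppressWarnings(storage.mode(vals) <- "double")
  bad <- !is.na(as.matrix(raw[, -1L, drop = FALSE])) &
    !is_missing_token(as.matrix(raw[, -1L, drop = FALSE])) & is.na(vals)
  if (any(bad)) {
    stop("non-numeric expression value(s), e.g. '",
         as.matrix(raw[, -1L, drop = FALSE])[which(bad)[1L]], "'", call. = FALSE)
  }
  dimnames(vals) <- list(gene_ids, sample_ids)
  vals
}

is_missing_token <- function(x) {
  x <- trimws(x)
  x == "" | toupper(x) %in% c("NA", "NAN")
}

#' Write an expression matrix in the tab-delimited dialect of [read_expression()]
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param path Output path.
#' @param digits Significant digits for floating-point output.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, digits = 6L) {
  expr <- as_expression_matrix(expr)
  out <- data.frame(gene = rownames(expr),
                    signif(expr, digits), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read right-censored survival data
#'
#' Expects a tab-delimited file with header columns `sample`, `time` and
#' `status`, where `time` is the observed follow-up time (minimum of the
#' event and censoring times, strictly positive) and `status` is the event
#' indicator (1 = event observed, 0 = censored).
#'
#' @param path Path to a tab-delimited text file.
#' @return A tibble with columns `sample`, `time`, `status`, row order as in
#'   the file.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop("survival file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("sample", "time", "status")
  if (!all(need %in% colnames(raw))) {
    stop("survival file must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  surv <- tibble::tibble(sample = as.character(raw$sample),
                         time = as.numeric(raw$time),
                         status = as.numeric(raw$status))
  validate_survival(surv)
  surv
}

#' Write survival data in the dialect of [read_survival()]
#' @param surv Tibble/data frame with `sample`, `time`, `status`.
#' @param path Output path.
#' @param digits Significant digits for times.
#' @return `path`, invisibly.
#' @export
write_survival <- function(surv, path, digits = 6L) {
  surv <- validate_survival(surv)
  out <- data.frame(sample = surv$sample,
                    time = signif(surv$time, digits),
                    status = as.integer(surv$status))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_survival <- function(surv) {
  if (!all(c("sample", "time", "status") %in% colnames(surv))) {
    stop("survival data must have columns sample, time, status", call. = FALSE)
  }
  if (anyDuplicated(surv$sample)) stop("duplicate sample identifiers in survival data", call. = FALSE)
  if (anyNA(surv$time) || anyNA(surv$status)) stop("missing values in survival data", call. = FALSE)
  if (any(surv$time <= 0)) stop("all survival times must be > 0", call. = FALSE)
  if (!all(surv$status %in% c(0, 1))) stop("status must be 0 (censored) or 1 (event)", call. = FALSE)
  invisible(surv)
}

as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression data must be a numeric genes x samples matrix", call. = FALSE)
  }
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  if (is.null(colnames(expr))) colnames(expr) <- paste0("s", seq_len(ncol(expr)))
  expr
}

#' Align an expression matrix with a survival table
#'
#' Checks the two inputs describe the same samples and reorders the survival
#' rows to the expression column order.
#'
#' @param expr Genes x samples expression matrix.
#' @param surv Survival tibble (`sample`, `time`, `status`).
#' @return A list with elements `expr` and `surv` in matched sample order.
#' @export
align_samples <- function(expr, surv) {
  expr <- as_expression_matrix(expr)
  surv <- validate_survival(surv)
  if (!setequal(colnames(expr), surv$sample) || ncol(expr) != nrow(surv)) {
    stop("sample identifiers of expression and survival data do not match", call. = FALSE)
  }
  list(expr = expr, surv = surv[match(colnames(expr), surv$sample), , drop = FALSE])
}

#' K-nearest-neighbour imputation of missing expression values
#'
#' Gene-wise KNN imputation, the microarray standard: for a gene with a
#' missing value at some sample, the `k` genes closest in Euclidean distance
#' (computed over mutually observed samples, scaled to a per-sample average so
#' genes with different missingness are comparable) that are observed at that
#' sample donate their mean value there. Observed entries are never modified.
#'
#' @param expr Genes x samples matrix, possibly with `NA` entries.
#' @param k Number of donor neighbours (default 10).
#' @return The matrix with all missing entries filled in.
#' @export
knn_impute <- function(expr, k = 10L) {
  expr <- as_expression_matrix(expr)
  if (!anyNA(expr)) return(expr)
  k <- as.integer(k)
  if (k < 1L || k >= nrow(expr)) stop("k must satisfy 1 <= k < number of genes", call. = FALSE)
  all_missing <- rowSums(!is.na(expr)) == 0L
  if (any(all_missing)) {
    stop("gene(s) with all values missing cannot be imputed: ",
         paste(head(rownames(expr)[all_missing], 5L), collapse = ", "), call. = FALSE)
  }
  out <- expr
  need <- which(rowSums(is.na(expr)) > 0L)
  for (g in need) {
    target <- expr[g, ]
    # mean squared difference over commonly observed samples, per candidate gene
    diffs <- sweep(expr, 2L, target)
    sq <- diffs^2
    n_common <- rowSums(!is.na(sq))
    msd <- rowMeans(sq, na.rm = TRUE)
    msd[g] <- Inf
    msd[n_common == 0L] <- Inf
    for (s in which(is.na(target))) {
      ok <- !is.na(expr[, s]) & is.finite(msd)
      if (!any(ok)) stop("no donor gene observed at sample ", colnames(expr)[s], call. = FALSE)
      donors <- order(msd[ok])[seq_len(min(k, sum(ok)))]
      out[g, s] <- mean(expr[which(ok)[donors], s])
    }
  }
  out
}

#' Keep the genes with the largest sample variance
#'
#' Standard prescreen before network construction: retains the `m` genes of
#' largest variance (default 2000). Ties are broken by original row order;
#' `m >= nrow(expr)` returns the input unchanged.
#'
#' @param expr Imputed genes x samples matrix.
#' @param m Number of genes to keep.
#' @return The filtered matrix, genes in original relative order.
#' @export
prescreen_by_variance <- function(expr, m = 2000L) {
  expr <- as_expression_matrix(expr)
  if (anyNA(expr)) stop("impute missing values before variance prescreening", call. = FALSE)
  m <- as.integer(m)
  if (m <= 0L) stop("m must be positive", call. = FALSE)
  if (m >= nrow(expr)) return(expr)
  v <- row_variances(expr)
  keep <- sort(order(-v, seq_along(v))[seq_len(m)])
  expr[keep, , drop = FALSE]
}

row_variances <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Standardize genes to zero median and unit variance
#'
#' Per gene, the median is subtracted and the result divided by the sample
#' standard deviation (computed about the mean), so each gene has median 0 and
#' variance 1. This is the preprocessing the Cox design matrix assumes.
#'
#' @param expr Imputed genes x samples matrix.
#' @return Standardized matrix of the same shape.
#' @export
standardize_expression <- function(expr) {
  expr <- as_expression_matrix(expr)
  if (anyNA(expr)) stop("impute missing values before standardization", call. = FALSE)
  v <- row_variances(expr)
  if (any(v == 0)) {
    stop("zero-variance gene(s) cannot be standardized: ",
         paste(head(rownames(expr)[v == 0], 5L), collapse = ", "), call. = FALSE)
  }
  # median centering leaves the variance untouched, so dividing by the sd
  # about the mean yields exact unit variance
  (expr - apply(expr, 1L, median)) / sqrt(v)
}
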