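#' Read a gene-expression matrix from TSV
#'
#' Expects genes in rows and samples in columns: the first column holds
#' gene symbols, the header row holds sample ids. Lines starting with `#`
#' are ignored.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
load_expression <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus >=1 sample")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene ids in expression matrix: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) stop("duplicate sample ids in expression matrix")
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) | !is.finite(vn))[1L]
      stop("non-numeric expression value for gene ", genes[bad],
           ", sample ", samples[j], ": '", v[bad], "'")
    }
    if (anyNA(v) || any(!is.finite(v))) {
      bad <- which(is.na(v) | !is.finite(v))[1L]
      stop("non-finite expression value for gene ", genes[bad],
           ", sample ", samples[j])
    }
  }
  m <- as.matrix(vals)
  dimnames(m) <- list(genes, samples)
  m
}

#' Read a clinical table from TSV
#'
#' Required columns: `sample`, `time_months`, `event`; optional `label`
#' (good/poor prognosis) and any further covariate columns.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with one row per sample.
#' @export
load_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample", "time_months", "event")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("clinical table lacks column(s): ", paste(miss, collapse = ", "))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicate sample ids in clinical table")
  if (any(!is.finite(df$time_months)) || any(df$time_months <= 0)) {
    stop("survival times must be finite and positive")
  }
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  if ("label" %in% colnames(df)) as_poor(df$label)  # validates values
  df
}

#' Reconcile expression and clinical sample sets
#'
#' Keeps the intersection of sample ids, warning about samples present in
#' only one of the two inputs; expression columns are reordered to the
#' clinical row order.
#'
#' @param expr Expression (or z-score) matrix, samples in columns.
#' @param clinical Clinical data.frame with a `sample` column.
#' @return List with elements `expr` and `clinical`, sample-aligned.
#' @export
reconcile_samples <- function(expr, clinical) {
  common <- intersect(colnames(expr), clinical$sample)
  if (!length(common)) stop("no samples shared between expression and clinical data")
  drop_c <- setdiff(clinical$sample, common)
  drop_e <- setdiff(colnames(expr), common)
  if (length(drop_c)) {
    warning("dropping ", length(drop_c), " clinical sample(s) absent from expression: ",
            paste(utils::head(drop_c, 5L), collapse = ", "))
  }
  if (length(drop_e)) {
    warning("dropping ", length(drop_e), " expression sample(s) absent from clinical: ",
            paste(utils::head(drop_e, 5L), collapse = ", "))
  }
  clinical <- clinical[clinical$sample %in% common, , drop = FALSE]
  list(expr = expr[, clinical$sample, drop = FALSE], clinical = clinical)
}

#' Per-gene z-score normalization
#'
#' Applies a log2 transform when the input is on the raw intensity scale,
#' then centres and scales every gene row to mean 0 and standard deviation
#' 1 (sample sd, n - 1 denominator) across samples. Genes with zero
#' variance are dropped with a message; z-scores for them are undefined.
#'
#' @param expr Numeric genes-by-samples matrix.
#' @param already_log2 Set `FALSE` for raw intensities (all values must be
#'   positive); `TRUE` (default) if values are already on log2 scale.
#' @return The z-score matrix, same orientation, possibly fewer rows.
#' @export
normalize_expression <- function(expr, already_log2 = TRUE) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 2L) stop("need at least 2 samples per gene to compute a z-score")
  if (!already_log2) {
    if (any(expr <= 0)) stop("log2 transform requires strictly positive values")
    expr <- log2(expr)
  }
  s <- sqrt(row_vars(expr))
  zero <- s == 0
  if (any(zero)) {
    message("dropping ", sum(zero), " zero-variance gene(s): ",
            paste(utils::head(rownames(expr)[zero], 5L), collapse = ", "))
    expr <- expr[!zero, , drop = FALSE]
    s <- s[!zero]
  }
  if (!nrow(expr)) stop("no genes left after dropping zero-variance rows")
  (expr - rowMeans(expr)) / s
}
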