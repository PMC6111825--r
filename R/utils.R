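# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards so package functions do not perturb it.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic child seed, kept inside the 32-bit integer range.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647L)
}

# Row-wise sample variance (n - 1 denominator).
row_vars <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Welch two-sample t statistic per row of `x`, oriented case minus reference.
# Rows with zero variance in both groups and equal means score 0.
welch_t_rows <- function(x, is_case) {
  x <- rbind(x)
  n1 <- sum(is_case)
  n2 <- sum(!is_case)
  if (n1 < 2L || n2 < 2L) {
    stop("each class needs at least 2 samples (got ", n1, " and ", n2, ")")
  }
  x1 <- x[, is_case, drop = FALSE]
  x2 <- x[, !is_case, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  se <- sqrt(row_vars(x1) / n1 + row_vars(x2) / n2)
  t <- (m1 - m2) / se
  t[se == 0 & m1 == m2] <- 0
  t
}

# Coerce a prognosis label vector to logical "is poor" with validation.
as_poor <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("good", "poor"))
  if (length(bad)) {
    stop("prognosis labels must be 'good' or 'poor'; found: ",
         paste(bad, collapse = ", "))
  }
  labels == "poor"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
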