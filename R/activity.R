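#' Greedy search configuration
#'
#' @param r Improvement rate: a candidate gene addition is accepted only if
#'   the new discriminative score exceeds `(1 + r)` times the current one.
#'   Default 0.05.
#' @param min_size,max_size Size filter on emitted subpathways; defaults 4
#'   and 49 (more than three genes, fewer than 50).
#' @param score_mode `"absolute_t"` (default) ranks candidates by |t| so
#'   both over- and under-active subpathways are found; `"signed_t"` ranks
#'   by the signed statistic.
#' @param divisor Eq-1 divisor for the combined z-score: `"n"` (default,
#'   the arithmetic mean) or `"sqrt_n"`.
#' @return A `search_config` list.
#' @export
search_config <- function(r = 0.05, min_size = 4L, max_size = 49L,
                          score_mode = c("absolute_t", "signed_t"),
                          divisor = c("n", "sqrt_n")) {
  score_mode <- match.arg(score_mode)
  divisor <- match.arg(divisor)
  stopifnot(r >= 0, min_size >= 1L, min_size <= max_size)
  structure(list(r = r, min_size = as.integer(min_size),
                 max_size = as.integer(max_size),
                 score_mode = score_mode, divisor = divisor),
            class = "search_config")
}

activity_divisor <- function(n, divisor) {
  if (divisor == "sqrt_n") sqrt(n) else n
}

#' Subpathway activity: the combined z-score
#'
#' For a subpathway with member genes `genes`, the activity of sample `j`
#' is the sum of the members' z-scores in that sample divided by `n` (or
#' `sqrt(n)` when `divisor = "sqrt_n"`).
#'
#' @param z Gene-by-sample z-score matrix (see [normalize_expression()]).
#' @param genes Character vector of member gene symbols, all present in `z`.
#' @param divisor `"n"` or `"sqrt_n"`.
#' @return Named numeric vector of activities, one per sample.
#' @export
subpathway_activity <- function(z, genes, divisor = "n") {
  idx <- match(genes, rownames(z))
  if (anyNA(idx)) {
    stop("gene(s) absent from the z-score matrix: ",
         paste(genes[is.na(idx)], collapse = ", "))
  }
  if (!length(idx)) stop("a subpathway needs at least one gene")
  colSums(z[idx, , drop = FALSE]) / activity_divisor(length(idx), divisor)
}

#' Discriminative score of an activity vector
#'
#' The Welch two-sample t statistic of the activity values, oriented poor
#' minus good prognosis. With `score_mode = "absolute_t"` the absolute
#' value is returned (the search ranks two-sided discriminativeness); the
#' signed statistic is available with `score_mode = "signed_t"`.
#'
#' @param activity Numeric activity vector, one value per sample.
#' @param labels Prognosis labels, `"good"` / `"poor"`, aligned to
#'   `activity`.
#' @param score_mode `"absolute_t"` or `"signed_t"`.
#' @return The t statistic (absolute or signed).
#' @export
discriminative_score <- function(activity, labels, score_mode = "absolute_t") {
  t <- welch_t_rows(matrix(activity, nrow = 1L), as_poor(labels))[1L]
  if (score_mode == "absolute_t") abs(t) else t
}

#' Seeded greedy search for discriminative subpathways
#'
#' Every expressed gene of the pathway graph seeds one search. The current
#' subpathway grows by repeatedly adding, among the graph neighbours of
#' its members (restricted to genes with expression), the gene that
#' maximizes the new discriminative score; an addition is accepted only if
#' the new score strictly exceeds `(1 + r)` times the current score, which
#' guards against over-fitting. Grown sets within the size filter are
#' emitted; identical gene sets reached from different seeds are collapsed
#' (first seed in lexicographic order wins). Score ties between candidate
#' genes break to the lexicographically smallest symbol, making the search
#' fully deterministic.
#'
#' @param graph A [pathway_graph].
#' @param z Gene-by-sample z-score matrix.
#' @param labels Prognosis labels aligned to the columns of `z`.
#' @param config A [search_config()].
#' @return A data.frame with one row per subpathway: `subpathway_id`,
#'   `pathway_id`, `seed`, `n`, `score` (signed t), `abs_score`, and a
#'   list-column `genes` (insertion order of the greedy growth).
#' @export
greedy_search <- function(graph, z, labels, config = search_config()) {
  is_poor <- as_poor(labels)
  stopifnot(length(is_poor) == ncol(z))
  expressed <- which(!is.na(match(graph$genes, rownames(z))))
  if (!length(expressed)) {
    warning("pathway ", graph$pathway_id, ": no genes with expression; skipped")
    return(empty_subpathways())
  }
  zrow <- match(graph$genes, rownames(z))  # NA for unexpressed
  seeds <- expressed[order(graph$genes[expressed])]

  score_of <- function(idx) {
    a <- colSums(z[zrow[idx], , drop = FALSE]) /
      activity_divisor(length(idx), config$divisor)
    t <- welch_t_rows(matrix(a, nrow = 1L), is_poor)[1L]
    if (config$score_mode == "absolute_t") abs(t) else t
  }

  out_sets <- list()
  out_rows <- list()
  seen <- character(0)
  for (seed in seeds) {
    members <- seed
    cur <- score_of(members)
    repeat {
      cand <- graph_frontier(graph, members, allowed = expressed)
      if (!length(cand)) break
      sc <- vapply(cand, function(g) score_of(c(members, g)), numeric(1))
      best <- which(sc == max(sc))
      if (length(best) > 1L) {
        best <- best[order(graph$genes[cand[best]])][1L]
      }
      if (sc[best] > (1 + config$r) * cur) {
        members <- c(members, cand[best])
        cur <- sc[best]
      } else break
    }
    n <- length(members)
    if (n < config$min_size || n > config$max_size) next
    key <- paste(sort(graph$genes[members]), collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    signed <- {
      a <- colSums(z[zrow[members], , drop = FALSE]) /
        activity_divisor(n, config$divisor)
      welch_t_rows(matrix(a, nrow = 1L), is_poor)[1L]
    }
    out_rows[[length(out_rows) + 1L]] <- data.frame(
      pathway_id = graph$pathway_id,
      seed = graph$genes[seed],
      n = n,
      score = signed,
      abs_score = abs(signed),
      stringsAsFactors = FALSE
    )
    out_sets[[length(out_sets) + 1L]] <- graph$genes[members]
  }
  if (!length(out_rows)) return(empty_subpathways())
  df <- do.call(rbind, out_rows)
  df$subpathway_id <- paste0(df$pathway_id, "_", seq_len(nrow(df)))
  df$genes <- I(out_sets)
  df[, c("subpathway_id", "pathway_id", "seed", "n", "score", "abs_score", "genes")]
}

empty_subpathways <- function() {
  df <- data.frame(subpathway_id = character(0), pathway_id = character(0),
                   seed = character(0), n = integer(0), score = numeric(0),
                   abs_score = numeric(0), stringsAsFactors = FALSE)
  df$genes <- I(list())
  df
}

#' Greedy search over a list of pathways
#'
#' @inheritParams greedy_search
#' @param graphs List of [pathway_graph] objects.
#' @return Row-bound subpathway table across pathways (see
#'   [greedy_search()]); subpathway ids are unique across pathways.
#' @export
greedy_search_all <- function(graphs, z, labels, config = search_config()) {
  res <- lapply(graphs, function(g) greedy_search(g, z, labels, config))
  res <- res[vapply(res, nrow, integer(1)) > 0L]
  if (!length(res)) return(empty_subpathways())
  df <- do.call(rbind, res)
  rownames(df) <- NULL
  df
}

#' Build the subpathway activity matrix
#'
#' One row per subpathway, computed with [subpathway_activity()]; row
#' order follows the subpathway table.
#'
#' @param z Gene-by-sample z-score matrix.
#' @param subpathways Subpathway table as returned by [greedy_search()].
#' @param divisor `"n"` or `"sqrt_n"`.
#' @return Numeric matrix, subpathways x samples.
#' @export
build_activity_matrix <- function(z, subpathways, divisor = "n") {
  m <- matrix(numeric(0), nrow = 0L, ncol = ncol(z),
              dimnames = list(NULL, colnames(z)))
  if (!nrow(subpathways)) return(m)
  m <- t(vapply(subpathways$genes,
                function(g) subpathway_activity(z, g, divisor),
                numeric(ncol(z))))
  rownames(m) <- subpathways$subpathway_id
  colnames(m) <- colnames(z)
  m
}

#' Write / read a subpathway table as TSV
#'
#' Gene lists are semicolon-joined in the file.
#'
#' @param subpathways Subpathway table (see [greedy_search()]).
#' @param path File path.
#' @param header Optional comment lines written with a `#` prefix.
#' @return `path` (write) or the subpathway table (read).
#' @export
write_subpathways <- function(subpathways, path, header = NULL) {
  df <- subpathways
  df$genes <- vapply(df$genes, paste, character(1), collapse = ";")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subpathways
#' @export
read_subpathways <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  df$genes <- I(strsplit(df$genes, ";", fixed = TRUE))
  df$n <- as.integer(df$n)
  df
}

#' Write / read an activity (or z-score) matrix as TSV
#'
#' @param m Numeric matrix with rownames and sample colnames.
#' @param path File path.
#' @param id_col Name of the first (rowname) column in the file.
#' @param header Optional comment lines written with a `#` prefix.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id", header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c(id_col, colnames(m)), collapse = "\t"), con)
  utils::write.table(cbind(rownames(m), format(m, digits = 15, trim = TRUE)),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}
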