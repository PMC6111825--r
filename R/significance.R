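# Permutation significance of discovered subpathways.
#
# Three complementary nulls are tested for every subpathway: (1) gene
# labels are permuted across the pathway networks, breaking the link
# between expression rows and graph topology; (2) the prognosis status
# vector is permuted, breaking the link between activity and class; (3)
# random connected gene sets of the same size, grown from the same seed
# gene within the same pathway, replace the subpathway. Each p-value is
# the plain permutation fraction P = M/N, M being the number of permuted
# scores strictly greater than the real score (scores compared as |t|).

# Scores (|t| or signed per mode) for a set of gene-index lists under a
# fixed z matrix; idx_list holds row indices into z.
score_sets <- function(z, idx_list, is_poor, divisor = "n",
                       score_mode = "absolute_t") {
  if (!length(idx_list)) return(numeric(0))
  A <- t(vapply(idx_list, function(idx) {
    colSums(z[idx, , drop = FALSE]) / activity_divisor(length(idx), divisor)
  }, numeric(ncol(z))))
  t <- welch_t_rows(A, is_poor)
  if (score_mode == "absolute_t") abs(t) else t
}

subpathway_gene_indices <- function(subpathways, z) {
  lapply(subpathways$genes, function(g) {
    idx <- match(g, rownames(z))
    if (anyNA(idx)) {
      stop("subpathway gene(s) absent from z matrix: ",
           paste(g[is.na(idx)], collapse = ", "))
    }
    idx
  })
}

#' Permutation test 1: gene labels across pathway networks
#'
#' Each permutation globally shuffles the assignment of expression rows to
#' the genes appearing in the pathway graphs (expression profiles and
#' prognosis status are preserved), then re-scores every real subpathway
#' gene set under the shuffled assignment. `scope = "per_pathway"`
#' restricts each shuffle to within one pathway's gene set.
#'
#' @param graphs List of [pathway_graph] objects the subpathways came from.
#' @param z Gene-by-sample z-score matrix.
#' @param labels Prognosis labels aligned to `z` columns.
#' @param subpathways Subpathway table (see [greedy_search()]).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for reproducibility.
#' @param scope `"global"` (one shuffle across the union of pathway genes)
#'   or `"per_pathway"`.
#' @param divisor Eq-1 divisor mode.
#' @return Numeric vector of p-values `M/N`, one per subpathway.
#' @export
permtest_gene_labels <- function(graphs, z, labels, subpathways,
                                 n_perm = 10000L, seed = NULL,
                                 scope = c("global", "per_pathway"),
                                 divisor = "n") {
  scope <- match.arg(scope)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  is_poor <- as_poor(labels)
  idx_list <- subpathway_gene_indices(subpathways, z)
  real <- score_sets(z, idx_list, is_poor, divisor)
  pool <- sort(unique(unlist(lapply(graphs, function(g) {
    intersect(g$genes, rownames(z))
  }))))
  pool_idx <- match(pool, rownames(z))
  pathway_pools <- lapply(graphs, function(g) {
    match(intersect(g$genes, rownames(z)), rownames(z))
  })
  names(pathway_pools) <- vapply(graphs, `[[`, character(1), "pathway_id")
  M <- numeric(length(idx_list))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      map <- seq_len(nrow(z))
      if (scope == "global") {
        map[pool_idx] <- sample(pool_idx)
      } else {
        for (pp in pathway_pools) map[pp] <- pp[sample.int(length(pp))]
      }
      perm <- score_sets(z, lapply(idx_list, function(i) map[i]), is_poor, divisor)
      M <- M + (perm > real)
    }
  })
  M / n_perm
}

#' Permutation test 2: prognosis status
#'
#' Re-scores every subpathway over random permutations of the class-label
#' vector; gene assignment and expression are preserved.
#'
#' @inheritParams permtest_gene_labels
#' @param n_perm Number of permutations (default 1000).
#' @return Numeric vector of p-values, one per subpathway.
#' @export
permtest_class_labels <- function(z, labels, subpathways, n_perm = 1000L,
                                  seed = NULL, divisor = "n") {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  is_poor <- as_poor(labels)
  idx_list <- subpathway_gene_indices(subpathways, z)
  A <- t(vapply(idx_list, function(idx) {
    colSums(z[idx, , drop = FALSE]) / activity_divisor(length(idx), divisor)
  }, numeric(ncol(z))))
  real <- abs(welch_t_rows(A, is_poor))
  M <- numeric(length(idx_list))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- abs(welch_t_rows(A, sample(is_poor)))
      M <- M + (perm > real)
    }
  })
  M / n_perm
}

# Grow a uniformly random connected node set of size `n` from `seed_idx`
# by repeated uniform draws from the current frontier. Returns indices or
# NULL if fewer than n genes are reachable.
random_connected_set <- function(graph, seed_idx, n, allowed = NULL) {
  members <- seed_idx
  frontier <- graph_frontier(graph, members, allowed)
  while (length(members) < n) {
    if (!length(frontier)) return(NULL)
    pick <- frontier[sample.int(length(frontier), 1L)]
    members <- c(members, pick)
    nb <- graph$adj[[pick]]
    if (!is.null(allowed)) nb <- intersect(nb, allowed)
    frontier <- setdiff(unique(c(frontier, nb)), members)
  }
  members
}

#' Sample random connected subpathways
#'
#' Draws random connected gene sets (uniform frontier expansion from a
#' random expressed seed gene) across a list of pathway graphs and scores
#' them. Used for null calibration; the same sampler drives
#' [permtest_within_pathway()].
#'
#' @inheritParams permtest_gene_labels
#' @param n_sets Number of subpathways to draw.
#' @param size Target gene-set size.
#' @param seed Integer seed.
#' @return Subpathway table in the [greedy_search()] layout.
#' @export
random_subpathways <- function(graphs, z, labels, n_sets, size, seed = NULL,
                               divisor = "n") {
  is_poor <- as_poor(labels)
  rows <- list(); sets <- list()
  with_seed(seed, {
    tries <- 0L
    while (length(sets) < n_sets && tries < 50L * n_sets) {
      tries <- tries + 1L
      g <- graphs[[sample.int(length(graphs), 1L)]]
      allowed <- which(g$genes %in% rownames(z))
      if (length(allowed) < size) next
      seed_idx <- allowed[sample.int(length(allowed), 1L)]
      idx <- random_connected_set(g, seed_idx, size, allowed)
      if (is.null(idx)) next
      genes <- g$genes[idx]
      a <- subpathway_activity(z, genes, divisor)
      t <- welch_t_rows(matrix(a, nrow = 1L), is_poor)[1L]
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = g$pathway_id, seed = genes[1L], n = size,
        score = t, abs_score = abs(t), stringsAsFactors = FALSE)
      sets[[length(sets) + 1L]] <- genes
    }
  })
  if (!length(rows)) return(empty_subpathways())
  df <- do.call(rbind, rows)
  df$subpathway_id <- paste0("rnd_", seq_len(nrow(df)))
  df$genes <- I(sets)
  df[, c("subpathway_id", "pathway_id", "seed", "n", "score", "abs_score", "genes")]
}

#' Permutation test 3: random subpathways within the parent pathway
#'
#' For one subpathway, draws `n_perm` random connected gene sets of the
#' same size grown from the same seed gene within the parent pathway and
#' compares their scores with the real score.
#'
#' @inheritParams permtest_gene_labels
#' @param graph The parent [pathway_graph].
#' @param subpathway One-row subpathway table.
#' @param n_perm Number of random sets (default 1000).
#' @return p-value `M/N`, or `NA` (with a warning) if fewer than `n` genes
#'   are reachable from the seed.
#' @export
permtest_within_pathway <- function(graph, z, labels, subpathway,
                                    n_perm = 1000L, seed = NULL, divisor = "n") {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  is_poor <- as_poor(labels)
  genes <- subpathway$genes[[1L]]
  n <- length(genes)
  seed_gene <- subpathway$seed[1L]
  seed_idx <- match(seed_gene, graph$genes)
  if (is.na(seed_idx)) stop("seed gene ", seed_gene, " not in pathway ", graph$pathway_id)
  allowed <- which(graph$genes %in% rownames(z))
  real <- abs(discriminative_score(subpathway_activity(z, genes, divisor),
                                   labels, "signed_t"))
  M <- 0L
  failed <- FALSE
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- random_connected_set(graph, seed_idx, n, allowed)
      if (is.null(idx)) { failed <- TRUE; break }
      sc <- abs(discriminative_score(
        subpathway_activity(z, graph$genes[idx], divisor), labels, "signed_t"))
      if (sc > real) M <- M + 1L
    }
  })
  if (failed) {
    warning("pathway ", graph$pathway_id, ": fewer than ", n,
            " genes reachable from seed ", seed_gene, "; p3 undefined")
    return(NA_real_)
  }
  M / n_perm
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement; input order
#' is preserved. Thin wrapper over [stats::p.adjust()] with validation.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the three permutation tests and assemble significance records
#'
#' @inheritParams permtest_gene_labels
#' @param n_perm Integer vector of length 3: permutation counts for the
#'   gene-label, class-label and within-pathway tests (defaults
#'   `c(10000, 1000, 1000)`).
#' @param thresholds FDR cut-offs applied jointly (strict `<`) to the
#'   three adjusted values; defaults `c(1e-4, 1e-3, 1e-3)`.
#' @return Data.frame `subpathway_id, p1, p2, p3, fdr1, fdr2, fdr3, pass`.
#'   Subpathways with an undefined p3 get `pass = FALSE`.
#' @export
significance_test <- function(graphs, z, labels, subpathways,
                              n_perm = c(10000L, 1000L, 1000L), seed = NULL,
                              thresholds = c(1e-4, 1e-3, 1e-3),
                              scope = "global", divisor = "n") {
  stopifnot(length(n_perm) == 3L, length(thresholds) == 3L)
  by_id <- stats::setNames(graphs, vapply(graphs, `[[`, character(1), "pathway_id"))
  p1 <- permtest_gene_labels(graphs, z, labels, subpathways, n_perm[1L],
                             derive_seed(seed, 1L), scope, divisor)
  p2 <- permtest_class_labels(z, labels, subpathways, n_perm[2L],
                              derive_seed(seed, 2L), divisor)
  p3 <- vapply(seq_len(nrow(subpathways)), function(i) {
    permtest_within_pathway(by_id[[subpathways$pathway_id[i]]], z, labels,
                            subpathways[i, , drop = FALSE], n_perm[3L],
                            derive_seed(seed, 100L + i), divisor)
  }, numeric(1))
  ok3 <- !is.na(p3)
  fdr3 <- rep(NA_real_, length(p3))
  fdr3[ok3] <- bh_fdr(p3[ok3])
  rec <- data.frame(
    subpathway_id = subpathways$subpathway_id,
    p1 = p1, p2 = p2, p3 = p3,
    fdr1 = bh_fdr(p1), fdr2 = bh_fdr(p2), fdr3 = fdr3,
    stringsAsFactors = FALSE
  )
  rec$pass <- ok3 & rec$fdr1 < thresholds[1L] & rec$fdr2 < thresholds[2L] &
    rec$fdr3 < thresholds[3L]
  rec
}

#' Filter significance records at the triple-FDR thresholds
#'
#' @param records Data.frame from [significance_test()].
#' @param thresholds FDR cut-offs (strict `<`) for fdr1, fdr2, fdr3.
#' @return Character vector of surviving subpathway ids.
#' @export
filter_significant <- function(records, thresholds = c(1e-4, 1e-3, 1e-3)) {
  if (!nrow(records)) return(character(0))
  keep <- !is.na(records$fdr3) &
    records$fdr1 < thresholds[1L] &
    records$fdr2 < thresholds[2L] &
    records$fdr3 < thresholds[3L]
  records$subpathway_id[keep]
}
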