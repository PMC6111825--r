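# Synthetic cohorts with planted discriminative subpathways.
#
# The generator emulates the data model the method consumes: a collection
# of connected, undirected pathway graphs; log2-scale expression that is
# standard normal per gene; a binary good/poor prognosis label; planted
# connected modules whose genes are mean-shifted in the poor class on the
# per-gene sd scale; and right-censored exponential survival whose
# log-hazard is tied to the planted module activity.

#' Simulation configuration
#'
#' @param n_pathways Number of pathway graphs (default 8).
#' @param genes_per_pathway Genes per pathway (default 20).
#' @param extra_edge_fraction Extra random edges added on top of a random
#'   spanning tree, as a fraction of the gene count (default 0.2).
#' @param n_per_class Samples per prognosis class (default 50).
#' @param planted List of planted modules, each
#'   `list(pathway = <index>, module_size = <int>, delta = <shift in
#'   per-gene sd units>)`. Default: one 5-gene module with delta 3 in
#'   pathway 1.
#' @param baseline_hazard Exponential baseline hazard per month (default
#'   `log(2)/80`, i.e. 80-month median survival at baseline).
#' @param beta_true Log-hazard slope on the planted-module activity
#'   (default 1).
#' @param censoring_rate Target fraction of censored subjects under
#'   independent uniform censoring (default 0.3).
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_pathways = 8L, genes_per_pathway = 20L,
                              extra_edge_fraction = 0.2, n_per_class = 50L,
                              planted = list(list(pathway = 1L,
                                                  module_size = 5L,
                                                  delta = 3)),
                              baseline_hazard = log(2) / 80,
                              beta_true = 1, censoring_rate = 0.3,
                              seed = 1L) {
  stopifnot(n_pathways >= 1L, genes_per_pathway >= 2L,
            extra_edge_fraction >= 0, n_per_class >= 2L,
            baseline_hazard > 0, censoring_rate >= 0, censoring_rate < 1)
  for (p in planted) {
    stopifnot(p$pathway >= 1L, p$pathway <= n_pathways, p$delta >= 0)
    if (p$module_size > genes_per_pathway) {
      stop("planted module_size exceeds genes_per_pathway")
    }
  }
  structure(list(n_pathways = as.integer(n_pathways),
                 genes_per_pathway = as.integer(genes_per_pathway),
                 extra_edge_fraction = extra_edge_fraction,
                 n_per_class = as.integer(n_per_class),
                 planted = planted, baseline_hazard = baseline_hazard,
                 beta_true = beta_true, censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Connected random graph: uniform random spanning tree plus extra edges.
random_pathway_graph <- function(pathway_id, genes, extra_edge_fraction) {
  n <- length(genes)
  g <- igraph::sample_tree(n)
  extra <- round(extra_edge_fraction * n)
  if (extra > 0) {
    full <- utils::combn(n, 2L)
    have <- igraph::as_edgelist(g)
    have_key <- paste(pmin(have[, 1], have[, 2]), pmax(have[, 1], have[, 2]))
    free <- which(!(paste(full[1L, ], full[2L, ]) %in% have_key))
    take <- free[sample.int(length(free), min(extra, length(free)))]
    g <- igraph::add_edges(g, as.vector(full[, take, drop = FALSE]))
  }
  el <- igraph::as_edgelist(g)
  pathway_graph(pathway_id, genes,
                cbind(genes[el[, 1L]], genes[el[, 2L]]))
}

#' Simulate a cohort with planted prognostic subpathways
#'
#' @param config A [simulation_config()].
#' @return List of class `synthetic_cohort`: `graphs` (pathway graphs),
#'   `expression` (genes x samples, log2 scale), `clinical` (data.frame
#'   `sample, time_months, event, label`), `truth` (per planted module:
#'   pathway id, gene set, delta).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    graphs <- list()
    for (p in seq_len(config$n_pathways)) {
      pid <- sprintf("P%02d", p)
      genes <- sprintf("%sG%03d", pid, seq_len(config$genes_per_pathway))
      graphs[[pid]] <- random_pathway_graph(pid, genes,
                                            config$extra_edge_fraction)
    }
    n <- 2L * config$n_per_class
    samples <- sprintf("S%03d", seq_len(n))
    labels <- rep(c("good", "poor"), each = config$n_per_class)
    all_genes <- unlist(lapply(graphs, `[[`, "genes"), use.names = FALSE)
    expr <- matrix(stats::rnorm(length(all_genes) * n), nrow = length(all_genes),
                   dimnames = list(all_genes, samples))
    truth <- list()
    planted_activity <- rep(0, n)
    for (p in config$planted) {
      g <- graphs[[p$pathway]]
      seed_idx <- sample.int(length(g$genes), 1L)
      idx <- random_connected_set(g, seed_idx, p$module_size)
      if (is.null(idx)) stop("could not grow a connected planted module")
      mod <- g$genes[idx]
      expr[mod, labels == "poor"] <- expr[mod, labels == "poor"] + p$delta
      truth[[length(truth) + 1L]] <- list(pathway = g$pathway_id,
                                          genes = mod, delta = p$delta)
      planted_activity <- planted_activity + colMeans(expr[mod, , drop = FALSE])
    }
    if (length(truth)) {
      planted_activity <- planted_activity - mean(planted_activity)
    }
    rate <- config$baseline_hazard * exp(config$beta_true * planted_activity)
    t_event <- stats::rexp(n, rate = rate)
    if (config$censoring_rate > 0) {
      lam <- mean(rate)
      # Solve P(U(0,u) < T) = censoring_rate for exponential(lam) times.
      f <- function(u) (1 - exp(-lam * u)) / (lam * u) - config$censoring_rate
      u_max <- stats::uniroot(f, c(1e-6, 1e6 / lam))$root
      t_cens <- stats::runif(n, 0, u_max)
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n)
      time <- t_event
    }
    clinical <- data.frame(sample = samples,
                           time_months = pmax(time, 1e-3),
                           event = event, label = labels,
                           stringsAsFactors = FALSE)
    structure(list(graphs = graphs, expression = expr, clinical = clinical,
                   truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

#' Write a synthetic cohort in the pipeline's file formats
#'
#' Produces `pathways.tsv` (edge list), `expression.tsv`, `clinical.tsv`
#' and `truth.json` under `dir`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param header Optional comment line for the TSV headers.
#' @return Named character vector of the four file paths.
#' @export
write_cohort <- function(cohort, dir, header = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(pathways = file.path(dir, "pathways.tsv"),
             expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_pathway_edgelists(cohort$graphs, paths["pathways"], header = header)
  write_matrix_tsv(cohort$expression, paths["expression"], id_col = "gene",
                   header = header)
  con <- file(paths["clinical"], "w")
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(cohort$clinical, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  jsonlite::write_json(cohort$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}
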