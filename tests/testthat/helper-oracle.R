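# Independent oracles for the core statistics, deliberately written with
# different primitives than the package implementation.

# Combined z-score via per-sample apply/mean.
oracle_activity <- function(z, genes) {
  apply(z[genes, , drop = FALSE], 2, mean)
}

# Welch t via stats::t.test, oriented poor minus good.
oracle_t <- function(a, labels) {
  unname(stats::t.test(a[labels == "poor"], a[labels == "good"])$statistic)
}

# Textbook two-group log-rank: loop over distinct event times, accumulate
# observed minus expected events and the hypergeometric variance.
oracle_logrank_chi2 <- function(time, event, group) {
  g1 <- sort(unique(group))[1L]
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Hand product-limit estimator on the distinct event times.
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  list(time = ts, surv = surv)
}

# Connectivity of the induced subgraph, via igraph.
oracle_connected <- function(graph, genes) {
  g <- igraph::graph_from_edgelist(graph$edges, directed = FALSE)
  g <- g + igraph::vertices(setdiff(graph$genes, c(graph$edges)))
  sub <- igraph::induced_subgraph(g, genes)
  igraph::is_connected(sub)
}

# Random connected test graph on <= `n` nodes with single-letter genes.
random_test_graph <- function(n, seed, extra = 0.3, id = "T") {
  set.seed(seed)
  genes <- LETTERS[seq_len(n)]
  tree <- igraph::as_edgelist(igraph::sample_tree(n))
  edges <- cbind(genes[tree[, 1L]], genes[tree[, 2L]])
  n_extra <- round(extra * n)
  if (n_extra > 0 && n > 2) {
    all_pairs <- t(utils::combn(genes, 2L))
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    free <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in% key), ,
                      drop = FALSE]
    if (nrow(free)) {
      take <- sample.int(nrow(free), min(n_extra, nrow(free)))
      edges <- rbind(edges, free[take, , drop = FALSE])
    }
  }
  pathway_graph(id, genes, edges)
}

# z-like matrix: iid N(0,1) per gene, `shift_genes` shifted by `delta` in
# the poor class, then z-normalized.
make_z <- function(genes, n_per_class, shift_genes = character(0), delta = 0,
                   seed = 1) {
  set.seed(seed)
  n <- 2L * n_per_class
  m <- matrix(rnorm(length(genes) * n), nrow = length(genes),
              dimnames = list(genes, sprintf("S%03d", seq_len(n))))
  labels <- rep(c("good", "poor"), each = n_per_class)
  m[shift_genes, labels == "poor"] <- m[shift_genes, labels == "poor"] + delta
  list(z = normalize_expression(m), labels = labels)
}

# Exponential survival with log-hazard beta * x and uniform censoring.
sim_survival <- function(x, beta, n, seed, base = 0.02, censor_max = Inf) {
  set.seed(seed)
  t_event <- rexp(n, rate = base * exp(beta * x))
  if (is.finite(censor_max)) {
    cens <- runif(n, 0, censor_max)
    list(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
  } else {
    list(time = t_event, event = rep(1L, n))
  }
}
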