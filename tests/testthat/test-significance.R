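# Shared planted-signal setup: a small signal graph plus a larger pure-
# noise graph so the gene-label permutation pool is mostly null.
sig_setup <- function(delta = 3, seed = 201) {
  g <- random_test_graph(10, seed = seed, id = "SIG")
  gn0 <- random_test_graph(26, seed = seed + 500, id = "NOISE", extra = 0.2)
  gn <- pathway_graph("NOISE", paste0("n", gn0$genes),
                      cbind(paste0("n", gn0$edges[, 1]),
                            paste0("n", gn0$edges[, 2])))
  sim <- make_z(c(g$genes, gn$genes), n_per_class = 20,
                shift_genes = g$genes[1:4], delta = delta, seed = seed + 1)
  sp <- greedy_search(g, sim$z, sim$labels, search_config(min_size = 3))
  list(g = g, gn = gn, z = sim$z, labels = sim$labels, sp = sp)
}

test_that("a dominant real score gives p = 0 in all three tests", {
  s <- sig_setup(delta = 4)
  expect_gt(nrow(s$sp), 0L)
  top <- s$sp[which.max(s$sp$abs_score), , drop = FALSE]
  p1 <- permtest_gene_labels(list(s$g, s$gn), s$z, s$labels, top, n_perm = 100,
                             seed = 1)
  p2 <- permtest_class_labels(s$z, s$labels, top, n_perm = 100, seed = 2)
  p3 <- permtest_within_pathway(s$g, s$z, s$labels, top, n_perm = 100, seed = 3)
  expect_equal(p1, 0)
  expect_equal(p2, 0)
  expect_lte(p3, 0.05)
})

test_that("a subpathway spanning the whole gene pool is permutation-invariant", {
  # every global reassignment maps the full pool onto itself, so no
  # permuted score can strictly exceed the real one: p1 = 0 exactly
  s <- sig_setup(delta = 1)
  pool <- c(s$g$genes, s$gn$genes)
  sp <- data.frame(subpathway_id = "all", pathway_id = "SIG", seed = "A",
                   n = length(pool), score = 1, abs_score = 1,
                   stringsAsFactors = FALSE)
  sp$genes <- I(list(pool))
  expect_equal(permtest_gene_labels(list(s$g, s$gn), s$z, s$labels, sp,
                                    n_perm = 50, seed = 3), 0)
})

test_that("a null real score drives the class-permutation p toward 1", {
  # real t == 0 exactly (equal class means on distinct values), so almost
  # every relabelling scores strictly higher
  vals <- 1:20
  poor_idx <- c(1, 4, 5, 8, 9, 12, 13, 16, 17, 20)  # sums to 105 = total/2
  labels <- ifelse(seq_along(vals) %in% poor_idx, "poor", "good")
  z <- rbind(A = as.numeric(vals))
  colnames(z) <- paste0("s", 1:20)
  sp <- data.frame(subpathway_id = "x", pathway_id = "P", seed = "A", n = 1L,
                   score = 0, abs_score = 0, stringsAsFactors = FALSE)
  sp$genes <- I(list("A"))
  expect_equal(discriminative_score(z["A", ], labels, "signed_t"), 0)
  p2 <- permtest_class_labels(z, labels, sp, n_perm = 200, seed = 4)
  expect_gte(p2, 0.9)
  # the p = M/N counting rule itself, on a case where every permuted score
  # is bounded by the real one: a constant activity row scores 0 always
  zc <- rbind(A = rep(c(1, -1, 2, 0), 2), B = rep(c(-1, 1, -2, 0), 2))
  colnames(zc) <- paste0("s", 1:8)
  labels8 <- rep(c("poor", "good"), each = 4)
  spc <- sp; spc$genes <- I(list(c("A", "B")))
  # A + B cancel: activity identically 0, permuted t always 0, never > 0
  expect_equal(permtest_class_labels(zc, labels8, spc, n_perm = 100, seed = 5), 0)
})

test_that("within-pathway test is degenerate when the subpathway is the whole component", {
  g <- pathway_graph("P", c("A", "B", "C"), cbind(c("A", "B"), c("B", "C")))
  sim <- make_z(c("A", "B", "C"), n_per_class = 10, seed = 7)
  sp <- data.frame(subpathway_id = "all", pathway_id = "P", seed = "A", n = 3L,
                   score = 1, abs_score = 1, stringsAsFactors = FALSE)
  sp$genes <- I(list(c("A", "B", "C")))
  # every random size-3 set from the 3-node component is the real set
  expect_equal(permtest_within_pathway(g, sim$z, sim$labels, sp,
                                       n_perm = 50, seed = 5), 0)
})

test_that("unreachable sizes flag p3 as NA with a warning", {
  # two components: seed component has only 2 genes, subpathway asks for 3
  g <- pathway_graph("P", c("A", "B", "C", "D"),
                     cbind(c("A", "C"), c("B", "D")))
  sim <- make_z(c("A", "B", "C", "D"), n_per_class = 10, seed = 8)
  sp <- data.frame(subpathway_id = "x", pathway_id = "P", seed = "A", n = 3L,
                   score = 1, abs_score = 1, stringsAsFactors = FALSE)
  sp$genes <- I(list(c("A", "B", "C")))
  expect_warning(p3 <- permtest_within_pathway(g, sim$z, sim$labels, sp,
                                               n_perm = 20, seed = 6),
                 "reachable")
  expect_true(is.na(p3))
})

test_that("permutation engines are seed-reproducible", {
  s <- sig_setup(delta = 1, seed = 301)
  sp <- s$sp[seq_len(min(3L, nrow(s$sp))), ]
  a <- permtest_gene_labels(list(s$g), s$z, s$labels, sp, n_perm = 50, seed = 9)
  b <- permtest_gene_labels(list(s$g), s$z, s$labels, sp, n_perm = 50, seed = 9)
  expect_identical(a, b)
  a3 <- permtest_within_pathway(s$g, s$z, s$labels, sp[1, ], n_perm = 50, seed = 9)
  b3 <- permtest_within_pathway(s$g, s$z, s$labels, sp[1, ], n_perm = 50, seed = 9)
  expect_identical(a3, b3)
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # independent step-up oracle on random input
  set.seed(10)
  p <- runif(20)
  m <- length(p)
  o <- order(p)
  adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
  oracle <- numeric(m); oracle[o] <- pmin(adj, 1)
  expect_equal(bh_fdr(p), oracle)
})

test_that("the triple-FDR filter requires all three strict inequalities", {
  rec <- data.frame(
    subpathway_id = c("a", "b", "c"),
    p1 = 0, p2 = 0, p3 = 0,
    fdr1 = c(0, 5e-5, 5e-5),
    fdr2 = c(0, 1e-3, 5e-4),
    fdr3 = c(0, 1e-4, 1e-4),
    stringsAsFactors = FALSE)
  # b fails: fdr2 is not strictly below 1e-3
  expect_equal(filter_significant(rec), c("a", "c"))
  expect_equal(filter_significant(rec[0, ]), character(0))
})

test_that("significance_test assembles consistent records", {
  s <- sig_setup(delta = 3, seed = 401)
  rec <- significance_test(list(s$g, s$gn), s$z, s$labels, s$sp,
                           n_perm = c(100, 100, 100), seed = 11)
  expect_equal(nrow(rec), nrow(s$sp))
  expect_true(all(rec$p1 >= 0 & rec$p1 <= 1))
  expect_true(all(rec$fdr2 >= 0 & rec$fdr2 <= 1, na.rm = TRUE))
  expect_identical(filter_significant(rec), rec$subpathway_id[rec$pass])
  # the strongly planted top subpathway must pass at the default thresholds
  top <- which.max(s$sp$abs_score)
  expect_true(rec$pass[top])
})
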