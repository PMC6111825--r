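test_that("cox_beta fits a univariate proportional-hazards coefficient", {
  x <- rep(c(0, 1), each = 100)
  sv <- sim_survival(x, beta = log(2), n = 200, seed = 41, censor_max = 200)
  fit <- cox_beta(x, sv$time, sv$event)
  expect_equal(fit$hr, exp(fit$beta))
  expect_true(fit$ci[1] < fit$hr && fit$hr < fit$ci[2])
  # negating the covariate flips the coefficient exactly
  fit2 <- cox_beta(-x, sv$time, sv$event)
  expect_equal(fit2$beta, -fit$beta, tolerance = 1e-8)
  expect_error(cox_beta(x, sv$time, rep(0, 200)), "events")
  expect_error(cox_beta(rep(1, 200), sv$time, sv$event), "constant")
})

test_that("combination enumeration is complete and deterministically ordered", {
  ids9 <- paste0("sp", 1:9)
  combos <- enumerate_combinations(ids9)
  expect_length(combos, 511L)
  expect_length(enumerate_combinations("only"), 1L)
  expect_length(enumerate_combinations(paste0("s", 1:4)), 15L)
  # ordered by size then lexicographically; no duplicates
  expect_equal(lengths(combos), sort(lengths(combos)))
  keys <- vapply(combos, paste, character(1), collapse = ";")
  expect_false(anyDuplicated(keys) > 0)
  expect_identical(combos, enumerate_combinations(rev(ids9)))
  expect_error(enumerate_combinations(character(0)), "at least one")
  expect_error(enumerate_combinations(paste0("x", 1:21)), "refusing")
})

test_that("risk scores are the Cox-weighted linear combination", {
  A <- rbind(a = c(0.5, 0, 1), b = c(0.2, 0, 2))
  colnames(A) <- paste0("s", 1:3)
  beta <- c(a = 1, b = -1)
  expect_equal(unname(risk_scores(beta, A)), c(0.3, 0, -1))
  expect_equal(risk_scores(beta, 2 * A), 2 * risk_scores(beta, A))
  expect_error(risk_scores(c(zz = 1), A), "zz")
})

test_that("median split uses a strict cutoff and honours a frozen one", {
  sc <- setNames(c(1, 2, 3, 4, 5), paste0("s", 1:5))
  sp <- median_split(sc)
  expect_equal(sp$group, c("low", "low", "low", "high", "high"))
  expect_equal(median_split(setNames(0.2, "x"), cutoff = 0.1067)$group, "high")
  expect_true(all(median_split(rep(1, 4))$group == "low"))
  expect_error(median_split(numeric(0)), "no scores")
  # invariance under a strictly increasing transform of scores and cutoff
  tr <- function(v) exp(v) + v
  expect_equal(median_split(tr(sc), cutoff = tr(3))$group,
               median_split(sc, cutoff = 3)$group)
})

# Activity fixture with one truly prognostic row among noise rows, and
# survival driven by that row.
sig_fixture <- function(k, n, seed, beta = 1.2) {
  set.seed(seed)
  A <- matrix(rnorm(k * n), nrow = k,
              dimnames = list(paste0("sp", seq_len(k)), paste0("s", seq_len(n))))
  sv <- sim_survival(A["sp1", ], beta = beta, n = n, seed = seed + 1,
                     censor_max = 150)
  sp <- data.frame(subpathway_id = rownames(A), pathway_id = "P",
                   seed = "g", n = 4L, score = 0, abs_score = 0,
                   stringsAsFactors = FALSE)
  sp$genes <- I(replicate(k, paste0("g", 1:4), simplify = FALSE))
  list(A = A, time = sv$time, event = sv$event, sp = sp)
}

test_that("the best signature contains the planted prognostic subpathway", {
  fx <- sig_fixture(3, 200, seed = 50)
  res <- select_best_signature(rownames(fx$A), fx$sp, fx$A, fx$time, fx$event)
  members <- vapply(res$signature$members, `[[`, character(1), "id")
  expect_true("sp1" %in% members)
  expect_equal(nrow(res$report), 3L)       # one row per subset size
  expect_equal(res$report$size, 1:3)
  # k = 1 trivially selects that subpathway
  res1 <- select_best_signature("sp1", fx$sp, fx$A, fx$time, fx$event)
  expect_equal(vapply(res1$signature$members, `[[`, character(1), "id"), "sp1")
})

test_that("select_best_signature matches a brute-force loop over subsets", {
  fx <- sig_fixture(5, 120, seed = 60)
  res <- select_best_signature(rownames(fx$A), fx$sp, fx$A, fx$time, fx$event)
  # independent oracle loop: refit betas, score every subset directly
  beta <- vapply(rownames(fx$A), function(id) {
    unname(coef(survival::coxph(survival::Surv(fx$time, fx$event) ~ fx$A[id, ])))
  }, numeric(1))
  best_p <- Inf
  ids <- rownames(fx$A)
  for (mask in 1:(2^5 - 1)) {
    s <- ids[bitwAnd(mask, 2^(0:4)) > 0]
    sc <- colSums(fx$A[s, , drop = FALSE] * beta[s])
    grp <- sc > median(sc)
    if (length(unique(grp)) < 2) next
    sd <- survival::survdiff(survival::Surv(fx$time, fx$event) ~ grp)
    p <- pchisq(sd$chisq, 1, lower.tail = FALSE)
    if (p < best_p) best_p <- p
  }
  expect_equal(res$best_p, best_p, tolerance = 1e-12)
})

test_that("applying a signature to its training cohort reproduces the groups", {
  g <- random_test_graph(10, seed = 70, id = "TP")
  sim <- make_z(g$genes, n_per_class = 30, shift_genes = g$genes[1:4],
                delta = 2, seed = 71)
  sp <- greedy_search(g, sim$z, sim$labels, search_config(min_size = 3))
  A <- build_activity_matrix(sim$z, sp)
  sv <- sim_survival(A[1, ], beta = 1, n = ncol(A), seed = 72, censor_max = 200)
  ids <- sp$subpathway_id[seq_len(min(4L, nrow(sp)))]
  res <- select_best_signature(ids, sp, A, sv$time, sv$event)
  risk_direct <- median_split(
    risk_scores(setNames(vapply(res$signature$members, `[[`, numeric(1), "beta"),
                         vapply(res$signature$members, `[[`, character(1), "id")),
                A),
    cutoff = res$signature$cutoff)
  risk_applied <- apply_signature(res$signature, sim$z)
  expect_equal(risk_applied$group, risk_direct$group)
  expect_equal(risk_applied$score, risk_direct$score, tolerance = 1e-12)
})

test_that("missing signature genes fall back to the present members", {
  sig <- structure(list(
    members = list(list(id = "m1", pathway = "P",
                        genes = c("A", "B", "C"), beta = 1)),
    cutoff = 0, divisor = "n"), class = "subpathway_signature")
  z <- rbind(A = c(1, -1), B = c(3, 1))
  colnames(z) <- c("s1", "s2")
  expect_warning(risk <- apply_signature(sig, z), "missing")
  expect_equal(risk$score, unname(colMeans(z)))   # averaged over A, B only
  z_none <- rbind(X = c(1, 2)); colnames(z_none) <- c("s1", "s2")
  expect_error(apply_signature(sig, z_none), "none of its genes")
})

test_that("signatures round-trip through JSON", {
  sig <- structure(list(
    members = list(list(id = "m1", pathway = "P1",
                        genes = c("A", "B"), beta = 1.25),
                   list(id = "m2", pathway = "P2",
                        genes = c("C"), beta = -0.5)),
    cutoff = 0.1067, divisor = "n"), class = "subpathway_signature")
  f <- tempfile(fileext = ".json")
  write_signature(sig, f, meta = list(note = "test"))
  back <- read_signature(f)
  expect_equal(back$cutoff, sig$cutoff)
  expect_equal(back$divisor, sig$divisor)
  expect_equal(back$members, sig$members)
})
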