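# Cox-weighted subpathway risk-score signature.
#
# Risk score of sample j: sum over signature members k of beta_k * a_kj,
# where beta_k is the univariate Cox coefficient of member k's activity on
# overall survival in the training cohort. Patients strictly above the
# training-median risk score are called high risk; the median is frozen
# with the signature and reused verbatim on external cohorts.

#' Univariate Cox coefficient of an activity vector
#'
#' Fits a univariate Cox proportional-hazards model of overall survival on
#' one subpathway's activity by partial-likelihood maximization.
#'
#' @param activity Numeric covariate vector.
#' @param time Survival times (months), positive.
#' @param event Event indicator (1 = death, 0 = censored).
#' @return List `beta`, `hr` (= exp(beta)), `ci` (Wald 95\% CI on the HR),
#'   `p` (Wald), `se`.
#' @export
cox_beta <- function(activity, time, event) {
  if (sum(event) < 1L) stop("cox_beta: no events in the survival data")
  if (stats::var(activity) == 0) stop("cox_beta: constant covariate")
  fit <- survival::coxph(survival::Surv(time, event) ~ activity)
  beta <- unname(stats::coef(fit)[1L])
  se <- sqrt(unname(stats::vcov(fit)[1L, 1L]))
  z <- beta / se
  list(beta = beta, hr = exp(beta),
       ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
       p = 2 * stats::pnorm(-abs(z)), se = se)
}

#' Enumerate all non-empty subsets of subpathway ids
#'
#' Deterministic order: by subset size, then lexicographically within a
#' size. Nine ids yield 511 candidate signatures.
#'
#' @param ids Character vector of 1--20 distinct ids.
#' @return List of character vectors, length `2^k - 1`.
#' @export
enumerate_combinations <- function(ids) {
  k <- length(ids)
  if (k < 1L) stop("need at least one id")
  if (k > 20L) stop("refusing to enumerate 2^", k, " - 1 subsets")
  if (anyDuplicated(ids)) stop("ids must be distinct")
  ids <- sort(ids)
  out <- list()
  for (size in seq_len(k)) {
    sets <- utils::combn(ids, size, simplify = FALSE)
    ord <- order(vapply(sets, paste, character(1), collapse = "\r"))
    out <- c(out, sets[ord])
  }
  out
}

#' Risk scores from member activities and Cox weights
#'
#' @param beta Named numeric vector of coefficients (names = member ids).
#' @param activity Activity matrix containing all member rows.
#' @return Named numeric vector of per-sample risk scores.
#' @export
risk_scores <- function(beta, activity) {
  miss <- setdiff(names(beta), rownames(activity))
  if (length(miss)) stop("member(s) missing from activity matrix: ",
                         paste(miss, collapse = ", "))
  s <- drop(beta %*% activity[names(beta), , drop = FALSE])
  stats::setNames(as.numeric(s), colnames(activity))
}

#' Split samples at a risk-score cutoff
#'
#' High risk iff score strictly exceeds the cutoff; the cutoff defaults to
#' the median of the supplied scores and, once frozen in a signature, is
#' reused verbatim for external cohorts.
#'
#' @param scores Named numeric vector of risk scores.
#' @param cutoff Optional frozen cutoff; default `median(scores)`.
#' @return Data.frame `sample, score, group` with group in
#'   `{"high","low"}`.
#' @export
median_split <- function(scores, cutoff = NULL) {
  if (!length(scores)) stop("no scores to split")
  if (is.null(cutoff)) {
    if (length(scores) < 2L) stop("need >= 2 samples to compute a median cutoff")
    cutoff <- stats::median(scores)
  }
  data.frame(sample = names(scores) %||% as.character(seq_along(scores)),
             score = as.numeric(scores),
             group = ifelse(scores > cutoff, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Select the best subpathway combination as the final signature
#'
#' Fits a univariate Cox coefficient per candidate subpathway on the
#' training cohort, then enumerates every non-empty combination: each is
#' scored by risk-score median split followed by a two-group log-rank
#' test. The combination with the smallest log-rank p wins (ties break to
#' the smaller subset, then lexicographic member order); the best subset
#' per size is reported alongside. The winner is frozen as a signature
#' carrying its members' gene sets, coefficients and the training median
#' cutoff.
#'
#' @param ids Candidate subpathway ids (typically the RF-selected set).
#' @param subpathways Subpathway table carrying the gene sets.
#' @param activity Activity matrix (training cohort).
#' @param time,event Training survival data aligned to activity columns.
#' @param divisor Eq-1 divisor mode recorded in the signature.
#' @return List: `signature` (class `subpathway_signature`: `members` with
#'   id/pathway/genes/beta, `cutoff`, `divisor`), `report` (best subset
#'   per size: `size, members, logrank_p`), `best_p`.
#' @export
select_best_signature <- function(ids, subpathways, activity, time, event,
                                  divisor = "n") {
  stopifnot(length(ids) >= 1L)
  rows <- match(ids, subpathways$subpathway_id)
  if (anyNA(rows)) stop("id(s) absent from subpathway table: ",
                        paste(ids[is.na(rows)], collapse = ", "))
  beta_all <- vapply(ids, function(id) {
    cox_beta(activity[id, ], time, event)$beta
  }, numeric(1))
  subsets <- enumerate_combinations(ids)
  res_p <- rep(NA_real_, length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    sc <- risk_scores(beta_all[s], activity)
    grp <- median_split(sc)
    if (length(unique(grp$group)) < 2L) {
      warning("subset {", paste(s, collapse = ","),
              "}: degenerate median split, skipped")
      next
    }
    res_p[i] <- logrank_test(grp$group, time, event)$p
  }
  if (all(is.na(res_p))) stop("no combination produced a valid log-rank test")
  sizes <- lengths(subsets)
  keys <- vapply(subsets, paste, character(1), collapse = ";")
  ord <- order(res_p, sizes, keys, na.last = TRUE)
  best <- ord[1L]
  report <- do.call(rbind, lapply(sort(unique(sizes)), function(sz) {
    sel <- which(sizes == sz)
    sel <- sel[order(res_p[sel], keys[sel], na.last = TRUE)][1L]
    data.frame(size = sz, members = keys[sel], logrank_p = res_p[sel],
               stringsAsFactors = FALSE)
  }))
  win <- subsets[[best]]
  members <- lapply(win, function(id) {
    r <- match(id, subpathways$subpathway_id)
    list(id = id, pathway = subpathways$pathway_id[r],
         genes = subpathways$genes[[r]], beta = unname(beta_all[id]))
  })
  cutoff <- stats::median(risk_scores(beta_all[win], activity))
  sig <- structure(list(members = members, cutoff = cutoff, divisor = divisor),
                   class = "subpathway_signature")
  list(signature = sig, report = report, best_p = res_p[best])
}

#' @export
print.subpathway_signature <- function(x, ...) {
  cat("<subpathway_signature> ", length(x$members), " member(s), cutoff ",
      signif(x$cutoff, 4), "\n", sep = "")
  for (m in x$members) {
    cat("  ", m$id, " (", m$pathway, "): beta=", signif(m$beta, 4),
        ", ", length(m$genes), " genes\n", sep = "")
  }
  invisible(x)
}

#' Apply a frozen signature to an external cohort
#'
#' Member activities are recomputed on the external cohort's own z-scores
#' (Eq-1 combined z-score over the member genes present in the matrix;
#' genes missing on the platform are skipped with a warning, a member with
#' no mapped genes is an error). Coefficients and the risk-score cutoff
#' are reused verbatim; nothing is refit.
#'
#' @param sig A `subpathway_signature`.
#' @param z Gene-by-sample z-score matrix of the external cohort.
#' @return Risk table as from [median_split()], plus an `activity`
#'   attribute holding the member-by-sample activity matrix.
#' @export
apply_signature <- function(sig, z) {
  A <- matrix(NA_real_, nrow = length(sig$members), ncol = ncol(z),
              dimnames = list(vapply(sig$members, `[[`, character(1), "id"),
                              colnames(z)))
  for (i in seq_along(sig$members)) {
    m <- sig$members[[i]]
    present <- intersect(m$genes, rownames(z))
    if (!length(present)) {
      stop("signature member ", m$id, ": none of its genes are in the matrix")
    }
    if (length(present) < length(m$genes)) {
      warning("signature member ", m$id, ": ",
              length(m$genes) - length(present),
              " gene(s) missing; activity averaged over ", length(present),
              " present gene(s)")
    }
    A[i, ] <- subpathway_activity(z, present, sig$divisor)
  }
  beta <- stats::setNames(vapply(sig$members, `[[`, numeric(1), "beta"),
                          rownames(A))
  out <- median_split(risk_scores(beta, A), cutoff = sig$cutoff)
  attr(out, "activity") <- A
  out
}

#' Write / read a signature as JSON
#'
#' @param sig A `subpathway_signature`.
#' @param path File path.
#' @param meta Optional named list of provenance metadata to embed.
#' @export
write_signature <- function(sig, path, meta = NULL) {
  obj <- list(
    members = lapply(sig$members, function(m) {
      list(id = m$id, pathway = m$pathway, genes = m$genes, beta = m$beta)
    }),
    cutoff = sig$cutoff, eq1_divisor = sig$divisor
  )
  if (!is.null(meta)) obj$created_from <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  obj <- jsonlite::read_json(path)
  members <- lapply(obj$members, function(m) {
    list(id = m$id, pathway = m$pathway,
         genes = unname(vapply(m$genes, identity, character(1))),
         beta = as.numeric(m$beta))
  })
  structure(list(members = members, cutoff = as.numeric(obj$cutoff),
                 divisor = obj$eq1_divisor %||% "n"),
            class = "subpathway_signature")
}

#' The four-subpathway breast cancer prognostic signature
#'
#' Loads the packaged reference table of the four-subpathway breast
#' cancer signature (hippo signalling, long-term depression, PI3K-Akt
#' signalling and purine metabolism subpathways) with its published
#' univariate Cox hazard ratios, risk-score coefficients and member gene
#' symbols.
#'
#' @return Data.frame `subpathway_id, pathway, hr, beta` plus a
#'   list-column `genes`.
#' @export
breast_signature <- function() {
  path <- system.file("extdata", "breast_signature_subpathways.tsv",
                      package = "subpathsig", mustWork = TRUE)
  df <- utils::read.delim(path, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  df$genes <- I(strsplit(df$genes, ";", fixed = TRUE))
  df
}
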