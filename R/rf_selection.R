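#' Iterative random-forest feature elimination
#'
#' Trains a random forest (via \pkg{ranger}) on the subpathway activity
#' matrix against the prognosis classes, estimates per-feature permutation
#' importance on out-of-bag samples, discards the least important third of
#' the features, and repeats until at most two features remain. The
#' out-of-bag (OOB) classification error is recorded after every fit; the
#' final feature set is picked from the trace by `stop_rule`.
#'
#' @param activity Subpathway-by-sample activity matrix.
#' @param labels Prognosis labels (`"good"`/`"poor"`) aligned to columns.
#' @param n_trees Trees per forest (default 10000, heavy but stable
#'   importance estimates; reduce for exploratory runs).
#' @param drop_fraction Fraction of features discarded per iteration;
#'   `floor(m * drop_fraction)` with a minimum drop of 1. Default 1/3.
#' @param seed Integer seed (forwarded to ranger per iteration).
#' @param stop_rule `"min_plus_se"` (default) selects the smallest
#'   retained set whose OOB error is within one standard error of the
#'   minimum trace error; `"min"` selects the set with the minimum error
#'   (smallest such set on ties).
#' @return List of class `elimination_trace`: `iterations` (data.frame
#'   `iteration, n_features, oob_error`), `retained` (list of id vectors
#'   per iteration), `importance` (list of named importance vectors),
#'   `selected` (chosen feature ids).
#' @export
rf_iterative_elimination <- function(activity, labels, n_trees = 10000L,
                                     drop_fraction = 1 / 3, seed = NULL,
                                     stop_rule = c("min_plus_se", "min")) {
  stop_rule <- match.arg(stop_rule)
  is_poor <- as_poor(labels)
  if (sum(is_poor) < 2L || sum(!is_poor) < 2L) {
    stop("each class needs at least 2 samples for the forest")
  }
  ids <- rownames(activity)
  if (is.null(ids)) stop("activity matrix needs rownames (subpathway ids)")
  if (length(ids) == 1L) {
    tr <- data.frame(iteration = 1L, n_features = 1L, oob_error = NA_real_)
    return(structure(list(iterations = tr, retained = list(ids),
                          importance = list(stats::setNames(NA_real_, ids)),
                          selected = ids),
                     class = "elimination_trace"))
  }
  y <- factor(ifelse(is_poor, "poor", "good"), levels = c("good", "poor"))
  retained <- ids
  trace <- list(); kept <- list(); imps <- list()
  it <- 0L
  repeat {
    it <- it + 1L
    m <- length(retained)
    df <- as.data.frame(t(activity[retained, , drop = FALSE]))
    colnames(df) <- paste0("f", seq_len(m))  # syntactic-safe names
    df$..class <- y
    fit <- ranger::ranger(
      dependent.variable.name = "..class", data = df,
      num.trees = n_trees, mtry = max(1L, floor(sqrt(m))),
      importance = "permutation",
      seed = if (is.null(seed)) NULL else derive_seed(seed, it)
    )
    imp <- stats::setNames(fit$variable.importance[paste0("f", seq_len(m))], retained)
    trace[[it]] <- data.frame(iteration = it, n_features = m,
                              oob_error = fit$prediction.error)
    kept[[it]] <- retained
    imps[[it]] <- imp
    if (m <= 2L) break
    drop_n <- max(1L, floor(m * drop_fraction))
    retained <- retained[order(-imp)][seq_len(m - drop_n)]
  }
  iterations <- do.call(rbind, trace)
  n_samp <- ncol(activity)
  err <- iterations$oob_error
  sel_it <- switch(stop_rule,
    min_plus_se = {
      i_min <- which.min(err)
      se <- sqrt(err[i_min] * (1 - err[i_min]) / n_samp)
      candidates <- which(err <= err[i_min] + se)
      candidates[which.min(iterations$n_features[candidates])]
    },
    min = {
      candidates <- which(err == min(err))
      candidates[which.min(iterations$n_features[candidates])]
    }
  )
  structure(list(iterations = iterations, retained = kept,
                 importance = imps, selected = kept[[sel_it]]),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat("<elimination_trace> ", nrow(x$iterations), " iterations; selected ",
      length(x$selected), " feature(s)\n", sep = "")
  print(x$iterations, row.names = FALSE)
  invisible(x)
}

#' Retained-set sizes implied by the drop schedule
#'
#' Pure arithmetic of the elimination rule: starting from `m0` features,
#' drop `floor(m * drop_fraction)` (at least 1) per iteration down to 2.
#'
#' @param m0 Starting feature count.
#' @param drop_fraction Fraction dropped per iteration.
#' @return Integer vector of retained sizes, starting at `m0`.
#' @export
elimination_schedule <- function(m0, drop_fraction = 1 / 3) {
  sizes <- m0 <- as.integer(m0)
  while (m0 > 2L) {
    m0 <- m0 - max(1L, floor(m0 * drop_fraction))
    sizes <- c(sizes, m0)
  }
  sizes
}
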