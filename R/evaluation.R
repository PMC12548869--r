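#' Edge-holdout split
#'
#' Removes a uniformly random set of `round(fraction * m)` edges from the
#' network.  The removed edges are the positives of the link-prediction
#' task; the negatives are all pairs never connected in the *original*
#' network, so the positives compete only with true non-edges.  The
#' candidate set of a score table computed on the training network is
#' exactly positives plus negatives.
#'
#' @param net a [bipartite_net()].
#' @param fraction fraction of edges to remove, in (0, 1); default 0.10.
#' @param seed integer seed.
#' @return an object of class `holdout_split`: `training` (a
#'   [bipartite_net()] with the same node sets), `positives` (two-column
#'   matrix of removed edges), and `original`.
#' @export
make_holdout <- function(net, fraction = 0.10, seed = NULL) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("`fraction` must be in (0, 1)", call. = FALSE)
  }
  m <- n_edges(net)
  n_remove <- round(fraction * m)
  if (n_remove < 1) {
    stop(sprintf("fraction %g of %d edges rounds to zero removals", fraction, m),
         call. = FALSE)
  }
  idx <- with_seed(seed, sample.int(m, n_remove))
  structure(list(training = drop_edges(net, idx),
                 positives = net$edges[idx, , drop = FALSE],
                 original = net),
            class = "holdout_split")
}

#' @export
print.holdout_split <- function(x, ...) {
  cat(sprintf("holdout split: %d training edges, %d held-out positives, %s negatives\n",
              n_edges(x$training), nrow(x$positives),
              format(unconnected_pair_count(x$original), big.mark = ",")))
  invisible(x)
}

# Align a score table with a split: returns scores and a positive/negative
# label per candidate, in deterministic (pair index) order.
split_labels <- function(scores, split) {
  pos_idx <- pair_index(split$original, split$positives[, 1],
                        split$positives[, 2])
  lab <- scores$pair_idx %in% pos_idx
  if (sum(lab) != nrow(split$positives)) {
    stop("score table does not cover all held-out positives", call. = FALSE)
  }
  if (!any(lab) || all(lab)) {
    stop("need at least one positive and one negative", call. = FALSE)
  }
  list(scores = scores$scores, labels = lab, pair_idx = scores$pair_idx)
}

#' Area under the ROC curve
#'
#' Computed through the rank-statistic (Mann-Whitney) equivalence: the
#' probability that a uniformly random positive outscores a uniformly
#' random negative, with ties counted one half.
#'
#' @param scores a [score_table][score_table_from_matrix()] computed on the
#'   training network of `split` (its candidates are then exactly the
#'   positives plus negatives).
#' @param split a [make_holdout()] split.
#' @return the AUROC, in `[0, 1]`.
#' @export
roc_auc <- function(scores, split) {
  al <- split_labels(scores, split)
  r <- rank(al$scores)           # average ranks handle ties as 1/2
  n_pos <- sum(al$labels)
  n_neg <- length(al$labels) - n_pos
  (sum(r[al$labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall metrics
#'
#' Ranks all candidates by decreasing score (ties broken by the
#' deterministic pair index) and reports:
#' \describe{
#'   \item{aupr}{average precision, in percent: the mean of the precision
#'     evaluated at each recalled positive.}
#'   \item{norm_aupr}{average precision divided by the prevalence
#'     (the precision of a no-skill classifier, which guesses correctly
#'     with probability equal to the candidate-set density) — the fold
#'     improvement over random guessing.}
#'   \item{topk}{precision over the top `k` predictions, in percent.}
#' }
#'
#' @inheritParams roc_auc
#' @param k top-k cutoff (default 100).
#' @return a named list with `aupr`, `norm_aupr`, `topk`.
#' @export
pr_metrics <- function(scores, split, k = 100) {
  if (k < 1) stop("`k` must be at least 1", call. = FALSE)
  al <- split_labels(scores, split)
  if (k > length(al$labels)) {
    stop(sprintf("k = %d exceeds the %d candidates", k, length(al$labels)),
         call. = FALSE)
  }
  ord <- order(-al$scores, al$pair_idx)
  lab <- al$labels[ord]
  hits <- cumsum(lab)
  prec_at_pos <- hits[lab] / which(lab)
  ap <- mean(prec_at_pos)
  prevalence <- sum(lab) / length(lab)
  list(aupr = 100 * ap,
       norm_aupr = ap / prevalence,
       topk = 100 * sum(lab[seq_len(k)]) / k)
}

#' Cross-validated benchmark of link predictors
#'
#' Repeats the edge-holdout protocol `n_reps` times and evaluates every
#' predictor on the *same* sequence of splits (a paired design, so
#' predictors can be compared repetition by repetition).  Per-repetition
#' seeds are derived deterministically from the master seed; a predictor
#' that draws random numbers sees a reproducible stream.
#'
#' @param net a [bipartite_net()].
#' @param predictors a named list of adapter functions, each taking a
#'   training [bipartite_net()] and returning a
#'   [score_table][score_table_from_matrix()] — any external method can be
#'   plugged in through this interface.
#' @param fraction holdout fraction (default 0.10).
#' @param n_reps repetitions (default 50).
#' @param k top-k cutoff (default 100).
#' @param seed master seed.
#' @return an object of class `eval_report`: `per_rep` (data.frame of
#'   per-repetition metrics, with failures recorded in the `error` column
#'   and excluded from means) and `summary` (mean and standard error,
#'   `sd / sqrt(n)`, of each metric per predictor).
#' @export
run_benchmark <- function(net, predictors, fraction = 0.10, n_reps = 50,
                          k = 100, seed = NULL) {
  if (length(predictors) == 0) stop("no predictors given", call. = FALSE)
  if (is.null(names(predictors)) || any(!nzchar(names(predictors)))) {
    stop("`predictors` must be a named list", call. = FALSE)
  }
  rep_seeds <- derive_seeds(seed, 2L * n_reps)
  rows <- list()
  for (i in seq_len(n_reps)) {
    split <- make_holdout(net, fraction, seed = rep_seeds[i])
    for (p in names(predictors)) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        tab <- with_seed(rep_seeds[n_reps + i], predictors[[p]](split$training))
        pr <- pr_metrics(tab, split, k)
        list(auroc = roc_auc(tab, split), aupr = pr$aupr,
             norm_aupr = pr$norm_aupr, topk = pr$topk, error = NA_character_)
      }, error = function(e) {
        list(auroc = NA_real_, aupr = NA_real_, norm_aupr = NA_real_,
             topk = NA_real_, error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- data.frame(
        predictor = p, rep = i, auroc = res$auroc, aupr = res$aupr,
        norm_aupr = res$norm_aupr, topk = res$topk,
        seconds = proc.time()[["elapsed"]] - t0, error = res$error,
        stringsAsFactors = FALSE)
    }
  }
  per_rep <- do.call(rbind, rows)
  se <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else NA_real_
  agg <- lapply(split(per_rep, per_rep$predictor), function(d) {
    ok <- d[is.na(d$error), , drop = FALSE]
    data.frame(predictor = d$predictor[1], n_ok = nrow(ok),
               auroc = mean(ok$auroc), auroc_se = se(ok$auroc),
               aupr = mean(ok$aupr), aupr_se = se(ok$aupr),
               norm_aupr = mean(ok$norm_aupr), norm_aupr_se = se(ok$norm_aupr),
               topk = mean(ok$topk), topk_se = se(ok$topk),
               seconds = mean(ok$seconds), stringsAsFactors = FALSE)
  })
  summary_df <- do.call(rbind, agg)
  summary_df <- summary_df[match(names(predictors), summary_df$predictor), ]
  rownames(summary_df) <- NULL
  structure(list(per_rep = per_rep, summary = summary_df,
                 fraction = fraction, n_reps = n_reps, k = k, seed = seed),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("benchmark: %d repetitions, %.0f%% of edges held out, top-%d precision\n\n",
              x$n_reps, 100 * x$fraction, x$k))
  s <- x$summary
  fmt <- function(m, e) {
    ifelse(is.na(m), "failed",
           sprintf("%.*f(%.0f)", digits, m,
                   round(e * 10^digits)))
  }
  out <- data.frame(method = s$predictor,
                    AUROC = fmt(s$auroc, s$auroc_se),
                    `AUPR%` = fmt(s$aupr, s$aupr_se),
                    norm.AUPR = fmt(s$norm_aupr, s$norm_aupr_se),
                    `top-k%` = fmt(s$topk, s$topk_se),
                    sec = sprintf("%.2f", s$seconds),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Upper bounds on missing edges and false positives
#'
#' If a fraction `mu` of the unconnected pairs are in truth edges, no
#' algorithm's measured AUROC can exceed `1 - mu/2`, because hidden true
#' edges sitting among the negatives are indistinguishable from held-out
#' positives.  Inverting: `mu <= 2 (1 - A)`.  The same argument applied to
#' the observed edges bounds the false-positive fraction `nu <= 2 (1 - A)`.
#'
#' @param A a measured (or extrapolated) AUROC, in `[0.5, 1]`.
#' @param unconnected_pairs number of unconnected pairs in the network.
#' @param m number of observed edges.
#' @return an object of class `bound_estimates`: `mu_max`, `nu_max`,
#'   `max_missing_pairs = round(mu_max * unconnected_pairs)`,
#'   `max_false_positives = round(nu_max * m)`, and the inputs.
#' @export
missing_edge_bound <- function(A, unconnected_pairs, m) {
  if (!(A >= 0.5 && A <= 1)) {
    stop("`A` must be in [0.5, 1]", call. = FALSE)
  }
  mu_max <- min(1, 2 * (1 - A))
  structure(list(A = A, mu_max = mu_max, nu_max = mu_max,
                 max_missing_pairs = round(mu_max * unconnected_pairs),
                 max_false_positives = round(mu_max * m),
                 unconnected_pairs = unconnected_pairs, m = m),
            class = "bound_estimates")
}

#' @export
print.bound_estimates <- function(x, ...) {
  cat(sprintf("AUROC %.4g implies:\n", x$A))
  cat(sprintf("  missing-edge fraction mu <= %.4g  (at most %s of %s unconnected pairs)\n",
              x$mu_max, format(x$max_missing_pairs, big.mark = ","),
              format(x$unconnected_pairs, big.mark = ",")))
  cat(sprintf("  false-positive fraction nu <= %.4g  (at most %s of %s observed edges)\n",
              x$nu_max, format(x$max_false_positives, big.mark = ","),
              format(x$m, big.mark = ",")))
  invisible(x)
}

#' Correct a measured precision for missing edges
#'
#' Hidden true edges among the negatives depress precision (and measures
#' proportional to it, such as AUPR and top-k precision) by a factor
#' `1 - mu`; the true value therefore lies between the measured value and
#' `measured / (1 - mu_max)`.
#'
#' @param measured measured precision (any precision-proportional metric,
#'   e.g. in percent).
#' @param mu_max upper bound on the missing-edge fraction, in `[0, 1)`.
#' @return a named numeric vector `c(lower, upper)`.
#' @export
precision_correction <- function(measured, mu_max) {
  if (!(mu_max >= 0 && mu_max < 1)) {
    stop("`mu_max` must be in [0, 1)", call. = FALSE)
  }
  c(lower = measured, upper = measured / (1 - mu_max))
}

#' Extrapolate AUROC to zero holdout
#'
#' Performance improves as less of the network is held out for
#' cross-validation; a straight-line fit of mean AUROC against holdout
#' fraction, weighted by inverse squared standard errors when available,
#' estimates the AUROC of the method trained on the full network.
#'
#' @param fractions holdout fractions (at least two distinct values).
#' @param auroc_means mean AUROC at each fraction.
#' @param auroc_ses optional standard errors (weights `1 / se^2`); `NULL`
#'   gives an unweighted fit.
#' @return a named list `intercept` (fitted AUROC at fraction zero) and
#'   `se` (its standard error from the least-squares fit).
#' @export
extrapolate_auroc <- function(fractions, auroc_means, auroc_ses = NULL) {
  if (length(fractions) < 2 || length(unique(fractions)) < 2) {
    stop("need at least two distinct holdout fractions", call. = FALSE)
  }
  stopifnot(length(auroc_means) == length(fractions))
  w <- if (is.null(auroc_ses)) NULL else 1 / auroc_ses^2
  fit <- lm(auroc_means ~ fractions, weights = w)
  se <- if (stats::df.residual(fit) > 0) unname(sqrt(vcov(fit)[1, 1]))
        else NA_real_
  list(intercept = unname(coef(fit)[1]), se = se)
}
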