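#' Block states for the bipartite degree-corrected SBM
#'
#' A `block_state` records a partition of the drugs into `k_drug` groups and
#' of the diseases into `k_disease` groups.  The two sides have separate
#' group sets (within-side cells are structurally empty in a bipartite
#' network).
#'
#' @param drug_groups integer group index per drug, in `1:k_drug`.
#' @param disease_groups integer group index per disease, in `1:k_disease`.
#' @param k_drug,k_disease declared group counts (defaults: the maxima of
#'   the index vectors).
#' @return an object of class `block_state`.
#' @export
block_state <- function(drug_groups, disease_groups,
                        k_drug = max(drug_groups),
                        k_disease = max(disease_groups)) {
  drug_groups <- as.integer(drug_groups)
  disease_groups <- as.integer(disease_groups)
  if (k_drug < 1 || k_disease < 1) stop("zero groups", call. = FALSE)
  if (any(drug_groups < 1L | drug_groups > k_drug) ||
      any(disease_groups < 1L | disease_groups > k_disease)) {
    stop("group index out of range", call. = FALSE)
  }
  structure(list(drug_groups = drug_groups, disease_groups = disease_groups,
                 k_drug = as.integer(k_drug),
                 k_disease = as.integer(k_disease)),
            class = "block_state")
}

# Sufficient statistics of a state: edge counts per group cell and per-group
# degree totals.
block_stats <- function(net, state) {
  if (length(state$drug_groups) != n_drugs(net) ||
      length(state$disease_groups) != n_diseases(net)) {
    stop("block state inconsistent with network", call. = FALSE)
  }
  r <- state$drug_groups[net$edges[, 1]]
  s <- state$disease_groups[net$edges[, 2]]
  m_rs <- matrix(0, state$k_drug, state$k_disease)
  if (length(r) > 0) {
    tab <- table(factor(r, levels = seq_len(state$k_drug)),
                 factor(s, levels = seq_len(state$k_disease)))
    m_rs[] <- as.numeric(tab)
  }
  list(m_rs = m_rs,
       kappa_r = rowSums(m_rs),
       kappa_s = colSums(m_rs))
}

#' Profile log-likelihood of the degree-corrected SBM
#'
#' The Poisson degree-corrected stochastic block model places
#' `A_uv ~ Poisson(theta_u theta_v omega[g_u, g_v])` on every drug-disease
#' pair.  With the rate parameters profiled out at their maximum-likelihood
#' values (`theta_u = d_u / kappa_{g_u}`, `omega_rs = m_rs`), the maximized
#' log-likelihood is a function of the partition alone:
#' \deqn{\ell = \sum_u d_u \log d_u + \sum_v d_v \log d_v
#'   + \sum_{rs} m_{rs} \log m_{rs}
#'   - \sum_r \kappa_r \log \kappa_r - \sum_s \kappa_s \log \kappa_s - m}
#' with the convention 0 log 0 = 0 (so an isolated, never-touched node
#' contributes nothing).
#'
#' @param net a [bipartite_net()].
#' @param state a [block_state()] consistent with `net`.
#' @return the profile log-likelihood (a single real).
#' @export
dcsbm_log_likelihood <- function(net, state) {
  st <- block_stats(net, state)
  sum(xlogx(drug_degrees(net))) + sum(xlogx(disease_degrees(net))) +
    sum(xlogx(st$m_rs)) - sum(xlogx(st$kappa_r)) - sum(xlogx(st$kappa_s)) -
    n_edges(net)
}

#' Sample block partitions by single-node MCMC
#'
#' Runs a Metropolis chain over bipartite partitions: each move proposes
#' reassigning one uniformly chosen node to a uniformly chosen group and
#' accepts with probability `min(1, exp(delta))`, where `delta` is the
#' change in the profile log-likelihood of [dcsbm_log_likelihood()] (a flat
#' prior over labelings).  One sweep is `n_drugs + n_diseases` proposals.
#' States are retained every `thin` sweeps after `burn_in`.
#'
#' @param net a [bipartite_net()].
#' @param k_drug,k_disease number of groups per side (defaults 30 and 30,
#'   the counts this model family typically finds on drug-disease
#'   indication data).
#' @param sweeps total sweeps (default 2000).
#' @param burn_in sweeps discarded before retention (default 500).
#' @param thin retain every `thin`-th sweep (default 10).
#' @param seed integer seed; the same seed reproduces the identical chain.
#' @return an object of class `dcsbm_samples`: a list with `states` (list of
#'   [block_state()]), `loglik` (profile log-likelihood at each retained
#'   state), and `acceptance_rate`.
#' @export
sample_partitions <- function(net, k_drug = 30, k_disease = 30,
                              sweeps = 2000, burn_in = 500, thin = 10,
                              seed = NULL) {
  if (k_drug < 1 || k_disease < 1) stop("zero groups", call. = FALSE)
  if (!(sweeps > burn_in && burn_in >= 0)) {
    stop("need sweeps > burn_in >= 0", call. = FALSE)
  }
  res <- with_seed(seed, {
    init_gu <- sample.int(k_drug, n_drugs(net), replace = TRUE)
    init_gv <- sample.int(k_disease, n_diseases(net), replace = TRUE)
    dcsbm_mcmc(net$edges[, 1] - 1L, net$edges[, 2] - 1L,
               n_drugs(net), n_diseases(net),
               as.integer(k_drug), as.integer(k_disease),
               init_gu - 1L, init_gv - 1L,
               as.integer(sweeps), as.integer(burn_in), as.integer(thin))
  })
  states <- lapply(seq_len(ncol(res$gu)), function(j) {
    block_state(res$gu[, j] + 1L, res$gv[, j] + 1L, k_drug, k_disease)
  })
  structure(list(states = states, loglik = as.numeric(res$loglik),
                 acceptance_rate = res$acceptance_rate,
                 k_drug = k_drug, k_disease = k_disease),
            class = "dcsbm_samples")
}

#' @export
print.dcsbm_samples <- function(x, ...) {
  cat(sprintf("DCSBM posterior sample: %d states (%d x %d groups), acceptance %.1f%%\n",
              length(x$states), x$k_drug, x$k_disease,
              100 * x$acceptance_rate))
  invisible(x)
}

# Change in profile log-likelihood from adding one edge at (u, v), as a
# dense matrix over all pairs, for a single state.  Adding an edge bumps
# d_u, d_v, m_{g_u g_v}, kappa_{g_u}, kappa_{g_v} and m by one; each bump
# contributes (x+1)log(x+1) - x log x.
dcsbm_delta_matrix <- function(net, state) {
  st <- block_stats(net, state)
  bump <- function(x) xlogx(x + 1) - xlogx(x)
  du <- bump(drug_degrees(net))
  dv <- bump(disease_degrees(net))
  G <- bump(st$m_rs) -
    outer(bump(st$kappa_r), rep(1, state$k_disease)) -
    outer(rep(1, state$k_drug), bump(st$kappa_s)) - 1
  outer(du, dv, "+") + G[cbind(rep(state$drug_groups, times = n_diseases(net)),
                               rep(state$disease_groups, each = n_drugs(net)))]
}

#' DCSBM prediction scores
#'
#' For each candidate pair and each sampled partition, computes the change
#' in the profile log-likelihood when that single edge is added to the
#' network; the final score is the average of this change over the retained
#' posterior samples (Bayesian averaging over partitions).
#'
#' @param net a [bipartite_net()].
#' @param samples a [dcsbm_samples][sample_partitions()] (or a list of
#'   [block_state()]s).
#' @param max_states cap on the number of states used for scoring (default
#'   150), taken evenly from the retained sequence.
#' @inheritParams score_similarity_sum
#' @return a [score_table][score_table_from_matrix()].
#' @export
score_dcsbm <- function(net, samples, max_states = 150,
                        include_edges = FALSE) {
  states <- if (inherits(samples, "dcsbm_samples")) samples$states
            else samples
  if (length(states) == 0) stop("no sampled states to score", call. = FALSE)
  if (length(states) > max_states) {
    keep <- unique(round(seq(1, length(states), length.out = max_states)))
    states <- states[keep]
  }
  acc <- matrix(0, n_drugs(net), n_diseases(net))
  for (st in states) acc <- acc + dcsbm_delta_matrix(net, st)
  score_table_from_matrix(acc / length(states), net, include_edges)
}
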