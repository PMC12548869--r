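#' Block mixing matrix for planted bipartite structure
#'
#' Builds a per-pair edge-rate matrix `omega` (drug groups x disease
#' groups) with assortative contrast: cells whose drug-group and
#' disease-group indices match (modulo the smaller group count) get
#' `contrast` times the baseline rate, and the whole matrix is scaled so
#' that the expected edge count over the full network equals `m_target`
#' (before probability capping).
#'
#' @param n_drugs,n_diseases node counts of the network the mixing is for.
#' @param k_drug,k_disease group counts per side.
#' @param m_target desired expected number of edges.
#' @param contrast ratio of matched-cell to unmatched-cell rate; `1` gives
#'   an unstructured (degree-only) network.
#' @return a `k_drug x k_disease` non-negative matrix of per-pair rates.
#' @export
planted_mixing <- function(n_drugs, n_diseases, k_drug, k_disease,
                           m_target, contrast = 8) {
  stopifnot(k_drug >= 1, k_disease >= 1, m_target > 0, contrast > 0)
  omega <- matrix(1, k_drug, k_disease)
  r <- seq_len(k_drug); s <- seq_len(k_disease)
  kk <- min(k_drug, k_disease)
  match_cell <- outer((r - 1) %% kk, (s - 1) %% kk, "==")
  omega[match_cell] <- contrast
  sizes_r <- group_sizes(n_drugs, k_drug)
  sizes_s <- group_sizes(n_diseases, k_disease)
  expected <- sum(outer(sizes_r, sizes_s) * omega)
  omega * (m_target / expected)
}

# Even split of n nodes over k groups (first n %% k groups get one extra).
group_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

even_groups <- function(n, k) rep(seq_len(k), times = group_sizes(n, k))

#' Generate a bipartite network with planted block structure
#'
#' Samples a degree-corrected planted-partition bipartite network: nodes are
#' assigned evenly to groups, each node gets a positive degree propensity
#' `theta` drawn from a Gamma distribution with mean 1 (normalized to mean
#' exactly 1 within each group), and each drug-disease pair (u, v) receives
#' an edge independently with probability
#' `min(1, theta_u * theta_v * omega[g_u, g_v])`.  Bernoulli sampling with a
#' probability cap keeps the graph simple; a warning is raised if more than
#' 1% of pairs hit the cap (degenerate regime).
#'
#' Defaults emulate a sparse drug-disease indication network: 2620 x 1669
#' nodes, 30 groups per side, about 8946 expected edges (density roughly
#' 2e-3) and heterogeneous, heavy-tailed degrees.
#'
#' @param n_drugs,n_diseases node counts.
#' @param k_drug,k_disease number of planted groups per side.
#' @param mixing per-pair rate matrix as from [planted_mixing()]; `NULL`
#'   builds one with `m_target` and `contrast`.
#' @param m_target,contrast passed to [planted_mixing()] when `mixing` is
#'   `NULL`.
#' @param propensity_shape shape of the mean-1 Gamma propensity
#'   distribution; smaller values give heavier-tailed degrees.
#' @param seed integer seed; the same seed reproduces the identical network.
#' @return a list with `net` (a [bipartite_net()], labels `d0001...` /
#'   `z0001...`) and `truth` (a `planted_truth`: group assignments, the
#'   mixing matrix, and the propensities).
#' @export
generate_planted_network <- function(n_drugs = 2620, n_diseases = 1669,
                                     k_drug = 30, k_disease = 30,
                                     mixing = NULL, m_target = 8946,
                                     contrast = 8, propensity_shape = 1,
                                     seed = NULL) {
  stopifnot(n_drugs >= 1, n_diseases >= 1, k_drug >= 1, k_disease >= 1,
            propensity_shape > 0)
  if (is.null(mixing)) {
    mixing <- planted_mixing(n_drugs, n_diseases, k_drug, k_disease,
                             m_target, contrast)
  }
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != k_drug || ncol(mixing) != k_disease)
    stop("mixing matrix dimensions must match the group counts", call. = FALSE)
  if (any(mixing < 0)) stop("mixing rates must be non-negative", call. = FALSE)
  with_seed(seed, {
    gu <- even_groups(n_drugs, k_drug)
    gv <- even_groups(n_diseases, k_disease)
    theta_u <- rgamma(n_drugs, shape = propensity_shape,
                      rate = propensity_shape)
    theta_v <- rgamma(n_diseases, shape = propensity_shape,
                      rate = propensity_shape)
    theta_u <- pmax(theta_u, 1e-12)
    theta_v <- pmax(theta_v, 1e-12)
    # identifiability: propensities average to exactly 1 within each group
    theta_u <- theta_u / stats::ave(theta_u, gu)
    theta_v <- theta_v / stats::ave(theta_v, gv)
    P <- outer(theta_u, theta_v) * mixing[cbind(
      rep(gu, times = n_diseases), rep(gv, each = n_drugs))]
    dim(P) <- c(n_drugs, n_diseases)
    capped <- P > 1
    if (mean(capped) > 0.01) {
      warning(sprintf("probability cap hit for %.1f%% of pairs (degenerate regime)",
                      100 * mean(capped)), call. = FALSE)
    }
    P[capped] <- 1
    A <- matrix(runif(length(P)) < P, n_drugs, n_diseases)
    edges <- which(A, arr.ind = TRUE)
    net <- bipartite_net(sprintf("d%04d", seq_len(n_drugs)),
                         sprintf("z%04d", seq_len(n_diseases)),
                         edges)
    truth <- structure(list(drug_groups = gu, disease_groups = gv,
                            mixing = mixing,
                            drug_propensities = theta_u,
                            disease_propensities = theta_v,
                            expected_m = sum(P)),
                       class = "planted_truth")
    list(net = net, truth = truth)
  })
}

#' @export
print.planted_truth <- function(x, ...) {
  cat(sprintf("planted truth: %d x %d groups, expected m = %.1f\n",
              nrow(x$mixing), ncol(x$mixing), x$expected_m))
  invisible(x)
}

#' Planted-truth edge probabilities as prediction scores
#'
#' The generative edge probability `min(1, theta_u theta_v omega)` of every
#' candidate pair — an oracle predictor against which the theoretical
#' missing-edge bound is tight, useful for validating the evaluation
#' harness.
#'
#' @param net the observed [bipartite_net()].
#' @param truth the `planted_truth` from [generate_planted_network()].
#' @inheritParams score_similarity_sum
#' @return a [score_table][score_table_from_matrix()].
#' @export
score_planted_truth <- function(net, truth, include_edges = FALSE) {
  P <- outer(truth$drug_propensities, truth$disease_propensities) *
    truth$mixing[cbind(rep(truth$drug_groups, times = n_diseases(net)),
                       rep(truth$disease_groups, each = n_drugs(net)))]
  dim(P) <- c(n_drugs(net), n_diseases(net))
  score_table_from_matrix(pmin(P, 1), net, include_edges)
}

#' Hide a random fraction of edges
#'
#' Removes a uniformly random subset of edges so that the hidden edges form
#' fraction `mu` of the *observed* network's unconnected pairs — the planted
#' missing-edge fraction of the theoretical bound calculus.  The required
#' hidden count solves `h = mu * (N - m + h)` with `N = n_drugs *
#' n_diseases`, i.e. `h = round(mu * (N - m) / (1 - mu))`.
#'
#' @param net a non-empty [bipartite_net()]: the complete ground-truth
#'   network.
#' @param mu target missing-edge fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return a list with `observed` (the thinned [bipartite_net()], same node
#'   sets) and `hidden` (two-column matrix of the removed edges).
#' @export
plant_missing_edges <- function(net, mu, seed = NULL) {
  stopifnot(mu >= 0, mu < 1)
  m <- n_edges(net)
  if (m == 0) stop("network has no edges", call. = FALSE)
  N <- as.numeric(n_drugs(net)) * n_diseases(net)
  h <- round(mu * (N - m) / (1 - mu))
  if (h > m) {
    stop(sprintf("mu = %g requires hiding %d edges but only %d exist", mu, h, m),
         call. = FALSE)
  }
  if (h == 0) {
    return(list(observed = net,
                hidden = matrix(integer(0), ncol = 2,
                                dimnames = list(NULL, c("drug", "disease")))))
  }
  idx <- with_seed(seed, sample.int(m, h))
  list(observed = drop_edges(net, idx),
       hidden = net$edges[idx, , drop = FALSE])
}
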