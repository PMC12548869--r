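#' Truncated-SVD prediction scores
#'
#' Computes the singular value decomposition `B = U S V'` of the incidence
#' matrix, keeps only the `K` largest singular values, and uses the entries
#' of the rank-K reconstruction `B' = U S_K V'` as prediction scores: larger
#' (more positive) elements indicate higher prediction certainty.  By the
#' Eckart-Young theorem `B'` is the best rank-K approximation to `B` in
#' Frobenius norm.
#'
#' @param net a [bipartite_net()].
#' @param K number of singular values retained (default 60, the dimension
#'   that performs best on sparse drug-disease indication data).
#' @inheritParams score_similarity_sum
#' @return a [score_table][score_table_from_matrix()].
#' @export
score_svd <- function(net, K = 60, include_edges = FALSE) {
  kmax <- min(n_drugs(net), n_diseases(net))
  if (K < 1 || K > kmax) {
    stop(sprintf("K must be in [1, %d]", kmax), call. = FALSE)
  }
  B <- incidence_matrix(net, sparse = FALSE)
  sv <- svd(B, nu = K, nv = K)
  X <- sv$u %*% (sv$d[seq_len(K)] * t(sv$v))
  score_table_from_matrix(X, net, include_edges)
}

#' Fit a PLSA model to the edge multiset
#'
#' The probabilistic latent semantic analysis (aspect) model expresses the
#' probability of observing an edge at pair (u, v) as a K-component mixture
#' `P(u, v) = sum_k P(k) P(u | k) P(v | k) = r_u . s_v`, where the drug
#' vector `r_u[k] = P(k) P(u | k)` absorbs the component weights and the
#' disease vector is `s_v[k] = P(v | k)`.  Fitted by expectation-
#' maximization on the observed edge multiset (each edge one count):
#' the E step computes the posterior over components for every edge, the M
#' step renormalizes; the log-likelihood never decreases.  Multiple random
#' restarts guard against local optima; the best final log-likelihood wins.
#'
#' @param net a [bipartite_net()] with at least one edge.
#' @param K number of mixture components (default 90).
#' @param max_iter EM iteration cap per restart.
#' @param tol stop when the log-likelihood gain drops below this.
#' @param seed integer seed for the random initializations.
#' @param n_restarts independent EM restarts.
#' @return an object of class `plsa_fit` with `drug_vectors`
#'   (`n_drugs x K`), `disease_vectors` (`n_diseases x K`), `loglik`
#'   (trajectory of the winning restart), and `K`.
#' @export
fit_plsa <- function(net, K = 90, max_iter = 200, tol = 1e-8, seed = NULL,
                     n_restarts = 5) {
  if (K < 1) stop("K must be at least 1", call. = FALSE)
  m <- n_edges(net)
  if (m < 1) stop("network has no edges", call. = FALSE)
  u <- net$edges[, 1]; v <- net$edges[, 2]
  nu <- n_drugs(net); nv <- n_diseases(net)
  run_em <- function() {
    pk <- rep(1 / K, K)
    pu <- matrix(runif(nu * K, 0.5, 1.5), nu, K)
    pu <- sweep(pu, 2, colSums(pu), "/")
    pv <- matrix(runif(nv * K, 0.5, 1.5), nv, K)
    pv <- sweep(pv, 2, colSums(pv), "/")
    ll_trace <- numeric(0)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      W <- pu[u, , drop = FALSE] * pv[v, , drop = FALSE] *
        rep(pk, each = m)                      # m x K joint weights
      rowtot <- rowSums(W)
      ll <- sum(log(rowtot))
      ll_trace <- c(ll_trace, ll)
      Q <- W / rowtot                           # E step: posteriors
      pk <- colSums(Q) / m                      # M step
      pu <- rowsum(Q, u, reorder = FALSE)
      pu_full <- matrix(0, nu, K)
      pu_full[as.integer(rownames(pu)), ] <- pu
      pu <- sweep(pu_full, 2, pmax(colSums(pu_full), 1e-300), "/")
      pv <- rowsum(Q, v, reorder = FALSE)
      pv_full <- matrix(0, nv, K)
      pv_full[as.integer(rownames(pv)), ] <- pv
      pv <- sweep(pv_full, 2, pmax(colSums(pv_full), 1e-300), "/")
      if (it > 1 && ll - ll_old < tol) break
      ll_old <- ll
    }
    list(pk = pk, pu = pu, pv = pv, ll = ll_trace)
  }
  best <- with_seed(seed, {
    fits <- lapply(seq_len(max(1L, n_restarts)), function(i) run_em())
    fits[[which.max(vapply(fits, function(f) f$ll[length(f$ll)], 0))]]
  })
  structure(list(drug_vectors = sweep(best$pu, 2, best$pk, "*"),
                 disease_vectors = best$pv,
                 loglik = best$ll, K = K),
            class = "plsa_fit")
}

#' @export
print.plsa_fit <- function(x, ...) {
  cat(sprintf("PLSA fit: K = %d, log-likelihood %.4f after %d EM iterations\n",
              x$K, x$loglik[length(x$loglik)], length(x$loglik)))
  invisible(x)
}

#' PLSA prediction scores
#'
#' The score of pair (u, v) is the model pair probability `r_u . s_v`.
#' Scores are non-negative and sum to 1 over all drug-disease pairs.
#'
#' @param model a [plsa_fit][fit_plsa()].
#' @param net the [bipartite_net()] the model was fitted to.
#' @inheritParams score_similarity_sum
#' @return a [score_table][score_table_from_matrix()].
#' @export
score_plsa <- function(model, net, include_edges = FALSE) {
  if (!inherits(model, "plsa_fit")) {
    stop("`model` must be a plsa_fit (flavor mismatch)", call. = FALSE)
  }
  X <- model$drug_vectors %*% t(model$disease_vectors)
  score_table_from_matrix(X, net, include_edges)
}

#' @rdname score_plsa
#' @export
predict.plsa_fit <- function(object, net, include_edges = FALSE, ...) {
  score_plsa(object, net, include_edges)
}

#' Non-negative matrix factorization prediction scores
#'
#' Approximates the incidence matrix by a product of two non-negative
#' factors, `B ~ W H` with `W` of size `n_drugs x K` and `H` of size
#' `K x n_diseases`, minimizing the mean-squared (Frobenius) error with the
#' classic multiplicative update rules, under which the objective
#' `||B - W H||_F^2` is non-increasing.  The score of pair (u, v) is
#' `(W H)[u, v]`.
#'
#' @param net a [bipartite_net()].
#' @param K factorization rank (default 80).
#' @param max_iter update iterations per restart.
#' @param tol stop when the relative objective decrease falls below this.
#' @param seed integer seed for the random initializations.
#' @param n_restarts independent restarts; best final objective wins.
#' @inheritParams score_similarity_sum
#' @return a [score_table][score_table_from_matrix()] with the winning fit
#'   attached as attribute `fit` (class `nnmf_fit`: `W`, `H`, `objective`
#'   trajectory).
#' @export
fit_and_score_nnmf <- function(net, K = 80, max_iter = 500, tol = 1e-5,
                               seed = NULL, n_restarts = 5,
                               include_edges = FALSE) {
  kmax <- min(n_drugs(net), n_diseases(net))
  if (K < 1 || K > kmax) {
    stop(sprintf("K must be in [1, %d]", kmax), call. = FALSE)
  }
  B <- incidence_matrix(net, sparse = FALSE)
  eps <- 1e-12
  run_mu <- function() {
    W <- matrix(runif(nrow(B) * K, 0.1, 1), nrow(B), K)
    H <- matrix(runif(K * ncol(B), 0.1, 1), K, ncol(B))
    obj <- numeric(0)
    obj_old <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (t(W) %*% B) / (t(W) %*% W %*% H + eps)
      W <- W * (B %*% t(H)) / (W %*% (H %*% t(H)) + eps)
      o <- sum((B - W %*% H)^2)
      obj <- c(obj, o)
      if (it > 1 && (obj_old - o) <= tol * max(obj_old, eps)) break
      obj_old <- o
    }
    list(W = W, H = H, objective = obj)
  }
  best <- with_seed(seed, {
    fits <- lapply(seq_len(max(1L, n_restarts)), function(i) run_mu())
    fits[[which.min(vapply(fits, function(f) f$objective[length(f$objective)],
                           0))]]
  })
  fit <- structure(best, class = "nnmf_fit")
  tab <- score_table_from_matrix(best$W %*% best$H, net, include_edges)
  attr(tab, "fit") <- fit
  tab
}

#' @export
print.nnmf_fit <- function(x, ...) {
  cat(sprintf("NNMF fit: K = %d, Frobenius objective %.6g after %d iterations\n",
              ncol(x$W), x$objective[length(x$objective)], length(x$objective)))
  invisible(x)
}
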