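# Shared fixtures and independent oracles used across the suite.

# Toy network T1: 3 drugs x 3 diseases, 6 edges.
toy_t1 <- function() {
  bipartite_net(c("u1", "u2", "u3"), c("v1", "v2", "v3"),
                rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 2), c(2, 3), c(3, 3)))
}

# Small Erdos-Renyi-style bipartite network for property checks.
random_net <- function(n_u, n_v, p, seed) {
  biplink:::with_seed(seed, {
    A <- matrix(runif(n_u * n_v) < p, n_u, n_v)
    bipartite_net(paste0("u", seq_len(n_u)), paste0("v", seq_len(n_v)),
                  which(A, arr.ind = TRUE))
  })
}

# Pull the full score matrix out of a predictor (via include_edges = TRUE).
score_matrix_of <- function(tab, n_u, n_v) {
  S <- matrix(NA_real_, n_u, n_v)
  S[tab$pairs] <- tab$scores
  S
}

# Oracle: disease-side similarity-sum score by exhaustive neighbour loops.
oracle_simsum <- function(net, measure, u, v) {
  B <- as.matrix(incidence_matrix(net, sparse = FALSE))
  d <- colSums(B)
  sig <- function(a, b) {
    nab <- sum(B[, a] * B[, b])
    val <- switch(measure,
      common_neighbors = nab,
      cosine = nab / sqrt(d[a] * d[b]),
      jaccard = nab / (d[a] + d[b] - nab),
      dice = nab / ((d[a] + d[b]) / 2),
      hub_suppressed = nab / max(d[a], d[b]))
    if (!is.finite(val)) 0 else val
  }
  nb <- which(B[u, ] == 1)
  if (length(nb) == 0) return(0)
  sum(vapply(nb, function(vp) sig(v, vp), 0))
}

# Oracle: number of paths of length exactly 2l between diseases a and b,
# by explicit matrix powers of the disease-projection walk matrix.
oracle_path_count <- function(net, a, b, l) {
  M <- as.matrix(Matrix::crossprod(incidence_matrix(net)))
  P <- diag(nrow(M))
  for (i in seq_len(l)) P <- P %*% M
  P[a, b]
}

# Oracle: Poisson DCSBM profile log-likelihood by direct summation over all
# pairs with explicitly profiled rate parameters.
oracle_dcsbm_ll <- function(net, state) {
  B <- as.matrix(incidence_matrix(net, sparse = FALSE))
  st <- list(r = state$drug_groups, s = state$disease_groups)
  m_rs <- matrix(0, state$k_drug, state$k_disease)
  for (e in seq_len(n_edges(net))) {
    m_rs[st$r[net$edges[e, 1]], st$s[net$edges[e, 2]]] <-
      m_rs[st$r[net$edges[e, 1]], st$s[net$edges[e, 2]]] + 1
  }
  kr <- rowSums(m_rs); ks <- colSums(m_rs)
  du <- rowSums(B); dv <- colSums(B)
  theta_u <- ifelse(kr[st$r] > 0, du / kr[st$r], 0)
  theta_v <- ifelse(ks[st$s] > 0, dv / ks[st$s], 0)
  ll <- 0
  for (u in seq_len(nrow(B))) {
    for (v in seq_len(ncol(B))) {
      lam <- theta_u[u] * theta_v[v] * m_rs[st$r[u], st$s[v]]
      if (B[u, v] > 0) ll <- ll + B[u, v] * log(lam)
      ll <- ll - lam
    }
  }
  ll
}

# Oracle: AUROC by explicit trapezoidal integration of the ROC curve over
# distinct score thresholds.
oracle_trapezoid_auc <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(scores[labels] >= t), 0))
  fpr <- c(0, vapply(thr, function(t) mean(scores[!labels] >= t), 0))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Build a holdout_split by hand (used for worked metric examples).
manual_split <- function(original, positive_rows) {
  structure(list(training = biplink:::drop_edges(original, positive_rows),
                 positives = original$edges[positive_rows, , drop = FALSE],
                 original = original),
            class = "holdout_split")
}
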