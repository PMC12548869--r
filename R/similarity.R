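#' Same-type node similarity matrices
#'
#' Topological similarity between nodes of one side of the bipartite
#' network, all based on the common-neighbour count `n_uv` (equivalently the
#' number of paths of length two):
#' \describe{
#'   \item{common_neighbors}{`n_uv`}
#'   \item{cosine}{`n_uv / sqrt(d_u d_v)`}
#'   \item{jaccard}{`n_uv / (d_u + d_v - n_uv)`}
#'   \item{dice}{`n_uv / ((d_u + d_v) / 2)`}
#'   \item{hub_suppressed}{`n_uv / max(d_u, d_v)`}
#' }
#' Whenever a normalized measure evaluates to 0/0 (a degree-zero node) the
#' similarity is defined to be zero.
#'
#' @param net a [bipartite_net()].
#' @param side which side's nodes to compare: `"disease"` (default) or
#'   `"drug"`.
#' @param measure one of the five measures above.
#' @return a dense symmetric matrix of similarities (diagonal included:
#'   `n_uu = d_u`).
#' @export
same_type_similarity <- function(net, side = c("disease", "drug"),
                                 measure = c("common_neighbors", "cosine",
                                             "jaccard", "dice",
                                             "hub_suppressed")) {
  side <- match.arg(side)
  measure <- match.arg(measure)
  B <- incidence_matrix(net)
  if (side == "disease") {
    C <- as.matrix(Matrix::crossprod(B))       # n_uv for disease pairs
    d <- disease_degrees(net)
  } else {
    C <- as.matrix(Matrix::tcrossprod(B))
    d <- drug_degrees(net)
  }
  if (measure == "common_neighbors") return(C)
  du <- matrix(d, nrow = length(d), ncol = length(d))
  dv <- t(du)
  denom <- switch(measure,
    cosine = sqrt(du * dv),
    jaccard = du + dv - C,
    dice = (du + dv) / 2,
    hub_suppressed = pmax(du, dv))
  S <- C / denom
  S[!is.finite(S)] <- 0   # 0/0 convention for degree-zero nodes
  S
}

#' Similarity-sum prediction scores
#'
#' The prediction score for drug u and disease v is the summed similarity
#' between v and the diseases u already treats,
#' `x(u, v) = sum over v' in N(u) of sigma(v, v')` (disease side, the
#' default), or between u and the drugs already treating v,
#' `x(u, v) = sum over u' in N(v) of sigma(u, u')` (drug side).  The disease
#' side is the default because it performs distinctly better on drug-disease
#' indication data.
#'
#' @inheritParams same_type_similarity
#' @param direction `"disease_side"` (default) or `"drug_side"`.
#' @param include_edges score existing edges too (see
#'   [score_table_from_matrix()]).
#' @return a [score_table][score_table_from_matrix()].
#' @export
score_similarity_sum <- function(net,
                                 measure = c("common_neighbors", "cosine",
                                             "jaccard", "dice",
                                             "hub_suppressed"),
                                 direction = c("disease_side", "drug_side"),
                                 include_edges = FALSE) {
  measure <- match.arg(measure)
  direction <- match.arg(direction)
  B <- incidence_matrix(net)
  if (direction == "disease_side") {
    Sig <- same_type_similarity(net, "disease", measure)
    X <- as.matrix(B %*% Sig)
  } else {
    Sig <- same_type_similarity(net, "drug", measure)
    X <- as.matrix(Sig %*% B)
  }
  score_table_from_matrix(X, net, include_edges)
}

#' Degree-product (preferential-attachment) prediction scores
#'
#' The score of pair (u, v) is simply `d_u * d_v`, the product of the two
#' node degrees.
#'
#' @inheritParams score_similarity_sum
#' @return a [score_table][score_table_from_matrix()].
#' @export
score_degree_product <- function(net, include_edges = FALSE) {
  X <- outer(drug_degrees(net), disease_degrees(net))
  score_table_from_matrix(X, net, include_edges)
}

#' Katz similarity prediction scores
#'
#' A path-counting similarity between same-type nodes that counts paths of
#' all (even) lengths with geometrically decaying weight:
#' `sigma(v, v') = sum over l >= 1 of alpha^l * (# paths of length 2l)`.
#' With `M = t(B) %*% B` the length-2 path-count matrix, the series sums in
#' closed form to `solve(I - alpha M) %*% (alpha M)`, convergent when
#' `alpha * lambda_max(M) < 1` where `lambda_max(M)` is the squared largest
#' singular value of the incidence matrix.  Scores are then assembled by
#' the disease-side similarity sum.
#'
#' @inheritParams score_similarity_sum
#' @param alpha attenuation factor; default `0.5 / lambda_max(M)`, safely
#'   inside the convergence region.
#' @return a [score_table][score_table_from_matrix()].
#' @export
score_katz <- function(net, alpha = NULL, include_edges = FALSE) {
  B <- incidence_matrix(net)
  M <- as.matrix(Matrix::crossprod(B))
  lam <- if (nrow(M) == 0) 0 else
    max(0, eigen(M, symmetric = TRUE, only.values = TRUE)$values[1])
  if (is.null(alpha)) {
    alpha <- if (lam > 0) 0.5 / lam else 1
  }
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  if (alpha * lam >= 1) {
    stop(sprintf(paste0("Katz series diverges: alpha = %g but must be below ",
                        "1 / lambda_max = %g"), alpha, 1 / lam), call. = FALSE)
  }
  n <- nrow(M)
  Sig <- solve(diag(n) - alpha * M, alpha * M)
  X <- as.matrix(B %*% Sig)
  score_table_from_matrix(X, net, include_edges)
}
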