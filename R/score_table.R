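#' Prediction score tables
#'
#' A `score_table` maps candidate drug-disease pairs to real-valued
#' prediction scores, higher meaning more likely to be a true missing edge.
#' By default the candidate set is every unconnected pair of the network the
#' scores were computed from; scoring of existing edges is available behind
#' `include_edges = TRUE` (useful for auditing suspect recorded edges, not
#' part of the standard prediction task).
#'
#' @param S numeric matrix of scores, `n_drugs x n_diseases`.
#' @param net the [bipartite_net()] the scores were computed from.
#' @param include_edges also keep pairs that are already edges of `net`.
#' @return an object of class `score_table`: a list with `pairs` (two-column
#'   integer matrix), `scores`, `pair_idx` (dense linear index used as the
#'   deterministic tie-break key), and the node labels.
#' @export
score_table_from_matrix <- function(S, net, include_edges = FALSE) {
  stopifnot(nrow(S) == n_drugs(net), ncol(S) == n_diseases(net))
  if (any(!is.finite(S))) stop("non-finite prediction scores", call. = FALSE)
  if (include_edges) {
    u <- rep(seq_len(n_drugs(net)), each = n_diseases(net))
    v <- rep(seq_len(n_diseases(net)), times = n_drugs(net))
  } else {
    A <- matrix(FALSE, n_drugs(net), n_diseases(net))
    A[net$edges] <- TRUE
    keep <- which(!t(A))  # column-major over t(A) = row-major over A
    u <- (keep - 1L) %/% n_diseases(net) + 1L
    v <- (keep - 1L) %% n_diseases(net) + 1L
  }
  scores <- S[cbind(u, v)]
  structure(list(pairs = cbind(drug = u, disease = v),
                 scores = as.numeric(scores),
                 pair_idx = pair_index(net, u, v),
                 drugs = net$drugs, diseases = net$diseases),
            class = "score_table")
}

#' @export
print.score_table <- function(x, n = 10, ...) {
  cat(sprintf("score table: %d candidate pairs\n", length(x$scores)))
  top <- top_predictions(x, min(n, length(x$scores)))
  print(top, row.names = FALSE)
  invisible(x)
}

#' Highest-scoring candidate pairs
#'
#' @param tab a `score_table`.
#' @param n number of predictions to return.
#' @return a data.frame with drug, disease, score and rank, sorted by
#'   decreasing score; ties broken by the deterministic pair index.
#' @export
top_predictions <- function(tab, n = 100) {
  ord <- order(-tab$scores, tab$pair_idx)[seq_len(min(n, length(tab$scores)))]
  data.frame(drug = tab$drugs[tab$pairs[ord, 1]],
             disease = tab$diseases[tab$pairs[ord, 2]],
             score = tab$scores[ord],
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}
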