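#' Built-in predictor adapters
#'
#' Returns a named adapter function `function(net) -> score_table` for one
#' of the built-in methods, suitable for [run_benchmark()] and the command
#' line.  Any user-supplied callable with the same signature plugs into the
#' benchmark the same way, which is how external embedding or deep-learning
#' methods can be compared without being reimplemented here.
#'
#' Methods: `degree`, `cn` (common neighbors), `cosine`, `jaccard`, `dice`,
#' `hub` (hub-suppressed), `katz`, `svd`, `plsa`, `nnmf`, `dcsbm`,
#' `random` (uniform-random scores, the no-skill baseline).
#'
#' @param method method name.
#' @param ... method parameters: `K` and `n_restarts` (svd/plsa/nnmf),
#'   `alpha` (katz), `k_drug`, `k_disease`, `sweeps`, `burn_in`, `thin`,
#'   `max_states` (dcsbm), `direction` (similarity measures).
#' @return a function taking a [bipartite_net()] and returning a
#'   [score_table][score_table_from_matrix()].
#' @export
make_predictor <- function(method = c("degree", "cn", "cosine", "jaccard",
                                      "dice", "hub", "katz", "svd", "plsa",
                                      "nnmf", "dcsbm", "random"), ...) {
  method <- match.arg(method)
  dots <- list(...)
  arg <- function(name, default) {
    if (!is.null(dots[[name]])) dots[[name]] else default
  }
  sim <- function(measure) {
    force(measure)
    function(net) score_similarity_sum(net, measure,
                                       arg("direction", "disease_side"))
  }
  switch(method,
    degree = function(net) score_degree_product(net),
    cn = sim("common_neighbors"),
    cosine = sim("cosine"),
    jaccard = sim("jaccard"),
    dice = sim("dice"),
    hub = sim("hub_suppressed"),
    katz = function(net) score_katz(net, alpha = arg("alpha", NULL)),
    svd = function(net) score_svd(net, K = arg("K", 60)),
    plsa = function(net) {
      fit <- fit_plsa(net, K = arg("K", 90),
                      max_iter = arg("max_iter", 200),
                      n_restarts = arg("n_restarts", 5))
      score_plsa(fit, net)
    },
    nnmf = function(net) fit_and_score_nnmf(net, K = arg("K", 80),
                                            max_iter = arg("max_iter", 500),
                                            n_restarts = arg("n_restarts", 5)),
    dcsbm = function(net) {
      samples <- sample_partitions(net,
                                   k_drug = arg("k_drug", 30),
                                   k_disease = arg("k_disease", 30),
                                   sweeps = arg("sweeps", 2000),
                                   burn_in = arg("burn_in", 500),
                                   thin = arg("thin", 10))
      score_dcsbm(net, samples, max_states = arg("max_states", 150))
    },
    random = function(net) {
      S <- matrix(runif(n_drugs(net) * n_diseases(net)),
                  n_drugs(net), n_diseases(net))
      score_table_from_matrix(S, net)
    })
}
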