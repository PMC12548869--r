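test_that("profile log-likelihood matches closed forms and the brute-force oracle", {
  t1 <- toy_t1()
  # one group per side: the bipartite configuration-model value
  s1 <- block_state(rep(1, 3), rep(1, 3), 1, 1)
  du <- drug_degrees(t1); dv <- disease_degrees(t1); m <- n_edges(t1)
  conf <- sum(du * log(du)) + sum(dv * log(dv)) - m * log(m) - m
  expect_equal(dcsbm_log_likelihood(t1, s1), conf, tolerance = 1e-12)
  # grouped toy state equals exhaustive summation over likelihood terms
  st <- block_state(c(1, 1, 2), c(1, 1, 2), 2, 2)
  expect_equal(dcsbm_log_likelihood(t1, st), oracle_dcsbm_ll(t1, st),
               tolerance = 1e-12)
  # label permutation leaves the value unchanged
  st_perm <- block_state(c(2, 2, 1), c(2, 2, 1), 2, 2)
  expect_equal(dcsbm_log_likelihood(t1, st),
               dcsbm_log_likelihood(t1, st_perm))
  # random states on random networks against the oracle
  for (seed in 1:3) {
    net <- random_net(8, 7, 0.35, seed = 500 + seed)
    st <- biplink:::with_seed(seed, block_state(sample(3, 8, TRUE),
                                                sample(2, 7, TRUE), 3, 2))
    expect_equal(dcsbm_log_likelihood(net, st), oracle_dcsbm_ll(net, st),
                 tolerance = 1e-10)
  }
  # adding an isolated, never-touched node changes nothing
  net <- random_net(6, 5, 0.4, seed = 9)
  st <- block_state(rep(1, 6), rep(1, 5), 2, 2)
  net2 <- bipartite_net(c(net$drugs, "isolated"), net$diseases, net$edges)
  st2 <- block_state(c(st$drug_groups, 2L), st$disease_groups, 2, 2)
  expect_equal(dcsbm_log_likelihood(net2, st2),
               dcsbm_log_likelihood(net, st))
  expect_error(dcsbm_log_likelihood(net, block_state(rep(1, 3), rep(1, 5))),
               "inconsistent")
})

test_that("edge-addition deltas equal full likelihood recomputation", {
  for (seed in 1:3) {
    net <- random_net(7, 6, 0.35, seed = 700 + seed)
    st <- biplink:::with_seed(seed, block_state(sample(2, 7, TRUE),
                                                sample(3, 6, TRUE), 2, 3))
    D <- biplink:::dcsbm_delta_matrix(net, st)
    B <- incidence_matrix(net, sparse = FALSE)
    for (u in 1:7) {
      for (v in 1:6) {
        if (B[u, v] == 1) next
        plus <- bipartite_net(net$drugs, net$diseases,
                              rbind(net$edges, c(u, v)))
        expect_equal(D[u, v],
                     dcsbm_log_likelihood(plus, st) -
                       dcsbm_log_likelihood(net, st),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("the sampler is deterministic, trivially stationary at k = 1, and logs acceptance", {
  net <- random_net(30, 25, 0.15, seed = 55)
  a <- sample_partitions(net, 3, 3, sweeps = 60, burn_in = 20, thin = 5,
                         seed = 42)
  b <- sample_partitions(net, 3, 3, sweeps = 60, burn_in = 20, thin = 5,
                         seed = 42)
  expect_identical(lapply(a$states, unclass), lapply(b$states, unclass))
  expect_identical(a$loglik, b$loglik)
  expect_true(a$acceptance_rate >= 0 && a$acceptance_rate <= 1)
  # retained log-likelihoods agree with recomputation from the states
  for (i in seq_along(a$states)) {
    expect_equal(a$loglik[i], dcsbm_log_likelihood(net, a$states[[i]]),
                 tolerance = 1e-8)
  }
  # k = 1 on both sides: the single partition, unchanged
  one <- sample_partitions(net, 1, 1, sweeps = 10, burn_in = 2, thin = 2,
                           seed = 1)
  expect_true(all(vapply(one$states,
                         function(s) all(s$drug_groups == 1L) &&
                           all(s$disease_groups == 1L), TRUE)))
  expect_error(sample_partitions(net, 0, 3, sweeps = 10, burn_in = 1), "zero")
  expect_error(sample_partitions(net, 2, 2, sweeps = 5, burn_in = 5), "sweeps")
})

test_that("the sampler recovers well-separated planted blocks", {
  # two dense blocks per side, essentially disconnected
  edges <- rbind(as.matrix(expand.grid(1:10, 1:8)),
                 as.matrix(expand.grid(11:20, 9:16)))
  keep <- biplink:::with_seed(3, runif(nrow(edges)) < 0.8)
  net <- bipartite_net(paste0("u", 1:20), paste0("v", 1:16), edges[keep, ])
  res <- sample_partitions(net, 2, 2, sweeps = 400, burn_in = 200, thin = 20,
                           seed = 7)
  final <- res$states[[length(res$states)]]
  truth_u <- rep(1:2, each = 10)
  # adjusted agreement up to label permutation
  agree <- function(g, truth) {
    max(mean(g == truth), mean((3L - g) == truth))
  }
  expect_gt(agree(final$drug_groups, truth_u), 0.9)
  expect_gt(agree(final$disease_groups, rep(1:2, each = 8)), 0.9)
})

test_that("DCSBM scoring averages deltas and tracks degree structure", {
  net <- random_net(12, 10, 0.3, seed = 88)
  st <- block_state(rep(1, 12), rep(1, 10), 1, 1)
  tab1 <- score_dcsbm(net, list(st))
  # averaging duplicated copies of one state changes nothing
  tab3 <- score_dcsbm(net, list(st, st, st))
  expect_equal(tab1$scores, tab3$scores)
  # one-group scores increase with the degree product (near-monotone link)
  dp <- score_degree_product(net)
  expect_gt(cor(tab1$scores, dp$scores, method = "spearman"), 0.99)
  expect_error(score_dcsbm(net, list()), "no sampled states")
})

test_that("planted 2x2 block structure orders candidate scores", {
  edges <- rbind(as.matrix(expand.grid(1:12, 1:9)),
                 as.matrix(expand.grid(13:24, 10:18)))
  keep <- biplink:::with_seed(11, runif(nrow(edges)) < 0.6)
  net <- bipartite_net(paste0("u", 1:24), paste0("v", 1:18), edges[keep, ])
  samples <- sample_partitions(net, 2, 2, sweeps = 300, burn_in = 100,
                               thin = 10, seed = 5)
  tab <- score_dcsbm(net, samples)
  same <- (tab$pairs[, 1] <= 12) == (tab$pairs[, 2] <= 9)
  expect_gt(mean(tab$scores[same]), mean(tab$scores[!same]))
})

test_that("DCSBM beats the degree heuristic on planted structure", {
  # paired holdout splits across 20 seeds; sign test at the 5% level
  wins <- 0
  diffs <- numeric(20)
  for (i in 1:20) {
    gen <- suppressWarnings(generate_planted_network(100, 70, 3, 3, m_target = 900,
                                    contrast = 15, propensity_shape = 3,
                                    seed = 8000 + i))
    pm <- plant_missing_edges(gen$net, 0.05, seed = 8100 + i)
    sp <- make_holdout(pm$observed, 0.10, seed = 8200 + i)
    samples <- sample_partitions(sp$training, 3, 3, sweeps = 250,
                                 burn_in = 100, thin = 10, seed = 8300 + i)
    a_sbm <- roc_auc(score_dcsbm(sp$training, samples), sp)
    a_deg <- roc_auc(score_degree_product(sp$training), sp)
    diffs[i] <- a_sbm - a_deg
    if (diffs[i] > 0) wins <- wins + 1
  }
  expect_lt(binom.test(wins, 20, alternative = "greater")$p.value, 0.05)
  expect_gt(mean(diffs), 0)
})
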