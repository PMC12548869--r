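test_that("holdout splits partition the edges and are seed-reproducible", {
  gen <- generate_planted_network(100, 80, 3, 3, m_target = 800,
                                  contrast = 5, propensity_shape = 2, seed = 1)
  net <- gen$net
  sp <- make_holdout(net, 0.10, seed = 5)
  expect_equal(nrow(sp$positives), round(0.10 * n_edges(net)))
  both <- rbind(sp$training$edges, sp$positives)
  expect_equal(both[order(both[, 1], both[, 2]), ], net$edges,
               ignore_attr = TRUE)
  sp2 <- make_holdout(net, 0.10, seed = 5)
  expect_identical(sp$positives, sp2$positives)
  # the removal count matches nearest-integer rounding at full scale:
  # 10% of 8946 edges is 895 positives
  expect_equal(round(0.10 * 8946), 895)
  expect_error(make_holdout(net, 0), "in \\(0, 1\\)")
  expect_error(make_holdout(toy_t1(), 0.01), "zero removals")
})

test_that("AUROC equals the rank statistic on worked examples", {
  orig <- bipartite_net(paste0("u", 1:2), paste0("v", 1:3),
                        rbind(c(1, 1), c(1, 2), c(2, 1), c(2, 3)))
  sp <- manual_split(orig, c(1, 4))  # positives u1-v1, u2-v3
  S <- matrix(0, 2, 3)
  S[1, 1] <- 3; S[2, 2] <- 2; S[2, 3] <- 1; S[1, 3] <- 0
  tab <- score_table_from_matrix(S, sp$training)
  # positives score {3, 1}; negatives {2, 0}: 3 of 4 comparisons won
  expect_equal(roc_auc(tab, sp), 3 / 4)
  # perfect separation
  S2 <- matrix(0, 2, 3); S2[1, 1] <- 1; S2[2, 3] <- 1
  expect_equal(roc_auc(score_table_from_matrix(S2, sp$training), sp), 1)
  # all scores tied
  S3 <- matrix(1, 2, 3)
  expect_equal(roc_auc(score_table_from_matrix(S3, sp$training), sp), 0.5)
})

test_that("rank-statistic AUROC equals trapezoidal ROC integration", {
  for (seed in 1:6) {
    gen <- suppressWarnings(generate_planted_network(40, 30, 2, 2, m_target = 250,
                                    contrast = 6, propensity_shape = 2,
                                    seed = 900 + seed))
    sp <- make_holdout(gen$net, 0.15, seed = seed)
    # a scorer with many ties (integer common-neighbour counts)
    tab <- score_similarity_sum(sp$training, "common_neighbors")
    al <- biplink:::split_labels(tab, sp)
    expect_equal(roc_auc(tab, sp),
                 oracle_trapezoid_auc(al$scores, al$labels),
                 tolerance = 1e-12)
  }
})

test_that("precision-recall metrics reproduce the worked example", {
  # six candidates ranked (+, -, +, -, -, +)
  orig <- bipartite_net(paste0("u", 1:3), paste0("v", 1:3),
                        rbind(c(1, 1), c(2, 2), c(3, 3)))
  sp <- manual_split(orig, 1:3)  # all three edges held out; 6 negatives
  S <- matrix(0, 3, 3)
  S[1, 1] <- 6; S[1, 2] <- 5; S[2, 2] <- 4; S[2, 1] <- 3; S[2, 3] <- 2
  S[3, 3] <- 1
  tab <- score_table_from_matrix(S, sp$training)
  pr <- pr_metrics(tab, sp, k = 3)
  expect_equal(pr$aupr, 100 * mean(c(1, 2 / 3, 1 / 2)), tolerance = 1e-12)
  expect_equal(round(pr$aupr, 1), 72.2)
  expect_equal(pr$topk, 100 * 2 / 3)
  # perfect ranking: AUPR and top-k at 100 for k <= p
  S2 <- matrix(0, 3, 3); S2[1, 1] <- 3; S2[2, 2] <- 2; S2[3, 3] <- 1
  pr2 <- pr_metrics(score_table_from_matrix(S2, sp$training), sp, k = 3)
  expect_equal(pr2$aupr, 100)
  expect_equal(pr2$topk, 100)
  # normalization: perfect predictor attains 1 / prevalence
  expect_equal(pr2$norm_aupr, 9 / 3)
  expect_error(pr_metrics(tab, sp, k = 50), "exceeds")
})

test_that("tie-breaking by pair index makes rankings deterministic", {
  orig <- bipartite_net(paste0("u", 1:2), paste0("v", 1:2),
                        rbind(c(1, 1), c(2, 2)))
  sp <- manual_split(orig, 1)
  S <- matrix(5, 2, 2)  # all tied: order must follow pair index
  tab <- score_table_from_matrix(S, sp$training)
  pr <- pr_metrics(tab, sp, k = 1)
  # pair (1,1) has the smallest index and is the positive
  expect_equal(pr$topk, 100)
})

test_that("benchmark pairs predictors on identical splits and is reproducible", {
  gen <- suppressWarnings(generate_planted_network(80, 60, 3, 3, m_target = 600,
                                  contrast = 8, propensity_shape = 2, seed = 2))
  oracle_pred <- function(net) {
    # scores 1 on every pair missing from the training network relative to
    # the generator's full network, 0 elsewhere: a perfect predictor
    S <- matrix(0, n_drugs(net), n_diseases(net))
    S[gen$net$edges] <- 1
    S[net$edges] <- 0
    score_table_from_matrix(S, net)
  }
  preds <- list(oracle = oracle_pred, degree = make_predictor("degree"),
                broken = function(net) stop("boom"))
  r1 <- run_benchmark(gen$net, preds, fraction = 0.10, n_reps = 3, k = 10,
                      seed = 11)
  r2 <- run_benchmark(gen$net, preds, fraction = 0.10, n_reps = 3, k = 10,
                      seed = 11)
  r1$per_rep$seconds <- r2$per_rep$seconds <- NULL
  r1$summary$seconds <- r2$summary$seconds <- NULL
  expect_identical(r1$per_rep, r2$per_rep)
  expect_identical(r1$summary, r2$summary)
  # the oracle is perfect on every repetition
  o <- r1$per_rep[r1$per_rep$predictor == "oracle", ]
  expect_true(all(o$auroc == 1))
  expect_true(all(o$aupr == 100))
  # failures are recorded and excluded from the means
  b <- r1$summary[r1$summary$predictor == "broken", ]
  expect_equal(b$n_ok, 0)
  expect_true(all(!is.na(r1$per_rep$error[r1$per_rep$predictor == "broken"])))
  expect_error(run_benchmark(gen$net, list()), "no predictors")
})

test_that("bound arithmetic reproduces the published worked example", {
  b <- missing_edge_bound(0.967, 4363834, 8946)
  expect_equal(b$mu_max, 0.066, tolerance = 1e-12)
  expect_equal(b$nu_max, 0.066, tolerance = 1e-12)
  expect_equal(b$max_missing_pairs, 288013)
  expect_equal(round(b$max_missing_pairs, -3), 288000)
  expect_equal(b$max_false_positives, 590)
  # boundary and error cases
  expect_equal(missing_edge_bound(1, 100, 10)$mu_max, 0)
  expect_equal(missing_edge_bound(0.75, 100, 10)$mu_max, 0.5)
  expect_error(missing_edge_bound(0.3, 100, 10), "0.5")
})

test_that("precision correction divides by one minus the missing fraction", {
  pc <- precision_correction(20.0, 0.066)
  expect_equal(unname(pc["lower"]), 20.0)
  expect_equal(round(unname(pc["upper"]), 1), 21.4)
  expect_equal(unname(precision_correction(50, 0.5)["upper"]), 100)
  expect_identical(unname(precision_correction(7, 0)),
                   c(7, 7))
  expect_error(precision_correction(10, 1), "mu_max")
})

test_that("AUROC extrapolation matches the normal-equations oracle", {
  fr <- c(0.10, 0.05, 0.02)
  au <- c(0.94, 0.95, 0.962)
  ex <- extrapolate_auroc(fr, au)
  # closed-form least squares through the three points
  X <- cbind(1, fr)
  beta <- solve(t(X) %*% X, t(X) %*% au)
  expect_equal(ex$intercept, beta[1], tolerance = 1e-12)
  expect_equal(round(ex$intercept, 3), 0.966)
  # weighted fit reduces to the same line when weights are equal
  exw <- extrapolate_auroc(fr, au, auroc_ses = rep(0.001, 3))
  expect_equal(exw$intercept, ex$intercept, tolerance = 1e-12)
  # two points: the exact interpolating line
  ex2 <- extrapolate_auroc(c(0.1, 0.05), c(0.9, 0.95))
  expect_equal(ex2$intercept, 1.0, tolerance = 1e-12)
  expect_error(extrapolate_auroc(c(0.1, 0.1), c(0.9, 0.91)), "distinct")
})

test_that("random scorers sit at the no-skill baseline", {
  gen <- generate_planted_network(500, 320, 4, 4, m_target = 8000,
                                  contrast = 4, propensity_shape = 2, seed = 4)
  rep <- run_benchmark(gen$net, list(random = make_predictor("random")),
                       fraction = 0.10, n_reps = 40, k = 20, seed = 21)
  s <- rep$summary
  expect_lt(abs(s$auroc - 0.5), 3 * s$auroc_se)
  expect_lt(abs(s$norm_aupr - 1), 3 * s$norm_aupr_se)
})
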