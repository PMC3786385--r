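test_that("forced prediction: '21' on the uniform L=2 network is strict
           absence at locus 1", {
  set.seed(61)
  # only step-1 node compatible with '21' is 01, which carries 0 at locus 1
  pred <- predict_missing(uniform_network(2), "21", n_chain = 2000)
  expect_equal(pred$mean, 0)
  expect_equal(pred$call, "absent")
  expect_true(pred$strict)
})

test_that("a balanced case is neutral and fully observed species are
           rejected", {
  set.seed(62)
  # '210': compatible intermediates are 010 (step 1) and 110 (step 2),
  # visited equally often on the uniform network, so locus 1 is 50/50
  pred <- predict_missing(uniform_network(3), "210", n_chain = 2e4)
  expect_equal(pred$mean, 0.5, tolerance = 0.05)
  expect_equal(pred$call, "neutral")
  expect_false(pred$strict)
  expect_error(predict_missing(uniform_network(2), "10"), "no missing")
})

test_that("predictions are invariant to posterior sample order up to
           ensemble noise", {
  d <- c("100", "110")
  fit <- mcmc_run(d, config = tiny_config(seed = 63))
  set.seed(1)
  a <- predict_missing(fit$networks, "120", n_chain = 2000)
  set.seed(1)
  b <- predict_missing(rev(fit$networks), "120", n_chain = 2000)
  expect_equal(a$mean, b$mean, tolerance = 0.1)
  expect_equal(a$n_networks, b$n_networks)
})

test_that("contingency on the uniform L=3 network is one half off the
           diagonal", {
  set.seed(64)
  n <- 2e4
  g <- contingency_tables(uniform_network(3), n_chain = n)
  off <- g[row(g) != col(g)]
  se <- sqrt(0.25 / n)
  expect_lt(max(abs(off - 0.5)), 3.5 * se)
  expect_true(all(is.na(diag(g))))
  expect_equal(unname(rowSums(g, na.rm = TRUE)), rep(1, 3))
})

test_that("contingency on a deterministic-ordering network is degenerate", {
  L <- 3
  W <- matrix(1e-9, 2^L, L)
  v <- 0
  for (b in 1:3) {
    W[v + 1, b] <- 1e9
    v <- v + 2^(b - 1)
  }
  net <- traitpaths:::new_trait_network(W, L)
  set.seed(65)
  g <- contingency_tables(net, n_chain = 1000)
  expect_gt(g[1, 2], 0.999)
})

test_that("ordering search matches brute force and flags the two-species
           counterexample", {
  res <- deterministic_sequence_search(c("10", "01"))
  expect_equal(res$unaccounted_species, 1)
  expect_equal(res$unaccounted_observations, 1)
  expect_false(res$all_accounted)
  all2 <- deterministic_sequence_search(c("22", "22"))
  expect_true(all2$all_accounted)
  expect_equal(all2$unaccounted_observations, 0)
})

test_that("DP ordering search equals brute-force enumeration on random
           datasets", {
  set.seed(66)
  for (rep in 1:20) {
    L <- sample(2:5, 1)
    n <- sample(2:6, 1)
    strings <- vapply(seq_len(n), function(i) {
      paste(sample(c("0", "1", "2"), L, replace = TRUE), collapse = "")
    }, character(1))
    dp <- deterministic_sequence_search(strings)
    expect_equal(dp$max_accounted, brute_ordering_best(strings),
                 info = paste(strings, collapse = ","))
  }
})

test_that("data generated from one deterministic ordering is fully
           accounted and the ordering recovered", {
  d <- generate_diagonal(L = 6, n_species = 25, ordering = c(2, 4, 1, 6, 3, 5),
                         seed = 67)
  res <- deterministic_sequence_search(d)
  expect_true(res$all_accounted)
  expect_equal(res$unaccounted_species, 0)
  # prefix sets of the recovered ordering must cover every species; with
  # all intermediate steps present the order of informative traits is fixed
  expect_equal(res$best_ordering[1:5], c(2, 4, 1, 6, 3))
})

test_that("occlusion validation tallies sum to the requested points and a
           universally present trait is recovered", {
  # trait 2 present in every species; trait 1 varies
  d <- generate_diagonal(L = 4, n_species = 16, seed = 68)
  res <- occlusion_experiment(d, n_points = 2,
                              config = tiny_config(n_runs = 1), seed = 69)
  expect_equal(sum(unlist(res$tallies)), 2)
  expect_equal(nrow(res$results), 2)
  expect_true(all(res$results$outcome %in%
                    c("strict_correct", "strict_false_positive",
                      "strict_false_negative", "neutral")))
})

test_that("occlusion on strongly ordered ground truth is mostly strict
           correct", {
  d <- generate_diagonal(L = 5, n_species = 30, seed = 70)
  res <- occlusion_experiment(d, n_points = 5,
                              config = tiny_config(n_runs = 1), seed = 71)
  strict <- res$results[res$results$strict, ]
  expect_gte(res$tallies$strict_correct,
             ceiling(0.8 * max(nrow(strict), 1)))
})
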