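test_that("compatibility implements the wildcard product rule", {
  expect_equal(compatibility("101", "101"), 1L)
  expect_equal(compatibility("001", "201"), 1L)
  expect_equal(compatibility("100", "001"), 0L)
  expect_equal(compatibility("222", "010"), 1L)
  expect_error(compatibility("10", "100"), "equal length")
})

test_that("L=1 has the unique two-node path", {
  set.seed(31)
  tr <- simulate_trajectories(uniform_network(1), 5)
  expect_true(all(tr$node == "1"))
  expect_true(all(tr$trait == 1))
})

test_that("acquisition orders are permutations and uniform-network node
           visits match enumeration", {
  set.seed(32)
  net <- uniform_network(3)
  orders <- acquisition_orders(net, 3e4)
  expect_true(all(apply(orders, 1, function(o) all(sort(o) == 1:3))))
  # exact path enumeration gives P(visit 100) = 1/3
  visited100 <- mean(orders[, 1] == 1)
  se <- sqrt(1 / 3 * 2 / 3 / nrow(orders))
  expect_lt(abs(visited100 - 1 / 3), 3 * se)
})

test_that("worked L=2 example: species '12' has likelihood one half", {
  set.seed(33)
  net <- uniform_network(2)
  # exact: two equiprobable paths, only the 10-intermediate is compatible
  expect_equal(exhaustive_log_likelihood(net, "12")$loglik, log(0.5))
  est <- ensemble_log_likelihood(net, "12", n_chain = 2e4)
  se <- sqrt(0.5 * 0.5 / 2e4) / 0.5  # delta method on log scale
  expect_lt(abs(est$loglik - log(0.5)), 3 * se)
})

test_that("an all-2 species contributes exactly L-1 per trajectory and
           shifts the log-likelihood by ln(L-1)", {
  set.seed(34)
  for (L in c(2, 4)) {
    net <- random_network(L)
    wild <- paste(rep("2", L), collapse = "")
    est <- ensemble_log_likelihood(net, wild, n_chain = 500)
    expect_equal(est$terms$term, L - 1)
    base <- exhaustive_log_likelihood(net, c("1" = substr("1000", 1, L)))
    # appending the wildcard species shifts the exact loglik by ln(L-1)
    both <- exhaustive_log_likelihood(net, c(substr("1000", 1, L), wild))
    expect_equal(both$loglik - base$loglik, log(L - 1))
  }
})

test_that("a species no intermediate node can match yields the -Inf
           sentinel naming it", {
  set.seed(35)
  net <- uniform_network(2)
  expect_warning(est <- ensemble_log_likelihood(net, c(bad = "11"),
                                                n_chain = 100),
                 "bad")
  expect_identical(est$loglik, -Inf)
  expect_identical(exhaustive_log_likelihood(net, "11")$loglik, -Inf)
})

test_that("empty species list has zero log-likelihood", {
  expect_equal(exhaustive_log_likelihood(uniform_network(3),
                                         character())$loglik, 0)
  set.seed(36)
  expect_equal(ensemble_log_likelihood(uniform_network(3), character(),
                                       n_chain = 10)$loglik, 0)
})

test_that("occupancy-propagation likelihood equals explicit path
           enumeration on random networks", {
  set.seed(37)
  for (L in c(3, 4)) {
    for (rep in 1:5) {
      net <- random_network(L)
      strings <- vapply(1:3, function(i) {
        paste(sample(c("0", "1", "2"), L, replace = TRUE,
                     prob = c(.4, .3, .3)), collapse = "")
      }, character(1))
      expect_equal(exhaustive_log_likelihood(net, strings)$loglik,
                   brute_exact_loglik(net, strings), tolerance = 1e-10)
    }
  }
})

test_that("the Monte-Carlo estimate converges on the exact value and is
           invariant to species order", {
  set.seed(38)
  net <- random_network(4)
  strings <- c("1022", "0120", "2222")
  exact <- exhaustive_log_likelihood(net, strings)$loglik
  ests <- replicate(6, ensemble_log_likelihood(net, strings,
                                               n_chain = 5e3)$loglik)
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - exact), 3 * se + 1e-12)
  # permutation invariance given the same ensemble seed
  set.seed(39)
  a <- ensemble_log_likelihood(net, strings, n_chain = 2e3)$loglik
  set.seed(39)
  b <- ensemble_log_likelihood(net, rev(strings), n_chain = 2e3)$loglik
  expect_equal(a, b)
})

test_that("exhaustive likelihood refuses large L", {
  expect_error(exhaustive_log_likelihood(uniform_network(9), "222222222"),
               class = "traitpaths_resource_error")
})
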