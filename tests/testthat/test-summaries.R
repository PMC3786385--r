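test_that("summary matrices are exactly doubly stochastic by counting", {
  set.seed(51)
  pi <- summarize_network(random_network(4), n_chain = 500)
  expect_equal(unname(colSums(pi)), rep(1, 4))
  expect_equal(unname(rowSums(pi)), rep(1, 4))
})

test_that("uniform network summary is flat at 1/L (enumeration symmetry)", {
  set.seed(52)
  n <- 2e4
  pi <- summarize_network(uniform_network(4), n_chain = n)
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(max(abs(pi - 0.25)), 3.5 * se)
})

test_that("a network concentrated on one permutation has a permutation
           summary matrix", {
  set.seed(53)
  L <- 4
  ord <- c(3, 1, 4, 2)
  W <- matrix(1e-9, 2^L, L)
  v <- 0
  for (b in ord) {
    W[v + 1, b] <- 1e9
    v <- v + 2^(b - 1)
  }
  net <- traitpaths:::new_trait_network(W, L)
  pi <- summarize_network(net, n_chain = 2000)
  target <- matrix(0, L, L)
  target[cbind(ord, seq_len(L))] <- 1
  expect_equal(unclass(pi), target, ignore_attr = TRUE)
})

test_that("coarse-graining block-sums columns and conserves row mass", {
  idp <- diag(16)
  cg <- coarse_grain(idp, block = 4)
  expect_equal(dim(cg), c(16, 4))
  for (i in 1:16) {
    expect_equal(unname(cg[i, ceiling(i / 4)]), 1)
  }
  unif <- matrix(1 / 16, 16, 16)
  expect_true(all(abs(coarse_grain(unif) - 0.25) < 1e-12))
  expect_equal(unname(rowSums(cg)), rep(1, 16))
  expect_error(coarse_grain(diag(6), block = 4),
               class = "traitpaths_config_error")
})

test_that("posterior summaries average retained samples with sd halos", {
  d <- c("100", "110")
  fit <- mcmc_run(d, config = tiny_config(seed = 54))
  ps <- posterior_summaries(fit)
  expect_equal(ps$n, dim(fit$pi_samples)[3])
  # mean of doubly stochastic matrices stays doubly stochastic
  expect_lt(max(abs(colSums(ps$mean) - 1)), 1e-9)
  expect_lt(max(abs(rowSums(ps$mean) - 1)), 1e-9)
  # single-sample posterior has zero spread
  one <- fit
  one$pi_samples <- fit$pi_samples[, , 1, drop = FALSE]
  expect_true(all(posterior_summaries(one)$sd == 0))
})

test_that("landscape PCA separates subgroups built from different orderings
           and not identical ones", {
  cfg <- tiny_config(seed = 55)
  d1 <- generate_diagonal(L = 4, n_species = 20, ordering = 1:4, seed = 56)
  d2 <- generate_diagonal(L = 4, n_species = 20, ordering = 4:1, seed = 57)
  pca <- subgroup_landscape_pca(list(fwd = d1, rev = d2), config = cfg,
                                n_matrices = 30)
  expect_equal(ncol(pca$loadings), nrow(pca$loadings))
  expect_equal(nrow(pca$loadings), 16)  # flattened L x L
  expect_gt(pca$separation, 1)
  same <- subgroup_landscape_pca(list(a = d1, b = d1), config = cfg,
                                 n_matrices = 30)
  expect_lt(same$separation, 1)
})

test_that("autoplot methods return ggplot objects", {
  d <- c("100", "110")
  fit <- mcmc_run(d, config = tiny_config(seed = 58))
  expect_s3_class(autoplot(posterior_summaries(fit)), "ggplot")
  expect_s3_class(autoplot(contingency_tables(uniform_network(3),
                                              n_chain = 100)), "ggplot")
})
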