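test_that("monotone successors flip exactly one zero", {
  expect_setequal(monotone_successors("000"), c("100", "010", "001"))
  expect_length(monotone_successors("111"), 0)
  expect_equal(monotone_successors("10"), "11")
})

test_that("total monotone edge count is L * 2^(L-1), by enumeration at L=3", {
  nodes <- traitpaths:::node_to_string(0:7, 3)
  n_edges <- sum(lengths(lapply(nodes, monotone_successors)))
  expect_equal(n_edges, 12)
  expect_equal(n_edges, 3 * 2^(3 - 1))
})

test_that("uniform network assigns equal outgoing probabilities", {
  tp <- transition_probabilities(uniform_network(2))
  expect_equal(tp$prob[tp$from == "00" & tp$to == "10"], 0.5)
  p1 <- transition_probabilities(uniform_network(1))
  expect_equal(p1$prob, 1)
  # every non-terminal row sums to one
  sums <- tapply(tp$prob, tp$from, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("the L=16 phenotype space has 65536 nodes", {
  net <- uniform_network(16)
  expect_equal(nrow(net$W), 65536)
  expect_error(uniform_network(21), class = "traitpaths_resource_error")
})

test_that("perturbation kernel is log-normal with the requested scale", {
  set.seed(21)
  net <- uniform_network(3)
  draws <- replicate(200, {
    p <- perturb_network(net, sigma = 0.1)
    log(p$W[traitpaths:::valid_edge_mask(3)])  # w was 1, so this is ln(w'/w)
  })
  d <- as.numeric(draws)  # 12 edges x 200 reps
  expect_lt(abs(mean(d)), 3 * 0.1 / sqrt(length(d)))
  expect_lt(abs(sd(d) - 0.1), 0.005)
})

test_that("perturbation preserves row-stochasticity and edge sparsity", {
  set.seed(22)
  net <- random_network(4)
  p <- perturb_network(net, 0.5)
  tp <- transition_probabilities(p)
  sums <- tapply(tp$prob, tp$from, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # same structural edge set as the uniform reference
  tp0 <- transition_probabilities(uniform_network(4))
  expect_setequal(paste(tp$from, tp$to), paste(tp0$from, tp0$to))
  expect_error(perturb_network(net, -1), "sigma")
})

test_that("vanishing sigma leaves transition probabilities unchanged", {
  set.seed(23)
  net <- random_network(3)
  p <- perturb_network(net, 1e-12)
  expect_equal(transition_probabilities(p)$prob,
               transition_probabilities(net)$prob, tolerance = 1e-8)
})

test_that("network serialization round-trips exactly", {
  set.seed(24)
  net <- random_network(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path, seed = 24)
  back <- read_network(path)
  msk <- traitpaths:::valid_edge_mask(3)
  expect_identical(back$W[msk], net$W[msk])
  expect_equal(attr(back, "seed"), 24)
})

test_that("trajectories on positive-weight networks reach the derived state
           in exactly L steps", {
  set.seed(25)
  for (L in c(1, 3, 5)) {
    tr <- simulate_trajectories(random_network(L), 20)
    final <- tr[tr$step == L, ]
    expect_true(all(final$node == paste(rep("1", L), collapse = "")))
    expect_equal(nrow(tr), 20 * L)
  }
})
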