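test_that("well-separated clusters are split correctly by both methods", {
  x <- c(0.9, 1.0, 1.1, 9.8, 10.0, 10.2)
  expect_equal(em_binarize(x, "larger")$scores, c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(hclust_binarize(x, "larger")$scores, c(0L, 0L, 0L, 1L, 1L, 1L))
})

test_that("degenerate and insufficient inputs are rejected", {
  expect_error(em_binarize(c(5, 5, 5, 5)),
               class = "traitpaths_degenerate_cluster")
  expect_error(hclust_binarize(c(5, 5, 5, 5)),
               class = "traitpaths_degenerate_cluster")
  expect_error(em_binarize(7), class = "traitpaths_insufficient_data")
})

test_that("EM recovers generating components on a simulated mixture", {
  set.seed(101)
  x <- c(rnorm(50, 0, 1), rnorm(50, 6, 1))
  truth <- rep(c(0L, 1L), each = 50)
  fit <- em_binarize(x, "larger")
  expect_gte(sum(fit$scores == truth), 98)
  expect_length(fit$report$means, 2)
  expect_length(fit$report$weights, 2)
})

test_that("complete-linkage puts the far outlier alone", {
  # hand enumeration: merging 1 and 2 first (distance 1), 100 stays apart
  expect_equal(hclust_binarize(c(1, 2, 100), "larger")$scores, c(0L, 0L, 1L))
})

test_that("binarization is invariant to positive affine rescaling and flips
           with direction", {
  set.seed(7)
  x <- c(rnorm(20, 0), rnorm(20, 5))
  for (f in list(em_binarize, hclust_binarize)) {
    base <- f(x, "larger")$scores
    expect_equal(f(3 * x + 10, "larger")$scores, base)
    expect_equal(f(x, "smaller")$scores, 1L - base)
  }
})

test_that("control-relative scoring follows the closeness rule with a
           conservative tie", {
  expect_identical(control_relative_score(8, 1, 10), 1L)
  expect_identical(control_relative_score(1, 1, 10), 0L)
  expect_identical(control_relative_score(5.5, 1, 10), 0L)   # equidistant
  expect_identical(control_relative_score(5.5, 1, 10, tie = 1L), 1L)
  expect_error(control_relative_score(3, 2, 2),
               class = "traitpaths_ambiguous_controls")
})

test_that("immunolocalisation scores require complete absence from one cell
           type", {
  expect_identical(immunolocalisation_score("absent_in_M"), 1L)
  expect_identical(immunolocalisation_score("absent_in_BS"), 1L)
  expect_identical(immunolocalisation_score("present_in_both"), 0L)
  expect_error(immunolocalisation_score("sometimes_absent"))
})

test_that("assembled phenotype strings encode presence/absence/missing and
           anchor the reference types", {
  d <- data.frame(
    species = c("c3", "int1", "int2", "c4"),
    type = c("C3", "C3-C4", "C3-C4", "C4"),
    t1 = c(0.1, 5.2, 0.2, 5.0),
    t2 = c(1.0, NA, 9.0, 10.0)
  )
  out <- assemble_phenotype_strings(d, method = "hclust")
  expect_equal(out$phenotype[out$species == "int1"], "12")
  expect_equal(out$phenotype[out$species == "c3"], "00")
  expect_equal(out$phenotype[out$species == "c4"], "11")
  expect_true(all(nchar(out$phenotype) == 2))
  rep <- binarization_report(out)
  expect_named(rep, c("t1", "t2"))
  expect_equal(rep$t1$method, "hclust")
})

test_that("an all-missing intermediate is retained as an all-2 string with a
           warning", {
  d <- data.frame(species = c("a", "b"), type = c("C3-C4", "C3-C4"),
                  t1 = c(NA, 1), t2 = c(NA, 5))
  expect_warning(
    out <- assemble_phenotype_strings(
      d, method = c(t1 = "binary", t2 = "control"),
      controls = list(t2 = c(c3 = 0, c4 = 10))),
    "all-2"
  )
  expect_equal(out$phenotype[out$species == "a"], "22")
})

test_that("mixed scoring routes combine into one string", {
  d <- data.frame(
    species = c("x", "y"), type = c("C3-C4", "C3-C4"),
    act = c(9.5, 0.5),
    loc = c("absent_in_M", "present_in_both"),
    bin = c(1L, 0L)
  )
  out <- assemble_phenotype_strings(
    d, method = c(act = "control", loc = "immuno", bin = "binary"),
    controls = list(act = c(c3 = 0, c4 = 10))
  )
  expect_equal(out$phenotype, c("111", "000"))
})
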