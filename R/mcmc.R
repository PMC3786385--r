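#' MCMC configuration
#'
#' Bundles the sampler settings. The study-scale defaults are sigma = 0.1
#' for the log-normal kernel, 2e4 burn-in steps, 2e5 sampling steps, 40
#' independent runs and 2e4 trajectories per likelihood evaluation;
#' `scaled_mcmc_config()` is the desk-scale preset (L <= 8: burn-in 1e3,
#' 1e4 sampling steps, 2e3 trajectories, 4 runs) used throughout the test
#' suite, and the study-scale preset is long-running.
#'
#' @param sigma kernel scale in log-weight space
#' @param burn_in burn-in iterations
#' @param samples post-burn-in iterations
#' @param n_runs independent runs for [mcmc_multirun()]
#' @param n_chain trajectories per likelihood evaluation
#' @param thin keep every `thin`-th post-burn-in state
#' @param seed integer seed (runs `k` of a multirun use `seed + k - 1`)
#' @param keep_networks store thinned networks (needed for prediction and
#'   contingency analyses); default on for `L <= 12`
#' @param refresh_incumbent re-estimate the incumbent's likelihood every
#'   iteration instead of storing it (default `FALSE`: the stored,
#'   pseudo-marginal-style variant)
#' @return a list of class `mcmc_config`
#' @export
mcmc_config <- function(sigma = 0.1, burn_in = 2e4, samples = 2e5,
                        n_runs = 40, n_chain = 2e4, thin = 100,
                        seed = NULL, keep_networks = NULL,
                        refresh_incumbent = FALSE) {
  stopifnot(sigma > 0, burn_in >= 0, samples >= 1, n_runs >= 1,
            n_chain >= 1, thin >= 1)
  structure(list(sigma = sigma, burn_in = as.integer(burn_in),
                 samples = as.integer(samples), n_runs = as.integer(n_runs),
                 n_chain = as.integer(n_chain), thin = as.integer(thin),
                 seed = seed, keep_networks = keep_networks,
                 refresh_incumbent = isTRUE(refresh_incumbent)),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
scaled_mcmc_config <- function(sigma = 0.1, burn_in = 1e3, samples = 1e4,
                               n_runs = 4, n_chain = 2e3, thin = 100,
                               seed = NULL, ...) {
  mcmc_config(sigma = sigma, burn_in = burn_in, samples = samples,
              n_runs = n_runs, n_chain = n_chain, thin = thin,
              seed = seed, ...)
}

#' Metropolis MCMC over transition networks
#'
#' Samples transition networks in proportion to their ensemble emission
#' likelihood. Each iteration perturbs every edge weight with the
#' log-normal kernel (a symmetric proposal in log-weight space), estimates
#' the proposal's log-likelihood with a fresh trajectory ensemble, and
#' accepts when the proposal's log-likelihood exceeds the incumbent's by
#' more than log(r), with r drawn uniformly from (0, 1). The incumbent's
#' log-likelihood estimate is stored, not refreshed (see
#' `refresh_incumbent`). The chain starts from a randomly initialised
#' network (i.i.d. `exp(N(0,1))` weights), re-drawn up to 100 times if the
#' data are incompatible with it. Thinned post-burn-in states are retained;
#' for each, an acquisition-order summary matrix is computed from a fresh
#' ensemble on that network.
#'
#' @param data phenotype data for the intermediate species (strings over
#'   `{0,1,2}`, a data frame with a `phenotype` column, or a 0/1/2 matrix);
#'   may be empty, in which case the likelihood is constant and the sampler
#'   explores the prior kernel
#' @param L number of traits; required only when `data` is empty
#' @param config an [mcmc_config()]
#' @return an object of class `trait_mcmc`: `pi_samples` (`L x L x n`
#'   array), `sample_loglik`, `networks` (list of `trait_network`, if
#'   kept), `loglik_trace`, `accept_trace`, `acceptance_rate`, `L`,
#'   `config`, `data`
#' @examples
#' set.seed(1)
#' fit <- mcmc_run(c("100", "110"), config = scaled_mcmc_config(
#'   burn_in = 50, samples = 200, n_chain = 200, thin = 20))
#' glance(fit)
#' @export
mcmc_run <- function(data, L = NULL, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"))
  mat <- as_phenotype_matrix(data)
  if (nrow(mat) == 0) {
    if (is.null(L)) abort("L must be given when data is empty")
    mat <- matrix(integer(), nrow = 0, ncol = L)
  }
  L <- check_L(ncol(mat))
  if (!is.null(config$seed)) set.seed(config$seed)
  msk <- phenotype_masks(mat)

  # random initialization, re-drawn while the data reject it outright
  W0 <- NULL
  ll0 <- -Inf
  for (try in seq_len(100)) {
    W0 <- matrix(exp(rnorm(2^L * L)), nrow = 2^L, ncol = L)
    r0 <- cpp_ensemble(W0, L, msk$m1, msk$m0, config$n_chain)
    ll0 <- r0$loglik
    if (is.finite(ll0)) break
  }
  if (!is.finite(ll0)) {
    bad <- rownames(mat)[r0$S == 0]
    abort(paste0("could not initialise: data incompatible with 100 random ",
                 "networks (species: ", paste(bad, collapse = ", "), ")"),
          class = "traitpaths_init_error")
  }

  keep <- config$keep_networks %||% (L <= 12)
  res <- cpp_mcmc(W0, ll0, L, msk$m1, msk$m0, config$n_chain, config$sigma,
                  config$burn_in, config$samples, config$thin,
                  keep, config$refresh_incumbent)
  networks <- if (keep) {
    lapply(res$networks, new_trait_network, L = L)
  } else {
    list()
  }
  structure(list(
    pi_samples = res$pi_samples,
    sample_loglik = as.numeric(res$sample_loglik),
    networks = networks,
    loglik_trace = as.numeric(res$loglik_trace),
    accept_trace = as.logical(res$accept_trace),
    acceptance_rate = res$acceptance_rate,
    L = L, config = config, data = mat
  ), class = "trait_mcmc")
}

#' Independent MCMC runs with a convergence report
#'
#' Runs `config$n_runs` independent chains (run `k` seeded `seed + k - 1`
#' when a seed is set) and compares their posterior-mean summary matrices:
#' the maximum absolute cellwise deviation between any run and the pooled
#' mean, and the ratio of between-run to within-run cellwise variance.
#'
#' @inheritParams mcmc_run
#' @return class `trait_mcmc_multi`: `runs` (list of `trait_mcmc`),
#'   `convergence` (tibble with `max_deviation`, `bw_ratio`, `n_runs`),
#'   `L`, `config`
#' @export
mcmc_multirun <- function(data, L = NULL, config = mcmc_config()) {
  stopifnot(inherits(config, "mcmc_config"), config$n_runs >= 1)
  runs <- lapply(seq_len(config$n_runs), function(k) {
    cfg <- config
    if (!is.null(config$seed)) cfg$seed <- config$seed + k - 1
    mcmc_run(data, L = L, config = cfg)
  })
  means <- lapply(runs, function(r) apply(r$pi_samples, c(1, 2), mean))
  pooled <- Reduce(`+`, means) / length(means)
  max_dev <- max(vapply(means, function(m) max(abs(m - pooled)), numeric(1)))
  within <- mean(vapply(runs, function(r) {
    mean(apply(r$pi_samples, c(1, 2), var))
  }, numeric(1)))
  between <- mean((Reduce(`+`, lapply(means, function(m) (m - pooled)^2)) /
                     max(length(means) - 1, 1)))
  structure(list(
    runs = runs,
    convergence = tibble(n_runs = length(runs), max_deviation = max_dev,
                         bw_ratio = if (within > 0) between / within else NA_real_),
    L = runs[[1]]$L, config = config
  ), class = "trait_mcmc_multi")
}

# pooled L x L x n array of posterior pi samples from fits of either class
pooled_pi_samples <- function(fit) {
  if (inherits(fit, "trait_mcmc_multi")) {
    arrs <- lapply(fit$runs, function(r) r$pi_samples)
    L <- fit$L
    array(unlist(arrs), dim = c(L, L, sum(vapply(arrs, function(a) dim(a)[3],
                                                 numeric(1)))))
  } else if (inherits(fit, "trait_mcmc")) {
    fit$pi_samples
  } else {
    abort("expected a trait_mcmc or trait_mcmc_multi object")
  }
}

pooled_networks <- function(fit) {
  nets <- if (inherits(fit, "trait_mcmc_multi")) {
    unlist(lapply(fit$runs, function(r) r$networks), recursive = FALSE)
  } else if (inherits(fit, "trait_mcmc")) {
    fit$networks
  } else if (inherits(fit, "trait_network")) {
    list(fit)
  } else if (is.list(fit) && all(vapply(fit, inherits, logical(1),
                                        "trait_network"))) {
    fit
  } else {
    abort("expected a fit with stored networks or a list of trait_network")
  }
  if (!length(nets)) {
    abort("no stored networks: re-run MCMC with keep_networks = TRUE")
  }
  nets
}

#' @export
print.trait_mcmc <- function(x, ...) {
  cat("<trait_mcmc> L =", x$L, "|", dim(x$pi_samples)[3], "retained samples |",
      "acceptance", sprintf("%.3f", x$acceptance_rate), "\n")
  invisible(x)
}

#' @export
print.trait_mcmc_multi <- function(x, ...) {
  cat("<trait_mcmc_multi>", length(x$runs), "runs | L =", x$L,
      "| max cross-run deviation",
      sprintf("%.4f", x$convergence$max_deviation), "\n")
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.trait_mcmc <- function(x, ...) {
  arr <- pooled_pi_samples(x)
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), sd)
  tidyr::expand_grid(trait = seq_len(x$L), step = seq_len(x$L)) |>
    dplyr::mutate(mean = m[cbind(.data$trait, .data$step)],
                  sd = s[cbind(.data$trait, .data$step)])
}

#' @rdname tidy
#' @export
tidy.trait_mcmc_multi <- function(x, ...) tidy.trait_mcmc(x, ...)

#' @rdname tidy
#' @export
glance.trait_mcmc <- function(x, ...) {
  tibble(
    L = x$L,
    n_samples = dim(x$pi_samples)[3],
    acceptance_rate = x$acceptance_rate,
    mean_loglik = mean(x$sample_loglik),
    max_loglik = max(x$sample_loglik)
  )
}

#' @rdname tidy
#' @export
glance.trait_mcmc_multi <- function(x, ...) {
  g <- dplyr::bind_rows(lapply(x$runs, glance))
  dplyr::bind_cols(
    tibble(L = x$L, n_samples = sum(g$n_samples),
           acceptance_rate = mean(g$acceptance_rate),
           mean_loglik = mean(g$mean_loglik),
           max_loglik = max(g$max_loglik)),
    x$convergence[c("n_runs", "max_deviation", "bw_ratio")]
  )
}
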