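#' Predict missing trait values for a species
#'
#' For every locus coded `2` in the species' phenotype string, simulates a
#' trajectory ensemble on each posterior network, finds the intermediate
#' nodes compatible with the species, and records the value the node
#' carries at the missing locus. Within each network the statistic is the
#' proportion of compatible-node encounters carrying a 1; the posterior
#' mean `mu` and standard deviation `sigma` are taken across networks, so
#' `sigma` measures posterior (not sampling) spread. Calls: `present` if
#' `mu > 0.75`, `absent` if `mu < 0.25`, otherwise `neutral` (boundary
#' values are neutral); a call is `strict` when the threshold also lies
#' outside one standard deviation (`mu - sigma > 0.75` or
#' `mu + sigma < 0.25`).
#'
#' @param fit a `trait_mcmc`/`trait_mcmc_multi` with stored networks, a
#'   single `trait_network`, or a list of networks
#' @param species one phenotype string with at least one `2`
#' @param n_chain trajectories per network
#' @return a tibble, one row per missing locus: `locus`, `mean`, `sd`,
#'   `n_networks` (networks with at least one compatible encounter),
#'   `call`, `strict`
#' @examples
#' set.seed(1)
#' predict_missing(uniform_network(2), "21", n_chain = 500)
#' @export
predict_missing <- function(fit, species, n_chain = 2e4) {
  mat <- as_phenotype_matrix(species)
  if (nrow(mat) != 1) abort("species must be a single phenotype string")
  missing_loci <- which(mat[1, ] == 2L)
  if (!length(missing_loci)) {
    abort("species has no missing loci (no 2s) to predict")
  }
  nets <- pooled_networks(fit)
  L <- nets[[1]]$L
  if (ncol(mat) != L) abort("phenotype string must have length L")
  msk <- phenotype_masks(mat)
  props <- matrix(NA_real_, nrow = length(nets), ncol = length(missing_loci))
  for (k in seq_along(nets)) {
    res <- cpp_predict_counts(nets[[k]]$W, L, msk$m1[1], msk$m0[1],
                              as.integer(missing_loci), as.integer(n_chain))
    if (res$encounters > 0) {
      props[k, ] <- res$ones / res$encounters
    }
  }
  ok <- !is.na(props[, 1])
  purrr::map_dfr(seq_along(missing_loci), function(j) {
    if (!any(ok)) {
      return(tibble(locus = missing_loci[j], mean = NA_real_, sd = NA_real_,
                    n_networks = 0L, call = NA_character_, strict = FALSE))
    }
    mu <- mean(props[ok, j])
    sig <- if (sum(ok) > 1) sd(props[ok, j]) else 0
    call <- if (mu > 0.75) "present" else if (mu < 0.25) "absent" else "neutral"
    strict <- (call == "present" && mu - sig > 0.75) ||
      (call == "absent" && mu + sig < 0.25)
    tibble(locus = missing_loci[j], mean = mu, sd = sig,
           n_networks = sum(ok), call = call, strict = strict)
  })
}

#' Leave-one-out occlusion validation of predictions
#'
#' Samples `n_points` distinct observed (non-missing) entries of the
#' dataset without replacement; for each, occludes that single entry, runs
#' full inference on the occluded dataset, predicts the entry back, and
#' compares the call with the held-out truth. Tallies strict-correct,
#' strict false positive/negative and neutral outcomes (non-strict calls
#' count as neutral, matching how the study reports its 29-point
#' validation).
#'
#' @param data phenotype dataset (strings over `{0,1,2}`)
#' @param n_points number of entries to occlude
#' @param config an [mcmc_config()]; one MCMC run is fitted per occluded
#'   dataset (use `n_runs` in the config to pool runs)
#' @param seed integer seed controlling both the point sampling and the
#'   per-point inference
#' @return class `occlusion_result`: `results` tibble (`species`, `locus`,
#'   `truth`, `mean`, `sd`, `call`, `strict`, `outcome`) and `tallies`
#'   tibble (`strict_correct`, `strict_false_positive`,
#'   `strict_false_negative`, `neutral`)
#' @export
occlusion_experiment <- function(data, n_points, config = mcmc_config(),
                                 seed = 1) {
  mat <- as_phenotype_matrix(data)
  obs <- which(mat != 2L, arr.ind = TRUE)
  if (nrow(obs) < n_points) {
    abort(paste0("dataset has only ", nrow(obs), " observed entries; ",
                 n_points, " requested"))
  }
  set.seed(seed)
  picks <- obs[sample(nrow(obs), n_points), , drop = FALSE]
  rows <- purrr::map_dfr(seq_len(n_points), function(p) {
    i <- picks[p, 1]
    j <- picks[p, 2]
    truth <- mat[i, j]
    occ <- mat
    occ[i, j] <- 2L
    cfg <- config
    cfg$seed <- seed + p
    cfg$keep_networks <- TRUE
    fit <- if (config$n_runs > 1) {
      mcmc_multirun(occ, config = cfg)
    } else {
      mcmc_run(occ, config = cfg)
    }
    pred <- predict_missing(fit, paste(occ[i, ], collapse = ""),
                            n_chain = config$n_chain)
    pred <- pred[pred$locus == j, ]
    outcome <- if (!isTRUE(pred$strict)) {
      "neutral"
    } else if ((pred$call == "present") == (truth == 1L)) {
      "strict_correct"
    } else if (pred$call == "present") {
      "strict_false_positive"
    } else {
      "strict_false_negative"
    }
    tibble(species = rownames(mat)[i], locus = j, truth = truth,
           mean = pred$mean, sd = pred$sd, call = pred$call,
           strict = isTRUE(pred$strict), outcome = outcome)
  })
  tallies <- tibble(
    strict_correct = sum(rows$outcome == "strict_correct"),
    strict_false_positive = sum(rows$outcome == "strict_false_positive"),
    strict_false_negative = sum(rows$outcome == "strict_false_negative"),
    neutral = sum(rows$outcome == "neutral")
  )
  structure(list(results = rows, tallies = tallies),
            class = "occlusion_result")
}

#' @export
print.occlusion_result <- function(x, ...) {
  t <- x$tallies
  cat("<occlusion_result>", nrow(x$results), "occluded points |",
      t$strict_correct, "strict correct,",
      t$strict_false_positive + t$strict_false_negative, "strict wrong,",
      t$neutral, "neutral\n")
  invisible(x)
}

#' Contingent-acquisition tables
#'
#' Builds the `L x L` table `gamma` with `gamma[i, j]` = probability that
#' trait `j` is the second acquisition given trait `i` was acquired first.
#' For each start trait `i`, trajectories are simulated from the node with
#' only trait `i` present and the next acquisition recorded, averaged over
#' posterior networks. A pair of traits whose acquisition is mechanistically
#' linked shows elevated `gamma[i, j]` and `gamma[j, i]`; the diagonal is
#' undefined (`NA`) and each row sums to 1 over `j != i`.
#'
#' @param fit a fit with stored networks, a `trait_network`, or a list of
#'   networks
#' @param n_chain conditioned trajectories per start trait per network
#' @return an `L x L` matrix of class `contingency_table`
#' @examples
#' set.seed(1)
#' contingency_tables(uniform_network(3), n_chain = 2000)
#' @export
contingency_tables <- function(fit, n_chain = 2e4) {
  nets <- pooled_networks(fit)
  L <- nets[[1]]$L
  if (L < 2) abort("contingency analysis requires L >= 2")
  gamma <- matrix(0, L, L)
  for (nw in nets) {
    for (i in seq_len(L)) {
      counts <- cpp_first_step_counts(nw$W, L, as.integer(2^(i - 1)),
                                      as.integer(n_chain))
      gamma[i, ] <- gamma[i, ] + counts / n_chain
    }
  }
  gamma <- gamma / length(nets)
  diag(gamma) <- NA_real_
  dimnames(gamma) <- list(first = paste0("trait", seq_len(L)),
                          second = paste0("trait", seq_len(L)))
  class(gamma) <- c("contingency_table", class(gamma))
  gamma
}

#' @rdname contingency_tables
#' @param object a `contingency_table`
#' @param ... unused
#' @export
autoplot.contingency_table <- function(object, ...) {
  L <- nrow(object)
  d <- tidyr::expand_grid(first = seq_len(L), second = seq_len(L)) |>
    dplyr::mutate(gamma = object[cbind(.data$first, .data$second)]) |>
    dplyr::filter(!is.na(.data$gamma))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$second, y = .data$first,
                                  fill = .data$gamma)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::scale_y_reverse(breaks = seq_len(L)) +
    ggplot2::scale_x_continuous(breaks = seq_len(L)) +
    ggplot2::labs(x = "second acquisition", y = "first acquisition",
                  fill = expression(gamma)) +
    ggplot2::theme_minimal()
}

#' Search for a single deterministic acquisition ordering
#'
#' Asks whether one fixed ordering of trait acquisitions (trait `T_n`
#' always acquired at step `n`) can account for every observed species. An
#' ordering accounts for a species when some prefix set of the ordering is
#' compatible with the species' string, which holds exactly when every
#' observed-present trait precedes every observed-absent trait in the
#' ordering. A dynamic programme over trait subsets finds the maximum
#' number of species any single ordering accounts for (verified against
#' brute-force permutation enumeration for small L in the test suite).
#' Because "unaccounted" can be counted at several granularities, the
#' result reports unaccounted species, the conflicting species-trait
#' observations under the best ordering (mismatches at each species'
#' best-matching prefix), and the distinct traits involved.
#'
#' @param data phenotype dataset (strings over `{0,1,2}`)
#' @return class `ordering_search`: `best_ordering` (integer permutation),
#'   `max_accounted`, `n_species`, `unaccounted_species`,
#'   `unaccounted_observations`, `unaccounted_traits`, `all_accounted`
#'   flag, and `per_species` tibble (`species`, `accounted`, `mismatches`)
#' @examples
#' deterministic_sequence_search(c("10", "01"))
#' @export
deterministic_sequence_search <- function(data) {
  mat <- as_phenotype_matrix(data)
  if (nrow(mat) == 0) abort("dataset is empty")
  L <- check_L(ncol(mat))
  msk <- phenotype_masks(mat)
  dp <- cpp_ordering_dp(L, msk$m1, msk$m0)
  ordering <- as.integer(dp$ordering)
  per <- ordering_coverage(mat, ordering)
  un <- per[!per$accounted, , drop = FALSE]
  structure(list(
    best_ordering = ordering,
    max_accounted = dp$max_accounted,
    n_species = nrow(mat),
    unaccounted_species = nrow(mat) - dp$max_accounted,
    unaccounted_observations = sum(un$mismatches),
    unaccounted_traits = length(unique(unlist(un$mismatch_loci))),
    all_accounted = dp$max_accounted == nrow(mat),
    per_species = per
  ), class = "ordering_search")
}

# coverage and minimal observation conflicts of each species under ordering
ordering_coverage <- function(mat, ordering) {
  L <- ncol(mat)
  prefixes <- rbind(0L, vapply(seq_len(L), function(t) {
    p <- integer(L)
    p[ordering[seq_len(t)]] <- 1L
    p
  }, integer(L)) |> t())
  purrr::map_dfr(seq_len(nrow(mat)), function(i) {
    obs <- mat[i, ]
    mism <- apply(prefixes, 1, function(p) {
      which(obs != 2L & obs != p)
    }, simplify = FALSE)
    counts <- lengths(mism)
    best <- which.min(counts)
    tibble(
      species = rownames(mat)[i],
      accounted = counts[best] == 0L,
      mismatches = counts[best],
      mismatch_loci = list(mism[[best]])
    )
  })
}

#' @export
print.ordering_search <- function(x, ...) {
  cat("<ordering_search>", x$max_accounted, "of", x$n_species,
      "species accounted by best single ordering",
      paste(x$best_ordering, collapse = "-"), "\n")
  if (x$all_accounted) {
    cat("  a single deterministic ordering accounts for all data\n")
  } else {
    cat("  no single ordering accounts for all data (",
        x$unaccounted_species, " species, ", x$unaccounted_observations,
        " observations, ", x$unaccounted_traits,
        " traits unaccounted)\n", sep = "")
  }
  invisible(x)
}
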