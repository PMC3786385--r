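#' Acquisition-order summary matrix of a network
#'
#' The summary dynamics matrix `pi` has `pi[i, n]` = probability that trait
#' `i` is acquired at the `n`-th step of a trajectory. For a single network
#' it is estimated as the empirical frequency over a simulated ensemble; by
#' the counting identity each row and each column of the empirical matrix
#' sums to exactly 1 (every trajectory acquires each trait once and one
#' trait per step).
#'
#' @param net a `trait_network`
#' @param n_chain ensemble size
#' @return an `L x L` matrix of class `summary_matrix` (rows traits,
#'   columns steps)
#' @examples
#' set.seed(1)
#' summarize_network(uniform_network(3), n_chain = 1000)
#' @export
summarize_network <- function(net, n_chain = 2e4) {
  stopifnot(inherits(net, "trait_network"))
  orders <- acquisition_orders(net, n_chain)
  pi_from_orders(orders, net$L)
}

pi_from_orders <- function(orders, L) {
  pi <- matrix(0, L, L)
  for (n in seq_len(L)) {
    tab <- tabulate(orders[, n], nbins = L)
    pi[, n] <- tab / nrow(orders)
  }
  dimnames(pi) <- list(trait = paste0("trait", seq_len(L)),
                       step = paste0("step", seq_len(L)))
  class(pi) <- c("summary_matrix", class(pi))
  pi
}

#' Coarse-grain a summary matrix into step blocks
#'
#' Sums columns of `pi` over consecutive ordinal blocks (quartiles by
#' default, block size 4), giving the probability of each trait being
#' acquired within each coarse time window; with L = 16 this is the
#' sixteen-step to four-quartile reduction.
#'
#' @param pi an `L x L` summary matrix
#' @param block block size; must divide `L`
#' @return an `L x (L/block)` matrix; rows still sum to 1
#' @export
coarse_grain <- function(pi, block = 4) {
  L <- nrow(pi)
  if (L %% block != 0) {
    abort(paste0("block size ", block, " does not divide L = ", L),
          class = "traitpaths_config_error")
  }
  nb <- L %/% block
  cg <- vapply(seq_len(nb), function(q) {
    cols <- ((q - 1) * block + 1):(q * block)
    rowSums(pi[, cols, drop = FALSE])
  }, numeric(L))
  dimnames(cg) <- list(trait = rownames(pi),
                       quartile = paste0("q", seq_len(nb)))
  cg
}

#' Posterior distribution of summary matrices
#'
#' Collects the summary matrices computed for each retained posterior
#' network and reports the cellwise mean (the Bayes estimator plotted as
#' circle diameters in the study's figures) and standard deviation (the
#' halos). The mean inherits double stochasticity from its constituents.
#'
#' @param fit a `trait_mcmc` or `trait_mcmc_multi` object
#' @return class `posterior_summary`: `mean`, `sd` (`L x L` matrices), `n`
#'   (number of posterior samples), `L`
#' @export
posterior_summaries <- function(fit) {
  arr <- pooled_pi_samples(fit)
  if (dim(arr)[3] < 1) abort("no retained posterior samples")
  L <- dim(arr)[1]
  m <- apply(arr, c(1, 2), mean)
  s <- apply(arr, c(1, 2), sd)
  if (dim(arr)[3] == 1) s[] <- 0
  dn <- list(trait = paste0("trait", seq_len(L)),
             step = paste0("step", seq_len(L)))
  dimnames(m) <- dimnames(s) <- dn
  structure(list(mean = m, sd = s, n = dim(arr)[3], L = L),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("<posterior_summary>", x$n, "samples | modal acquisition order:",
      paste(apply(x$mean, 2, which.max), collapse = " "), "\n")
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.posterior_summary <- function(x, ...) {
  tidyr::expand_grid(trait = seq_len(x$L), step = seq_len(x$L)) |>
    dplyr::mutate(mean = x$mean[cbind(.data$trait, .data$step)],
                  sd = x$sd[cbind(.data$trait, .data$step)])
}

#' Plot a posterior summary as a circle-and-halo diagram
#'
#' Circle diameter is the posterior-mean probability of a trait being
#' acquired at each step; the halo radius adds one posterior standard
#' deviation.
#'
#' @param object a `posterior_summary`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.posterior_summary <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$trait)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$mean + .data$sd),
                        shape = 21, colour = "grey60", fill = NA) +
    ggplot2::geom_point(ggplot2::aes(size = .data$mean), shape = 21,
                        fill = "steelblue", colour = "black") +
    ggplot2::scale_size_area(max_size = 8, limits = c(0, NA)) +
    ggplot2::scale_y_reverse(breaks = seq_len(object$L)) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$L)) +
    ggplot2::labs(x = "acquisition step", y = "trait",
                  size = "probability") +
    ggplot2::theme_minimal()
}

#' Compare subgroup landscapes by PCA over sampled summary matrices
#'
#' Runs inference separately on two or more datasets (e.g. monocot vs
#' eudicot intermediates, or NADP-ME vs NAD-ME lineages), samples
#' `n_matrices` summary matrices from each posterior, flattens each to a
#' vector and performs a pooled-centred PCA. A separation statistic --
#' mean between-centroid distance over mean within-subgroup spread in the
#' first two components -- quantifies whether the subgroups occupy
#' distinct regions of landscape space.
#'
#' @param datasets named list of phenotype datasets (each as accepted by
#'   [mcmc_run()])
#' @param config an [mcmc_config()] used for every subgroup
#' @param n_matrices summary-matrix samples per subgroup (study default
#'   1e3), drawn evenly across runs and thinned samples
#' @param include_pooled also fit the concatenation of all subgroups and
#'   project its samples (labelled `"pooled"`)
#' @param matrices `"summary"` (PCA on flattened pi matrices, the primary
#'   analysis) or `"weights"` (PCA on flattened log edge-weight vectors;
#'   requires stored networks; no equivalence between the two is implied)
#' @return class `landscape_pca`: `scores` tibble (`subgroup`, `PC1`,
#'   `PC2`, ...), `sdev`, `loadings`, `separation`
#' @export
subgroup_landscape_pca <- function(datasets, config = mcmc_config(),
                                   n_matrices = 1e3,
                                   include_pooled = FALSE,
                                   matrices = c("summary", "weights")) {
  matrices <- match.arg(matrices)
  if (!is.list(datasets) || length(datasets) < 2) {
    abort("datasets must be a named list of two or more datasets")
  }
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    names(datasets) <- paste0("group", seq_along(datasets))
  }
  if (n_matrices < 2) abort("n_matrices must be >= 2 per subgroup")
  if (include_pooled) {
    pooled_data <- do.call(rbind, lapply(datasets, as_phenotype_matrix))
    datasets <- c(datasets, list(pooled = pooled_data))
  }
  rows <- lapply(names(datasets), function(nm) {
    fit <- tryCatch(
      mcmc_multirun(datasets[[nm]], config = config),
      error = function(e) {
        abort(paste0("inference failed on subset '", nm, "': ",
                     conditionMessage(e)))
      }
    )
    vecs <- if (matrices == "summary") {
      arr <- pooled_pi_samples(fit)
      idx <- unique(round(seq(1, dim(arr)[3], length.out = n_matrices)))
      t(apply(arr[, , idx, drop = FALSE], 3, as.numeric))
    } else {
      nets <- pooled_networks(fit)
      idx <- unique(round(seq(1, length(nets), length.out = n_matrices)))
      msk <- valid_edge_mask(fit$L)
      do.call(rbind, lapply(nets[idx], function(nw) log(nw$W[msk])))
    }
    list(subgroup = rep(nm, nrow(vecs)), vecs = vecs)
  })
  X <- do.call(rbind, lapply(rows, `[[`, "vecs"))
  subgroup <- unlist(lapply(rows, `[[`, "subgroup"))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  # fix component signs: largest-magnitude loading positive
  for (j in seq_len(ncol(pc$rotation))) {
    k <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[k, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- as_tibble(pc$x[, seq_len(min(5, ncol(pc$x))), drop = FALSE]) |>
    dplyr::mutate(subgroup = subgroup, .before = 1)
  structure(list(
    scores = scores, sdev = pc$sdev, loadings = pc$rotation,
    separation = centroid_separation(scores)
  ), class = "landscape_pca")
}

# between-centroid distance over mean within-subgroup spread, in PC1-PC2
centroid_separation <- function(scores) {
  sp <- split(scores[c("PC1", "PC2")], scores$subgroup)
  cents <- lapply(sp, colMeans)
  within <- mean(vapply(names(sp), function(g) {
    z <- sweep(as.matrix(sp[[g]]), 2, cents[[g]])
    mean(sqrt(rowSums(z^2)))
  }, numeric(1)))
  pairs <- utils::combn(names(cents), 2)
  between <- mean(apply(pairs, 2, function(p) {
    sqrt(sum((cents[[p[1]]] - cents[[p[2]]])^2))
  }))
  if (within == 0) {
    if (between == 0) 0 else Inf
  } else {
    between / within
  }
}

#' @export
print.landscape_pca <- function(x, ...) {
  cat("<landscape_pca>", nrow(x$scores), "sampled matrices |",
      length(unique(x$scores$subgroup)), "subgroups | separation",
      sprintf("%.2f", x$separation), "\n")
  invisible(x)
}

#' @rdname subgroup_landscape_pca
#' @param object a `landscape_pca`
#' @param ... unused
#' @export
autoplot.landscape_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               colour = .data$subgroup)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "PC1", y = "PC2", colour = NULL) +
    ggplot2::theme_minimal()
}
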