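#' PCA with EM imputation of missing values
#'
#' Principal component analysis tolerant of missing entries: missing
#' values are initialised at column means and iteratively re-estimated
#' from the current rank-`n_components` reconstruction until the imputed
#' entries stabilise (relative change below `tol`), after which scores are
#' those of a standard PCA on the completed matrix. On a complete matrix
#' this reduces exactly to [stats::prcomp()] (up to component sign). Used
#' to place species with partially measured enzyme activities into a
#' common component space and confirm phenotypic intermediacy.
#'
#' @param x numeric matrix (species x traits), NA for missing
#' @param n_components rank of the reconstruction (and number of scores
#'   returned); at most `min(nrow, ncol)`
#' @param tol convergence tolerance on the relative change of imputed
#'   entries
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   final relative change
#' @return class `pca_em`: `scores`, `loadings`, `sdev`,
#'   `explained_variance` (proportions, non-increasing), `completed`
#'   (imputed matrix), `n_iter`, `converged`
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' x[2, 3] <- NA
#' fit <- pca_em_impute(x, 2)
#' head(tidy(fit))
#' @export
pca_em_impute <- function(x, n_components, tol = 1e-8, max_iter = 1000) {
  x <- as.matrix(x)
  if (n_components > min(dim(x))) {
    abort("n_components must be <= min(nrow, ncol)")
  }
  miss <- is.na(x)
  mu <- colMeans(x, na.rm = TRUE)
  if (anyNA(mu)) abort("some columns have no observed values")
  xc <- x
  for (j in seq_len(ncol(x))) xc[miss[, j], j] <- mu[j]
  n_iter <- 0L
  converged <- !any(miss)
  delta <- 0
  while (!converged && n_iter < max_iter) {
    n_iter <- n_iter + 1L
    pc <- prcomp(xc, center = TRUE, scale. = FALSE)
    k <- seq_len(n_components)
    recon <- pc$x[, k, drop = FALSE] %*% t(pc$rotation[, k, drop = FALSE])
    recon <- sweep(recon, 2, pc$center, `+`)
    old <- xc[miss]
    xc[miss] <- recon[miss]
    delta <- sqrt(sum((xc[miss] - old)^2)) /
      max(sqrt(sum(old^2)), .Machine$double.eps)
    converged <- delta < tol
  }
  if (!converged && any(miss)) {
    abort(paste0("PCA-EM imputation did not converge in ", max_iter,
                 " iterations (last relative change ",
                 formatC(delta, format = "e", digits = 2), ")"),
          class = "traitpaths_convergence_error")
  }
  pc <- prcomp(xc, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = pc$x[, k, drop = FALSE],
    loadings = pc$rotation[, k, drop = FALSE],
    sdev = pc$sdev,
    explained_variance = ev,
    completed = xc,
    n_iter = n_iter,
    converged = TRUE
  ), class = "pca_em")
}

#' @export
print.pca_em <- function(x, ...) {
  cat("<pca_em>", ncol(x$scores), "components |",
      sprintf("%.1f%%", 100 * sum(x$explained_variance[seq_len(
        ncol(x$scores))])), "variance |", x$n_iter, "imputation iterations\n")
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.pca_em <- function(x, ...) {
  s <- x$scores
  as_tibble(s) |>
    dplyr::mutate(row = rownames(s) %||% as.character(seq_len(nrow(s))),
                  .before = 1)
}

#' @rdname tidy
#' @export
glance.pca_em <- function(x, ...) {
  tibble(n_components = ncol(x$scores),
         explained_variance = sum(x$explained_variance[
           seq_len(ncol(x$scores))]),
         n_iter = x$n_iter, converged = x$converged)
}

#' @rdname pca_em_impute
#' @param object a `pca_em`
#' @param colour optional vector (e.g. photosynthetic type) colouring the
#'   points
#' @param ... unused
#' @export
autoplot.pca_em <- function(object, colour = NULL, ...) {
  d <- tidy(object)
  if (!is.null(colour)) d$colour <- colour
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(
      x = sprintf("PC1 (%.0f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.0f%%)", 100 * object$explained_variance[2])
    )
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}
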