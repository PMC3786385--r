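#' Simulate trajectory ensembles
#'
#' Draws monotone trajectories on a transition network: each starts at the
#' all-zeros node (the ancestral, e.g. C3, phenotype), steps according to
#' the row-normalized edge probabilities, and reaches the all-ones node
#' (the derived, e.g. C4, phenotype) in exactly `L` steps, acquiring one
#' trait per step.
#'
#' @param net a `trait_network`
#' @param n number of trajectories
#' @return `simulate_trajectories()`: a tibble with columns `chain`, `step`
#'   (1..L), `trait` (locus acquired at that step) and `node` (bitstring
#'   after the step). `acquisition_orders()`: an `n x L` integer matrix
#'   whose rows are permutations of `1..L`.
#' @examples
#' set.seed(1)
#' simulate_trajectories(uniform_network(3), 2)
#' @export
simulate_trajectories <- function(net, n) {
  orders <- acquisition_orders(net, n)
  L <- net$L
  node_int <- t(apply(orders, 1, function(o) cumsum(2^(o - 1))))
  if (L == 1) node_int <- matrix(node_int, ncol = 1)
  tibble(
    chain = rep(seq_len(n), each = L),
    step = rep(seq_len(L), times = n),
    trait = as.integer(t(orders)),
    node = node_to_string(as.integer(t(node_int)), L)
  )
}

#' @rdname simulate_trajectories
#' @export
acquisition_orders <- function(net, n) {
  stopifnot(inherits(net, "trait_network"), n >= 1)
  cpp_simulate_orders(net$W, net$L, as.integer(n))
}

#' Monte-Carlo ensemble log-likelihood of phenotype data
#'
#' Estimates the hidden-Markov emission likelihood of a set of intermediate
#' phenotype strings given a transition network. An ensemble of `n_chain`
#' trajectories is simulated once; for each species the compatibility of
#' every intermediate node (steps 1..L-1, endpoints excluded) with the
#' species' string is summed over the ensemble, giving `S_i`. The
#' per-species likelihood term is `S_i / n_chain` and the returned estimate
#' is `sum_i log(S_i / n_chain)` (the constant emission probability is
#' dropped, as only likelihood ratios are ever used). A species never
#' matched by any intermediate node yields `-Inf`, reported with the
#' offending species.
#'
#' @param net a `trait_network`
#' @param data phenotype data: character vector of strings over `{0,1,2}`,
#'   a data frame with a `phenotype` column, or a 0/1/2 integer matrix; all
#'   strings must have length `net$L`
#' @param n_chain ensemble size (study default `2e4`)
#' @return a list of class `ensemble_loglik`: `loglik`, per-species tibble
#'   `terms` (`species`, `S`, `term`), `n_chain`, and the ensemble's
#'   acquisition-order frequency matrix `pi`
#' @examples
#' set.seed(1)
#' ensemble_log_likelihood(uniform_network(2), "12", n_chain = 1000)$loglik
#' @export
ensemble_log_likelihood <- function(net, data, n_chain = 2e4) {
  stopifnot(inherits(net, "trait_network"), n_chain >= 1)
  mat <- as_phenotype_matrix(data)
  if (nrow(mat) > 0 && ncol(mat) != net$L) {
    abort("phenotype strings must have length L")
  }
  msk <- phenotype_masks(mat)
  res <- cpp_ensemble(net$W, net$L, msk$m1, msk$m0, as.integer(n_chain))
  terms <- tibble(
    species = rownames(mat) %||% character(),
    S = as.numeric(res$S),
    term = as.numeric(res$S) / n_chain
  )
  if (!is.finite(res$loglik)) {
    warn(paste0("network incompatible with species: ",
                paste(terms$species[terms$S == 0], collapse = ", ")))
  }
  structure(list(loglik = res$loglik, terms = terms, n_chain = n_chain,
                 pi = res$pi),
            class = "ensemble_loglik")
}

#' Exact log-likelihood by exhaustive path enumeration
#'
#' Computes the emission log-likelihood exactly by propagating the full
#' occupancy distribution over hypercube nodes level by level (equivalent
#' to enumerating all `L!` monotone paths with their probabilities) and
#' summing exact expected per-species compatibility over intermediate
#' levels 1..L-1. Used as the deterministic oracle for the Monte-Carlo
#' estimator; refused above `L = 8`.
#'
#' @inheritParams ensemble_log_likelihood
#' @return list: `loglik`, per-species tibble `terms` (`species`, `term` =
#'   exact expected compatibility count per trajectory)
#' @export
exhaustive_log_likelihood <- function(net, data) {
  stopifnot(inherits(net, "trait_network"))
  check_L(net$L, max_L = 8L)
  mat <- as_phenotype_matrix(data)
  if (nrow(mat) == 0) {
    return(list(loglik = 0,
                terms = tibble(species = character(), term = numeric())))
  }
  if (ncol(mat) != net$L) abort("phenotype strings must have length L")
  msk <- phenotype_masks(mat)
  occ <- occupancy_levels(net)
  L <- net$L
  term <- numeric(nrow(mat))
  for (t in seq_len(L - 1)) {
    o <- occ[[t + 1]]
    nodes <- which(o > 0) - 1L
    for (i in seq_len(nrow(mat))) {
      ok <- bitwAnd(nodes, msk$m1[i]) == msk$m1[i] &
        bitwAnd(nodes, msk$m0[i]) == 0L
      term[i] <- term[i] + sum(o[nodes[ok] + 1])
    }
  }
  ll <- if (any(term == 0)) -Inf else sum(log(term))
  list(loglik = ll,
       terms = tibble(species = rownames(mat), term = term))
}

# occupancy distribution over nodes at each level 0..L (list of 2^L vectors)
occupancy_levels <- function(net) {
  L <- net$L
  N <- 2^L
  v_all <- 0:(N - 1)
  level <- vapply(v_all, function(v) sum(bitwAnd(bitwShiftR(v, 0:(L - 1)), 1L)),
                  numeric(1))
  occ <- vector("list", L + 1)
  cur <- numeric(N)
  cur[1] <- 1
  occ[[1]] <- cur
  for (t in seq_len(L)) {
    nxt <- numeric(N)
    for (v in v_all[level == t - 1]) {
      p <- cur[v + 1]
      if (p == 0) next
      zeros <- which(bitwAnd(bitwShiftR(v, seq_len(L) - 1L), 1L) == 0L)
      w <- net$W[v + 1, zeros]
      w <- w / sum(w)
      nxt[v + 2^(zeros - 1) + 1] <- nxt[v + 2^(zeros - 1) + 1] + p * w
    }
    cur <- nxt
    occ[[t + 1]] <- cur
  }
  occ
}

# exact acquisition-order summary matrix pi[i, n] for small L
exact_summary_matrix <- function(net) {
  L <- check_L(net$L, max_L = 12L)
  occ <- occupancy_levels(net)
  pi <- matrix(0, L, L)
  for (n in seq_len(L)) {
    o <- occ[[n]]
    nodes <- which(o > 0) - 1L
    for (v in nodes) {
      zeros <- which(bitwAnd(bitwShiftR(v, seq_len(L) - 1L), 1L) == 0L)
      w <- net$W[v + 1, zeros]
      w <- w / sum(w)
      pi[zeros, n] <- pi[zeros, n] + o[v + 1] * w
    }
  }
  dimnames(pi) <- list(trait = paste0("trait", seq_len(L)),
                       step = paste0("step", seq_len(L)))
  pi
}
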