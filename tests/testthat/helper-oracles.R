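# Independent brute-force oracles used across the suite. These deliberately
# work on bitstrings with string operations and explicit permutation
# enumeration, not the package's occupancy/DP machinery.

all_perms <- function(L) {
  if (L == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(L - 1)
  do.call(rbind, lapply(seq_len(L), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# nodes visited (as strings) along the path acquiring traits in order `ord`
path_nodes <- function(ord) {
  L <- length(ord)
  p <- integer(L)
  vapply(seq_len(L), function(t) {
    p[ord[seq_len(t)]] <<- 1L
    paste(p, collapse = "")
  }, character(1))
}

# probability of a full acquisition ordering under a network
path_prob <- function(net, ord) {
  L <- net$L
  v <- 0
  pr <- 1
  for (b in ord) {
    zeros <- which(bitwAnd(bitwShiftR(v, seq_len(L) - 1L), 1L) == 0L)
    w <- net$W[v + 1, zeros]
    pr <- pr * w[match(b, zeros)] / sum(w)
    v <- v + 2^(b - 1)
  }
  pr
}

# exact emission log-likelihood by explicit enumeration of all L! paths
brute_exact_loglik <- function(net, strings) {
  L <- net$L
  perms <- all_perms(L)
  terms <- numeric(length(strings))
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    pr <- path_prob(net, ord)
    mids <- path_nodes(ord)[seq_len(L - 1)]
    for (i in seq_along(strings)) {
      terms[i] <- terms[i] + pr * sum(compatibility(mids, strings[i]))
    }
  }
  if (any(terms == 0)) -Inf else sum(log(terms))
}

# brute-force single-ordering search: max species accounted over all L!
# orderings, where a species is accounted when some prefix node (incl. the
# empty and full sets) is compatible with its string
brute_ordering_best <- function(strings) {
  L <- nchar(strings[1])
  perms <- all_perms(L)
  best <- 0L
  for (r in seq_len(nrow(perms))) {
    prefixes <- c(paste(rep("0", L), collapse = ""), path_nodes(perms[r, ]))
    acc <- vapply(strings, function(s) {
      any(compatibility(prefixes, s) == 1L)
    }, logical(1))
    best <- max(best, sum(acc))
  }
  best
}

# likelihood-weighted enumeration over deterministic orderings: the
# exhaustive oracle for the sampler's long-run concentration set at small L
ordering_enumeration_pi <- function(strings) {
  L <- nchar(strings[1])
  perms <- all_perms(L)
  pi <- matrix(0, L, L)
  total <- 0
  for (r in seq_len(nrow(perms))) {
    ord <- perms[r, ]
    mids <- path_nodes(ord)[seq_len(L - 1)]
    term <- prod(vapply(strings, function(s) {
      sum(compatibility(mids, s))
    }, numeric(1)))
    if (term > 0) {
      total <- total + term
      for (t in seq_len(L)) pi[ord[t], t] <- pi[ord[t], t] + term
    }
  }
  pi / total
}

# fast scaled-down MCMC settings for unit (non-acceptance) tests
tiny_config <- function(seed = 1, n_runs = 2, ...) {
  scaled_mcmc_config(burn_in = 200, samples = 1500, n_chain = 500,
                     thin = 50, n_runs = n_runs, seed = seed, ...)
}
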