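#' Hypercubic transition networks
#'
#' A `trait_network` carries strictly positive weights on the monotone edges
#' of the L-dimensional hypercube: ordered node pairs at Hamming distance 1
#' where the destination gains exactly one trait. Transition probabilities
#' are derived by row normalization, `P_ij = w_ij / sum_k w_ik` over the
#' outgoing edges of node `i`, so every non-terminal row is stochastic by
#' construction and reverse (trait-loss) moves have probability zero.
#'
#' `uniform_network()` builds the uninformative prior network in which every
#' available acquisition from a node is equally likely; `random_network()`
#' draws i.i.d. log-normal weights (the MCMC initialization);
#' `perturb_network()` applies the multiplicative log-normal proposal kernel
#' `w' = exp(log w + N(0, sigma^2))` independently to every edge weight.
#'
#' Weights are stored densely as a `2^L x L` matrix (`W[v + 1, b]` is the
#' weight of acquiring trait `b` from node `v`, valid only where bit
#' `b - 1` of `v` is unset); `L > 20` is refused.
#'
#' @param L number of traits (1--20)
#' @param net a `trait_network`
#' @param sigma kernel scale in log-weight space (> 0)
#' @return a `trait_network` object
#' @examples
#' net <- uniform_network(3)
#' transition_probabilities(net)
#' @export
uniform_network <- function(L) {
  check_L(L)
  new_trait_network(matrix(1, nrow = 2^L, ncol = L), L)
}

#' @rdname uniform_network
#' @export
random_network <- function(L) {
  check_L(L)
  new_trait_network(matrix(exp(rnorm(2^L * L)), nrow = 2^L, ncol = L), L)
}

#' @rdname uniform_network
#' @export
perturb_network <- function(net, sigma) {
  stopifnot(inherits(net, "trait_network"))
  if (!is.numeric(sigma) || sigma <= 0) abort("sigma must be > 0")
  new_trait_network(cpp_perturb(net$W, net$L, sigma), net$L)
}

check_L <- function(L, max_L = 20L) {
  if (!is.numeric(L) || length(L) != 1 || L < 1 || L != round(L)) {
    abort("L must be a single positive integer")
  }
  if (L > max_L) {
    abort(paste0("L = ", L, " exceeds the supported maximum (", max_L,
                 "): 2^L nodes would be intractable here"),
          class = "traitpaths_resource_error")
  }
  invisible(as.integer(L))
}

new_trait_network <- function(W, L) {
  L <- as.integer(L)
  stopifnot(is.matrix(W), nrow(W) == 2^L, ncol(W) == L)
  valid <- valid_edge_mask(L)
  w <- W[valid]
  if (any(!is.finite(w)) || any(w <= 0)) {
    abort("edge weights must be strictly positive and finite")
  }
  structure(list(L = L, W = W), class = "trait_network")
}

# logical 2^L x L mask of structural (monotone) edges
valid_edge_mask <- function(L) {
  v <- 0:(2^L - 1)
  vapply(seq_len(L) - 1L, function(b) bitwAnd(bitwShiftR(v, b), 1L) == 0L,
         logical(2^L))
}

#' @export
print.trait_network <- function(x, ...) {
  cat("<trait_network> L =", x$L, "|", 2^x$L, "nodes,",
      x$L * 2^(x$L - 1), "monotone edges\n")
  invisible(x)
}

#' Node labels and monotone successors
#'
#' Nodes are labelled by bitstrings of length `L`, written locus 1 first
#' (locus `k` is bit `k - 1` of the node index). `monotone_successors()`
#' lists the nodes reachable by flipping exactly one 0 to 1 -- the only
#' moves the model permits.
#'
#' @param node a bitstring such as `"010"`
#' @return character vector of successor bitstrings (empty for the all-ones
#'   node)
#' @examples
#' monotone_successors("000")
#' monotone_successors("111")
#' @export
monotone_successors <- function(node) {
  if (grepl("[^01]", node)) abort("node label must be a 0/1 bitstring")
  L <- nchar(node)
  bits <- strsplit(node, "")[[1]]
  zeros <- which(bits == "0")
  vapply(zeros, function(k) {
    b <- bits
    b[k] <- "1"
    paste(b, collapse = "")
  }, character(1))
}

node_to_string <- function(v, L) {
  vapply(v, function(vi) {
    paste(bitwAnd(bitwShiftR(vi, seq_len(L) - 1L), 1L), collapse = "")
  }, character(1))
}

string_to_node <- function(s) {
  vapply(strsplit(s, ""), function(bits) {
    sum(as.integer(bits) * 2^(seq_along(bits) - 1))
  }, numeric(1))
}

#' Edge table of a transition network
#'
#' Enumerates every monotone edge with its weight and row-normalized
#' transition probability. Intended for small `L` (refused above `L = 12`,
#' where the table would exceed 24k rows).
#'
#' @param net a `trait_network`
#' @return tibble with columns `from`, `to`, `locus`, `weight`, `prob`
#' @export
transition_probabilities <- function(net) {
  stopifnot(inherits(net, "trait_network"))
  L <- check_L(net$L, max_L = 12L)
  v <- 0:(2^L - 1)
  rows <- lapply(v, function(vi) {
    zeros <- which(bitwAnd(bitwShiftR(vi, seq_len(L) - 1L), 1L) == 0L)
    if (!length(zeros)) return(NULL)
    w <- net$W[vi + 1, zeros]
    tibble(
      from = node_to_string(vi, L),
      to = node_to_string(vi + 2^(zeros - 1), L),
      locus = zeros,
      weight = w,
      prob = w / sum(w)
    )
  })
  dplyr::bind_rows(rows)
}

#' Serialize a transition network
#'
#' Writes a JSON header line (prefixed `#`, recording `L` and an optional
#' seed) followed by a tab-separated monotone edge list
#' `from  to  weight` with full-precision weights; `read_network()` inverts
#' it exactly.
#'
#' @param net a `trait_network`
#' @param path file path
#' @param seed optional creation seed recorded in the header
#' @return `write_network()` returns `path` invisibly; `read_network()` a
#'   `trait_network`
#' @export
write_network <- function(net, path, seed = NULL) {
  stopifnot(inherits(net, "trait_network"))
  L <- net$L
  header <- jsonlite::toJSON(list(L = L, seed = seed), auto_unbox = TRUE,
                             null = "null")
  valid <- valid_edge_mask(L)
  idx <- which(valid, arr.ind = TRUE)
  from <- idx[, 1] - 1L
  locus <- idx[, 2]
  lines <- c(
    paste0("# ", header),
    "from\tto\tweight",
    sprintf("%s\t%s\t%s",
            node_to_string(from, L),
            node_to_string(from + 2^(locus - 1), L),
            formatC(net$W[valid], format = "g", digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# ")) abort("missing JSON header line")
  header <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
  L <- check_L(header$L)
  d <- read.delim(text = lines[-1], colClasses = c("character", "character",
                                                   "numeric"))
  W <- matrix(NA_real_, nrow = 2^L, ncol = L)
  from <- string_to_node(d$from)
  to <- string_to_node(d$to)
  locus <- as.integer(round(log2(to - from))) + 1L
  W[cbind(from + 1, locus)] <- d$weight
  W[!valid_edge_mask(L)] <- 1  # structurally absent; placeholder
  if (anyNA(W)) abort("edge list does not cover every monotone edge")
  net <- new_trait_network(W, L)
  attr(net, "seed") <- header$seed
  net
}
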