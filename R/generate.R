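#' Generate artificial validation datasets
#'
#' Positive-control datasets with known ground-truth dynamics, used to
#' verify the inferential machinery.
#'
#' `generate_diagonal()` fixes a single deterministic acquisition ordering
#' (the identity by default, so the ground-truth summary matrix is the
#' identity, `pi[i, n] = delta_{i,n}`): each artificial species is the
#' prefix of that ordering at a step drawn uniformly from the intermediate
#' steps `1..L-1`. `generate_block_linked()` emulates pleiotropy: traits
#' are acquired in blocks of `block_size` simultaneously, so species are
#' sampled only at block boundaries and the ground truth assigns each
#' trait uniform acquisition probability across its block's steps.
#'
#' Defaults (40 species, uniform step sampling) are this package's choice
#' of realistic study conditions; both generators are deterministic under
#' a fixed seed.
#'
#' @param L number of traits
#' @param n_species number of artificial species
#' @param ordering the deterministic acquisition ordering (a permutation
#'   of `1..L`)
#' @param block_size traits acquired per step block; must divide `L`
#' @param occlusion fraction of entries replaced by the missing code `2`
#'   (see [occlude()])
#' @param seed integer seed
#' @return a tibble (`species`, `phenotype`) with attributes
#'   `ground_truth_pi` (the `L x L` ground-truth summary matrix) and
#'   `ordering`/`block_size`
#' @examples
#' generate_diagonal(L = 4, n_species = 3, seed = 1)
#' @export
generate_diagonal <- function(L = 16, n_species = 40,
                              ordering = seq_len(L), occlusion = 0,
                              seed = NULL) {
  check_L(L)
  if (n_species < 1) abort("n_species must be >= 1")
  stopifnot(length(ordering) == L, all(sort(ordering) == seq_len(L)))
  if (!is.null(seed)) set.seed(seed)
  steps <- if (L > 1) sample(seq_len(L - 1), n_species, replace = TRUE)
    else rep(0L, n_species)
  mat <- t(vapply(steps, function(t) {
    p <- integer(L)
    p[ordering[seq_len(t)]] <- 1L
    p
  }, integer(L)))
  rownames(mat) <- sprintf("art%02d", seq_len(n_species))
  gt <- diag(L)[order(ordering), , drop = FALSE]
  dimnames(gt) <- list(trait = paste0("trait", seq_len(L)),
                       step = paste0("step", seq_len(L)))
  out <- matrix_to_phenotypes(mat)
  if (occlusion > 0) out <- occlude(out, occlusion)
  attr(out, "ground_truth_pi") <- gt
  attr(out, "ordering") <- ordering
  out
}

#' @rdname generate_diagonal
#' @export
generate_block_linked <- function(L = 16, block_size = 4, n_species = 40,
                                  occlusion = 0, seed = NULL) {
  check_L(L)
  if (L %% block_size != 0) {
    abort("block_size must divide L", class = "traitpaths_config_error")
  }
  if (n_species < 1) abort("n_species must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  nb <- L %/% block_size
  # intermediate block boundaries only (1 .. nb-1 completed blocks)
  if (nb < 2) abort("need at least two blocks for intermediate boundaries")
  bnd <- sample(seq_len(nb - 1), n_species, replace = TRUE)
  mat <- t(vapply(bnd, function(k) {
    p <- integer(L)
    p[seq_len(k * block_size)] <- 1L
    p
  }, integer(L)))
  rownames(mat) <- sprintf("art%02d", seq_len(n_species))
  gt <- matrix(0, L, L)
  for (i in seq_len(L)) {
    q <- (i - 1) %/% block_size
    gt[i, (q * block_size + 1):((q + 1) * block_size)] <- 1 / block_size
  }
  dimnames(gt) <- list(trait = paste0("trait", seq_len(L)),
                       step = paste0("step", seq_len(L)))
  out <- matrix_to_phenotypes(mat)
  if (occlusion > 0) out <- occlude(out, occlusion)
  attr(out, "ground_truth_pi") <- gt
  attr(out, "block_size") <- block_size
  out
}

#' Occlude entries of a phenotype dataset
#'
#' Replaces uniformly chosen observed (non-2) entries with the missing
#' code `2`. Exactly `round(fraction * total entries)` entries are
#' occluded (sampled without replacement among the observed ones),
#' emulating the missing-data burden of real trait compilations.
#'
#' @param data phenotype dataset (strings, data frame, or 0/1/2 matrix)
#' @param fraction fraction of the table to occlude, in `[0, 1)`
#' @param seed optional integer seed
#' @return same shape as the input (tibble of strings), attributes
#'   preserved
#' @examples
#' occlude(generate_diagonal(L = 4, n_species = 5, seed = 1), 0.5, seed = 2)
#' @export
occlude <- function(data, fraction, seed = NULL) {
  if (fraction < 0 || fraction >= 1) abort("fraction must be in [0, 1)")
  at <- attributes(data)
  mat <- as_phenotype_matrix(data)
  if (!is.null(seed)) set.seed(seed)
  k <- round(fraction * length(mat))
  if (k > 0) {
    obs <- which(mat != 2L)
    if (k > length(obs)) {
      abort("occlusion fraction exceeds the number of observed entries")
    }
    mat[sample(obs, k)] <- 2L
  }
  out <- matrix_to_phenotypes(mat)
  keep <- setdiff(names(at), c("names", "row.names", "class", "dim",
                               "dimnames"))
  for (nm in keep) {
    attr(out, nm) <- at[[nm]]
  }
  out
}

#' Load the packaged curated-study fixture
#'
#' Returns the transcription of the study's species table (family,
#' species, photosynthetic type, literature reference key, lineage) plus a
#' 16-trait binary phenotype matrix for the intermediate species. The
#' trait matrix shipped with this package is a synthetic reconstruction
#' (the original supplementary binary scoring is not redistributed here):
#' it is generated deterministically with the package's own machinery,
#' with a realistic ~50% missing-data burden, and is clearly labelled as
#' such in its filename and provenance note. Results computed from it
#' validate the machinery, not the original study's data values.
#'
#' @return a list: `metadata` (tibble of all species), `phenotypes`
#'   (tibble `species`, `type`, `phenotype` for the C3-C4 intermediates),
#'   `traits` (the 16 trait labels), `provenance` (character note)
#' @export
load_study_fixture <- function() {
  meta_path <- system.file("extdata", "c4_species_metadata.tsv",
                           package = "traitpaths")
  trait_path <- system.file("extdata", "c4_trait_matrix_synthetic.tsv",
                            package = "traitpaths")
  if (meta_path == "" || trait_path == "") {
    abort("packaged fixture files are missing",
          class = "traitpaths_packaging_error")
  }
  metadata <- as_tibble(read.delim(meta_path, colClasses = "character",
                                   check.names = FALSE))
  tr <- read.delim(trait_path, colClasses = "character", check.names = FALSE)
  traits <- setdiff(names(tr), c("species", "type"))
  mat <- as.matrix(tr[traits])
  storage.mode(mat) <- "integer"
  rownames(mat) <- tr$species
  phen <- matrix_to_phenotypes(mat) |>
    dplyr::mutate(type = tr$type, .after = "species")
  list(
    metadata = metadata,
    phenotypes = phen,
    traits = traits,
    provenance = paste(
      "Species metadata transcribed from the study's species table;",
      "trait matrix is a SYNTHETIC reconstruction generated in-package",
      "(see inst/extdata/make_synthetic_fixture.R), not the original",
      "supplementary binary scoring."
    )
  )
}
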