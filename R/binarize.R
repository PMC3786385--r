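#' Binarize quantitative trait measurements
#'
#' Partition a vector of cross-comparable quantitative measurements into
#' presence (1) and absence (0) of the derived-state trait.
#'
#' `em_binarize()` fits a one-dimensional two-component Gaussian mixture by
#' expectation-maximization (unequal variances and mixing proportions
#' allowed) and assigns each value to the component with the larger
#' posterior responsibility; a responsibility of exactly 0.5 falls to the
#' ancestral-direction (absence) component. `hclust_binarize()` cuts a
#' complete-linkage agglomerative tree (Euclidean distance) into exactly
#' two clusters; it finds common-variance clusters and so complements the
#' variable-variance EM view. In both, the cluster whose mean lies in the
#' derived-state direction maps to 1: with `direction = "larger"` the
#' high-mean cluster is presence, with `"smaller"` (e.g. vein spacing,
#' which decreases toward the derived state) the low-mean cluster is.
#'
#' @param values numeric vector (NA allowed; NA values get NA scores)
#' @param direction `"larger"` if larger values indicate the derived (C4)
#'   state, `"smaller"` otherwise
#' @return a list of class `trait_binarization`: `scores` (integer 0/1,
#'   NA where the input was NA) and `report` (method, component means,
#'   variances and mixing weights)
#' @examples
#' em_binarize(c(0.9, 1.0, 1.1, 9.8, 10.0, 10.2))$scores
#' hclust_binarize(c(1, 2, 100))$scores
#' @importFrom mclust Mclust mclustBIC
#' @export
em_binarize <- function(values, direction = c("larger", "smaller")) {
  direction <- match.arg(direction)
  check_binarize_input(values)
  obs <- values[!is.na(values)]
  fit <- mclust::Mclust(obs, G = 2, modelNames = c("V", "E"),
                        verbose = FALSE)
  if (is.null(fit)) abort("mixture fit failed")
  means <- as.numeric(fit$parameters$mean)
  presence_comp <- if (direction == "larger") which.max(means) else
    which.min(means)
  # responsibility exactly 0.5 goes to the absence component
  z_presence <- fit$z[, presence_comp]
  scores <- rep(NA_integer_, length(values))
  scores[!is.na(values)] <- as.integer(z_presence > 0.5)
  vars <- fit$parameters$variance$sigmasq
  if (length(vars) == 1) vars <- rep(vars, 2)
  structure(list(
    scores = scores,
    report = list(method = "EM",
                  model = fit$modelName,
                  means = means,
                  variances = as.numeric(vars),
                  weights = as.numeric(fit$parameters$pro),
                  presence_component = presence_comp,
                  direction = direction)
  ), class = "trait_binarization")
}

#' @rdname em_binarize
#' @export
hclust_binarize <- function(values, direction = c("larger", "smaller")) {
  direction <- match.arg(direction)
  check_binarize_input(values)
  obs <- values[!is.na(values)]
  cl <- cutree(hclust(dist(obs), method = "complete"), k = 2)
  means <- tapply(obs, cl, mean)
  presence_cl <- as.integer(names(means)[
    if (direction == "larger") which.max(means) else which.min(means)])
  scores <- rep(NA_integer_, length(values))
  scores[!is.na(values)] <- as.integer(cl == presence_cl)
  structure(list(
    scores = scores,
    report = list(method = "hierarchical",
                  means = as.numeric(means),
                  presence_cluster = presence_cl,
                  direction = direction)
  ), class = "trait_binarization")
}

check_binarize_input <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2) {
    abort("need at least 2 non-missing values",
          class = "traitpaths_insufficient_data")
  }
  if (length(unique(obs)) < 2) {
    abort("all values identical: cannot form two clusters",
          class = "traitpaths_degenerate_cluster")
  }
  invisible(values)
}

#' Score a measurement against study-specific controls
#'
#' For measurements not cross-comparable between studies, a value is
#' scored 1 if closer to the C4 control used in the original study and 0
#' if closer to the C3 control. An exactly equidistant value scores 0 by
#' default -- the conservative choice of not over-calling derived traits
#' -- configurable via `tie`. Quantified immunoblot band intensities route
#' through this rule too.
#'
#' @param value numeric measurement (vectorized)
#' @param c3_control,c4_control the control values; must be finite and
#'   distinct
#' @param tie score assigned when exactly equidistant (`0` or `1`)
#' @return integer 0/1 vector
#' @examples
#' control_relative_score(8, c3_control = 1, c4_control = 10)
#' control_relative_score(5.5, 1, 10) # equidistant: 0
#' @export
control_relative_score <- function(value, c3_control, c4_control, tie = 0L) {
  if (!is.finite(c3_control) || !is.finite(c4_control) ||
      c3_control == c4_control) {
    abort("controls must be finite and distinct",
          class = "traitpaths_ambiguous_controls")
  }
  d4 <- abs(value - c4_control)
  d3 <- abs(value - c3_control)
  out <- ifelse(d4 < d3, 1L, ifelse(d4 > d3, 0L, as.integer(tie)))
  out[is.na(value)] <- NA_integer_
  out
}

#' Score immunolocalisation patterns
#'
#' Cell-specificity of an enzyme counts as a derived trait only when the
#' enzyme is completely absent from one cell type (mesophyll or bundle
#' sheath); presence in both scores 0.
#'
#' @param pattern character vector over `{"absent_in_M", "absent_in_BS",
#'   "present_in_both"}` (NA allowed)
#' @return integer 0/1 vector
#' @examples
#' immunolocalisation_score(c("absent_in_M", "present_in_both"))
#' @export
immunolocalisation_score <- function(pattern) {
  ok <- c("absent_in_M", "absent_in_BS", "present_in_both")
  bad <- !is.na(pattern) & !pattern %in% ok
  if (any(bad)) {
    abort(paste0("unknown pattern: ", paste(unique(pattern[bad]),
                                            collapse = ", ")))
  }
  ifelse(is.na(pattern), NA_integer_,
         as.integer(pattern %in% c("absent_in_M", "absent_in_BS")))
}

#' Assemble phenotype strings from a species-by-trait table
#'
#' Converts a heterogeneous table of trait measurements into phenotype
#' strings over `{0,1,2}`. Each trait column is scored by its configured
#' route: `"em"` or `"hclust"` cluster the cross-comparable quantitative
#' values (over all species in the table), `"control"` scores values
#' against per-trait study controls, `"immuno"` maps immunolocalisation
#' categories, and `"binary"` passes through already-binary 0/1 columns.
#' Missing measurements become `2`. Intermediate (`C3-C4`) species keep
#' their per-trait scores; `C3` species map to the all-zeros reference
#' string and `C4` species to all-ones (these anchor the landscape's
#' endpoints and are excluded from the likelihood). A species with every
#' trait missing is retained as an all-2 string with a warning, since it
#' constrains nothing.
#'
#' @param data a data frame with columns `species`, `type` (each in
#'   `{"C3", "C3-C4", "C4"}`) and one column per trait
#' @param traits character vector of trait column names (default: all
#'   columns except `species` and `type`)
#' @param method single string or named per-trait vector over `{"em",
#'   "hclust", "control", "immuno", "binary"}`
#' @param direction single string or named per-trait vector over
#'   `{"larger", "smaller"}` for the clustering routes
#' @param controls named list `trait -> c(c3 = ..., c4 = ...)` for traits
#'   scored `"control"`
#' @return a tibble (`species`, `type`, `phenotype`) with attribute
#'   `report`: a per-trait list of scoring method and parameters, including
#'   EM-vs-hierarchical assignment disagreement for clustered traits
#' @export
assemble_phenotype_strings <- function(data, traits = NULL, method = "em",
                                       direction = "larger",
                                       controls = list()) {
  stopifnot(all(c("species", "type") %in% names(data)))
  if (!all(data$type %in% c("C3", "C3-C4", "C4"))) {
    abort("type must be one of C3, C3-C4, C4")
  }
  traits <- traits %||% setdiff(names(data), c("species", "type"))
  L <- length(traits)
  if (L < 1) abort("no trait columns found")
  method_of <- function(tr) {
    if (length(method) == 1 && is.null(names(method))) method else
      method[[tr]] %||% "em"
  }
  dir_of <- function(tr) {
    if (length(direction) == 1 && is.null(names(direction))) direction else
      direction[[tr]] %||% "larger"
  }
  scores <- matrix(NA_integer_, nrow = nrow(data), ncol = L,
                   dimnames = list(data$species, traits))
  report <- list()
  for (tr in traits) {
    m <- method_of(tr)
    col <- data[[tr]]
    entry <- list(trait = tr, method = m)
    if (m %in% c("em", "hclust")) {
      vals <- as.numeric(col)
      fit <- if (m == "em") em_binarize(vals, dir_of(tr)) else
        hclust_binarize(vals, dir_of(tr))
      scores[, tr] <- fit$scores
      entry$params <- fit$report
      # cross-method disagreement, recorded not asserted
      alt <- tryCatch(
        if (m == "em") hclust_binarize(vals, dir_of(tr))$scores else
          em_binarize(vals, dir_of(tr))$scores,
        error = function(e) NULL
      )
      if (!is.null(alt)) {
        entry$disagreement <- sum(fit$scores != alt, na.rm = TRUE)
      }
    } else if (m == "control") {
      ctl <- controls[[tr]]
      if (is.null(ctl)) abort(paste0("no controls given for trait ", tr))
      scores[, tr] <- control_relative_score(as.numeric(col),
                                             ctl[["c3"]], ctl[["c4"]])
      entry$params <- as.list(ctl)
    } else if (m == "immuno") {
      scores[, tr] <- immunolocalisation_score(as.character(col))
    } else if (m == "binary") {
      v <- as.integer(col)
      if (!all(v %in% c(0L, 1L) | is.na(v))) {
        abort(paste0("trait ", tr, " is not binary"))
      }
      scores[, tr] <- v
    } else {
      abort(paste0("unknown method '", m, "' for trait ", tr))
    }
    report[[tr]] <- entry
  }
  scores[is.na(scores)] <- 2L
  scores[data$type == "C3", ] <- 0L
  scores[data$type == "C4", ] <- 1L
  all_missing <- rowSums(scores == 2L) == L & data$type == "C3-C4"
  if (any(all_missing)) {
    warn(paste0("species with all traits missing retained as all-2: ",
                paste(data$species[all_missing], collapse = ", ")))
  }
  out <- tibble(
    species = data$species,
    type = data$type,
    phenotype = unname(apply(scores, 1, paste, collapse = ""))
  )
  attr(out, "report") <- report
  out
}

#' @rdname assemble_phenotype_strings
#' @param x output of `assemble_phenotype_strings()`
#' @param path optional path to also write the report as JSON
#' @export
binarization_report <- function(x, path = NULL) {
  rep <- attr(x, "report")
  if (is.null(rep)) abort("no binarization report attached")
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  rep
}
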