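#' Phenotype strings
#'
#' A phenotype string encodes one species as a length-`L` sequence over
#' `{0, 1, 2}`: `0` = trait absent, `1` = trait present, `2` = missing data.
#' Locus `k` of the string corresponds to bit `k - 1` of the hypercube node
#' index (locus 1 is the least significant bit), so the string is read
#' left-to-right as locus 1 to locus L.
#'
#' `phenotype_strings()` validates a character vector (or the `phenotype`
#' column of a data frame) and returns a tibble with columns `species` and
#' `phenotype`. `as_phenotype_matrix()` converts phenotype data to an
#' integer matrix (species x locus, values 0/1/2), the internal canonical
#' form.
#'
#' @param x a character vector of strings over `{0,1,2}`, a data frame with
#'   a `phenotype` column (and optionally `species`), or an integer matrix
#'   with values in `{0,1,2}`
#' @param species optional species labels (recycled names when `x` is a
#'   bare character vector)
#' @return `phenotype_strings()`: a tibble with columns `species`,
#'   `phenotype`. `as_phenotype_matrix()`: an integer matrix with rownames.
#' @examples
#' phenotype_strings(c("0102", "1100"))
#' as_phenotype_matrix(c(a = "012", b = "110"))
#' @export
phenotype_strings <- function(x, species = NULL) {
  if (is.data.frame(x)) {
    if (!"phenotype" %in% names(x)) {
      abort("data frame input must have a `phenotype` column")
    }
    species <- species %||% x$species %||% paste0("sp", seq_len(nrow(x)))
    x <- x$phenotype
  }
  species <- species %||% names(x)
  x <- as.character(x)
  if (length(x) == 0) {
    return(tibble(species = character(), phenotype = character()))
  }
  bad <- grepl("[^012]", x)
  if (any(bad)) {
    abort(paste0("phenotype strings may contain only 0/1/2; offending: ",
                 paste(head(x[bad], 3), collapse = ", ")))
  }
  if (length(unique(nchar(x))) > 1) {
    abort("all phenotype strings must have equal length")
  }
  species <- species %||% names(x) %||% paste0("sp", seq_along(x))
  tibble(species = as.character(species), phenotype = unname(x))
}

#' @rdname phenotype_strings
#' @export
as_phenotype_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    if (length(x) && !all(x %in% 0:2)) abort("matrix entries must be 0/1/2")
    if (is.null(rownames(x))) rownames(x) <- paste0("sp", seq_len(nrow(x)))
    return(x)
  }
  ph <- phenotype_strings(x)
  if (nrow(ph) == 0) {
    return(matrix(integer(), nrow = 0, ncol = 0))
  }
  L <- nchar(ph$phenotype[1])
  m <- matrix(
    as.integer(unlist(strsplit(ph$phenotype, ""), use.names = FALSE)),
    nrow = nrow(ph), ncol = L, byrow = TRUE
  )
  rownames(m) <- ph$species
  m
}

# integer bitmasks (m1: observed-present loci, m0: observed-absent loci)
phenotype_masks <- function(mat) {
  if (nrow(mat) == 0) {
    return(list(m1 = integer(), m0 = integer()))
  }
  L <- ncol(mat)
  pw <- as.integer(2^(seq_len(L) - 1))
  list(
    m1 = as.integer((mat == 1L) %*% pw),
    m0 = as.integer((mat == 0L) %*% pw)
  )
}

# matrix back to strings
matrix_to_phenotypes <- function(mat) {
  tibble(
    species = rownames(mat) %||% paste0("sp", seq_len(nrow(mat))),
    phenotype = unname(apply(mat, 1, paste, collapse = ""))
  )
}

#' Compatibility of a signal with an observation
#'
#' Two strings over `{0,1,2}` are compatible when every locus either agrees
#' or is wildcarded by a `2` on either side; the compatibility is the
#' product of the per-locus indicator, so it is 1 iff no locus conflicts.
#' This is the emission rule connecting simulated trajectory nodes to
#' observed intermediate phenotypes.
#'
#' @param s,t strings (or vectors of strings, recycled) over `{0,1,2}` of
#'   equal length
#' @return integer 0/1 vector
#' @examples
#' compatibility("101", "101") # 1
#' compatibility("001", "201") # 1, wildcard
#' compatibility("100", "001") # 0
#' @export
compatibility <- function(s, t) {
  n <- max(length(s), length(t))
  s <- rep_len(as.character(s), n)
  t <- rep_len(as.character(t), n)
  if (any(nchar(s) != nchar(t))) abort("strings must have equal length")
  if (any(grepl("[^012]", c(s, t)))) abort("strings must be over {0,1,2}")
  vapply(seq_len(n), function(i) {
    si <- strsplit(s[i], "")[[1]]
    ti <- strsplit(t[i], "")[[1]]
    as.integer(all(si == ti | si == "2" | ti == "2"))
  }, integer(1))
}

#' Read and write phenotype-string tables
#'
#' Tab-separated files with columns `species` and `phenotype` (strings over
#' `{0,1,2}`); `type` and further columns are carried through if present.
#'
#' @param path file path
#' @param data a data frame with at least `species` and `phenotype`
#' @return `read_phenotypes()` returns a tibble; `write_phenotypes()`
#'   returns `path` invisibly.
#' @export
read_phenotypes <- function(path) {
  d <- as_tibble(read.delim(path, colClasses = "character",
                            check.names = FALSE))
  phenotype_strings(d) |>
    dplyr::bind_cols(d[setdiff(names(d), c("species", "phenotype"))])
}

#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(data, path) {
  stopifnot(all(c("species", "phenotype") %in% names(data)))
  write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
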