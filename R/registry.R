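#' Natural isotope abundances
#'
#' Default natural abundance table for the elements occurring in free amino
#' acids (C, H, N, O, S). For each element the entry is a numeric vector of
#' probabilities indexed by integer nominal mass shift (position 1 = shift 0,
#' i.e. the light isotope). IUPAC 2021 representative values; editable by
#' passing a modified copy to [build_correction_matrix()].
#'
#' @return Named list of per-element mass-shift probability vectors, each
#'   summing to 1.
#' @export
#' @examples
#' natural_abundance()$N
natural_abundance <- function() {
  list(
    C = c(1 - 0.0107, 0.0107),
    H = c(1 - 0.000115, 0.000115),
    N = c(1 - 0.00364, 0.00364),
    O = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    # 32S, 33S (+1), 34S (+2), no +3, 36S (+4)
    S = c(1 - 0.0075 - 0.0425 - 0.0001, 0.0075, 0.0425, 0, 0.0001)
  )
}

#' Parse an elemental formula in Hill notation
#'
#' @param formula Character scalar such as `"C5H9NO2"`. Only C, H, N, O and S
#'   are accepted (the elements of proteinogenic amino acids and SMCSO).
#' @return Named integer vector of element counts over C, H, N, O, S.
#' @export
#' @examples
#' parse_formula("C2H5NO2") # glycine
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  tokens <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  parts <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  if (length(parts) == 0L || sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula: ", formula, call. = FALSE)
  }
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L, S = 0L)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nchar(n) == 0L) 1L else as.integer(n)
    if (!el %in% names(counts)) {
      stop("unknown element '", el, "' in formula ", formula, call. = FALSE)
    }
    counts[el] <- counts[el] + n
  }
  counts
}

#' Build a metabolite specification
#'
#' @param name Metabolite name (unique within a registry).
#' @param formula Elemental formula string (Hill notation, elements C,H,N,O,S).
#' @param n_tracer Number of nitrogen atoms carrying tracer; defaults to the
#'   formula's N count and must equal it.
#' @param resolution_resolved Whether non-tracer isotopic species are mass
#'   resolved from the tracer isotopologues at the instrument's resolving
#'   power (TRUE for small amino acids on a high-resolution Orbitrap).
#' @return A list of class `metabolite_spec`.
#' @export
#' @examples
#' metabolite_spec("Pro", "C5H9NO2")
metabolite_spec <- function(name, formula, n_tracer = NULL,
                            resolution_resolved = TRUE) {
  counts <- parse_formula(formula)
  if (is.null(n_tracer)) n_tracer <- unname(counts[["N"]])
  n_tracer <- as.integer(n_tracer)
  if (n_tracer != counts[["N"]]) {
    stop("n_tracer (", n_tracer, ") must equal the formula's N count (",
         counts[["N"]], ") for ", name, call. = FALSE)
  }
  if (n_tracer < 1L) {
    stop("metabolite ", name, " has no nitrogen atom to trace", call. = FALSE)
  }
  structure(
    list(name = name, formula = formula, counts = counts,
         n_tracer = n_tracer,
         resolution_resolved = isTRUE(resolution_resolved)),
    class = "metabolite_spec"
  )
}

#' @export
print.metabolite_spec <- function(x, ...) {
  cat("<metabolite_spec> ", x$name, " (", x$formula, "), ",
      x$n_tracer, " N tracer position(s)\n", sep = "")
  invisible(x)
}

#' Default amino-acid registry
#'
#' Registry of the free amino acids measured in the leaf-disc labeling design:
#' the glycine label source, the subsystem precursors (Glu, Asp), the flux-
#' modeled products (Pro, Val, Thr) and the other abundant pools used by the
#' fingerprint statistics (Ser, Ala, Asn, Gln, SMCSO) plus a minor amino acid
#' (Trp) that exercises the abundance filter.
#'
#' @return Tibble with columns `name`, `formula`, `n_tracer`.
#' @export
#' @examples
#' default_registry()
default_registry <- function() {
  tibble::tribble(
    ~name,    ~formula,      ~n_tracer,
    "Gly",    "C2H5NO2",     1L,
    "Ala",    "C3H7NO2",     1L,
    "Ser",    "C3H7NO3",     1L,
    "Pro",    "C5H9NO2",     1L,
    "Val",    "C5H11NO2",    1L,
    "Thr",    "C4H9NO3",     1L,
    "Glu",    "C5H9NO4",     1L,
    "Asp",    "C4H7NO4",     1L,
    "Asn",    "C4H8N2O3",    2L,
    "Gln",    "C5H10N2O3",   2L,
    "SMCSO",  "C4H9NO3S",    1L,
    "Trp",    "C11H12N2O2",  2L
  )
}

#' Read a metabolite registry CSV
#'
#' Expects columns `name`, `formula` (Hill notation) and optionally
#' `n_tracer`; every row is validated through [metabolite_spec()].
#'
#' @param path Path to a CSV file.
#' @return Tibble with columns `name`, `formula`, `n_tracer`.
#' @export
read_registry <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("name", "formula") %in% names(df))) {
    stop("registry must have columns 'name' and 'formula'", call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("duplicate metabolite names in registry", call. = FALSE)
  }
  if (!"n_tracer" %in% names(df)) {
    df$n_tracer <- vapply(df$formula,
                          function(f) unname(parse_formula(f)[["N"]]),
                          integer(1))
  }
  purrr::pwalk(df[c("name", "formula", "n_tracer")],
               function(name, formula, n_tracer) {
                 metabolite_spec(name, formula, n_tracer)
               })
  tibble::as_tibble(df[c("name", "formula", "n_tracer")])
}

# registry tibble -> named list of metabolite_spec
registry_specs <- function(registry) {
  specs <- purrr::pmap(registry[c("name", "formula", "n_tracer")],
                       metabolite_spec)
  stats::setNames(specs, registry$name)
}
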