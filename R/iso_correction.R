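# Convolve two mass-shift probability vectors (index 1 = shift 0).
convolve_shift <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    if (a[i] != 0) {
      idx <- i + seq_along(b) - 1L
      out[idx] <- out[idx] + a[i] * b
    }
  }
  out
}

# n-fold self-convolution of a per-atom shift distribution.
convolve_n <- function(dist, n) {
  out <- 1
  for (i in seq_len(n)) out <- convolve_shift(out, dist)
  out
}

#' Build an isotope-correction matrix for a tracer metabolite
#'
#' Column `j` (0-based) is the predicted measured mass-shift distribution of a
#' molecule carrying exactly `j` tracer nitrogen atoms: a binomial purity
#' distribution over the `j` labeled positions (each heavy with probability
#' `purity`), convolved with a binomial natural-abundance distribution over the
#' `n_tracer - j` unlabeled nitrogen positions, and — in `"full"` mode only —
#' with the natural mass-shift distributions of C, H, O and S. Rows beyond the
#' tracer count are truncated, so `"full"` columns sum to slightly less than 1
#' while `"tracer_only"` columns sum to exactly 1.
#'
#' `"tracer_only"` is the default for small amino acids measured at high
#' resolving power, where isotopic species of non-tracer elements are mass
#' resolved from the 15N isotopologues and do not contaminate them.
#'
#' @param spec A [metabolite_spec()].
#' @param purity Tracer isotopic purity in (0, 1]; default 0.98.
#' @param mode `"tracer_only"` or `"full"`.
#' @param abundances Per-element natural abundance table, as
#'   [natural_abundance()].
#' @return A list of class `correction_matrix` with elements `metabolite`,
#'   `entries` (square matrix of size `n_tracer + 1`), `purity`, `mode`.
#' @export
#' @examples
#' m <- build_correction_matrix(metabolite_spec("Pro", "C5H9NO2"))
#' colSums(m$entries)
build_correction_matrix <- function(spec, purity = 0.98,
                                    mode = c("tracer_only", "full"),
                                    abundances = natural_abundance()) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "metabolite_spec"))
  if (!is.numeric(purity) || length(purity) != 1L || purity <= 0 || purity > 1) {
    stop("purity must be in (0, 1]; purity = 0 gives a degenerate matrix",
         call. = FALSE)
  }
  missing_el <- setdiff(names(spec$counts)[spec$counts > 0], names(abundances))
  if (length(missing_el)) {
    stop("no abundance table for element(s): ",
         paste(missing_el, collapse = ", "), call. = FALSE)
  }
  for (el in names(abundances)) {
    p <- abundances[[el]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("abundances for ", el, " must be nonnegative and sum to 1",
           call. = FALSE)
    }
  }
  n <- spec$n_tracer
  nat_n <- abundances$N[2] # natural heavy fraction of the tracer element
  # non-tracer element envelope, shared by every column in full mode
  env <- 1
  if (mode == "full") {
    for (el in c("C", "H", "O", "S")) {
      k <- spec$counts[[el]]
      if (k > 0) env <- convolve_shift(env, convolve_n(abundances[[el]], k))
    }
  }
  entries <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    lab <- stats::dbinom(0:j, j, purity)            # heavy among labeled
    unl <- stats::dbinom(0:(n - j), n - j, nat_n)   # natural 15N, unlabeled
    col <- convolve_shift(lab, unl)
    if (mode == "full") col <- convolve_shift(col, env)
    entries[, j + 1L] <- col[seq_len(n + 1L)]       # truncate beyond M+n
  }
  structure(
    list(metabolite = spec$name, entries = entries, purity = purity,
         mode = mode),
    class = "correction_matrix"
  )
}

#' @export
print.correction_matrix <- function(x, ...) {
  cat("<correction_matrix> ", x$metabolite, ", mode = ", x$mode,
      ", purity = ", x$purity, "\n", sep = "")
  print(round(x$entries, 6))
  invisible(x)
}

# Lawson-Hanson non-negative least squares: min ||Ax - b||_2 s.t. x >= 0.
# Small dense problems only (correction matrices are (n_tracer+1)-square).
nnls_solve <- function(A, b, tol = NULL) {
  m <- ncol(A)
  if (is.null(tol)) tol <- 10 * .Machine$double.eps * max(abs(A)) * m
  passive <- logical(m)
  x <- numeric(m)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  max_iter <- 30L * m
  while (any(!passive) && max(w[!passive]) > tol) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("non-negative least squares failed to converge", call. = FALSE)
    }
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(m)
      Ap <- A[, passive, drop = FALSE]
      s[passive] <- as.numeric(qr.solve(Ap, b))
      if (all(s[passive] > tol)) break
      neg <- passive & (s <= tol)
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & (x > tol)
      x[!passive] <- 0
    }
    x <- s
    w <- crossprod(A, b - A %*% x)
  }
  as.numeric(x)
}

#' Correct one raw isotopologue vector
#'
#' Removes natural-abundance and tracer-impurity contributions from a raw
#' mass-fraction vector by non-negative least squares against the correction
#' matrix, then renormalizes to sum 1.
#'
#' @param raw Numeric vector of raw mass fractions, length `n_tracer + 1`.
#' @param matrix A [build_correction_matrix()] result.
#' @return Numeric vector of corrected isotopologue fractions (nonnegative,
#'   summing to 1).
#' @export
#' @examples
#' m <- build_correction_matrix(metabolite_spec("Gly", "C2H5NO2"))
#' raw <- as.numeric(m$entries %*% c(0.3, 0.7))
#' correct_vector(raw, m)
correct_vector <- function(raw, matrix) {
  stopifnot(inherits(matrix, "correction_matrix"))
  if (length(raw) != ncol(matrix$entries)) {
    stop("raw vector length (", length(raw), ") does not match matrix size (",
         ncol(matrix$entries), ") for ", matrix$metabolite, call. = FALSE)
  }
  raw <- pmax(raw, 0) # clip small negative noise floors
  if (sum(raw) <= 0) {
    stop("empty measurement: all-zero raw vector for ", matrix$metabolite,
         call. = FALSE)
  }
  x <- nnls_solve(matrix$entries, raw)
  s <- sum(x)
  if (s <= 0) {
    stop("correction produced an all-zero distribution for ",
         matrix$metabolite, call. = FALSE)
  }
  x / s
}

#' Mean fractional tracer enrichment of a corrected distribution
#'
#' @param values Corrected isotopologue fractions `M+0 ... M+n` summing to 1.
#' @return `sum(i * values[i]) / n_tracer`, in `[0, 1]`.
#' @export
#' @examples
#' mean_enrichment(c(0.2, 0.8))
#' mean_enrichment(c(0.25, 0.5, 0.25))
mean_enrichment <- function(values) {
  if (any(values < -1e-9) || abs(sum(values) - 1) > 1e-6) {
    stop("mean_enrichment expects a corrected distribution summing to 1 ",
         "(got sum = ", format(sum(values)), ")", call. = FALSE)
  }
  n <- length(values) - 1L
  if (n == 0L) stop("distribution has no tracer position", call. = FALSE)
  sum((0:n) * values) / n
}

#' Correct a long table of raw isotopologue mass fractions
#'
#' Data-frame-first wrapper around [build_correction_matrix()] and
#' [correct_vector()]: corrects every (sample, metabolite) raw vector in a
#' long table and appends the mean fractional enrichment.
#'
#' @param data Long tibble with columns `sample_id`, `leaf_rank`, `replicate`,
#'   `time_min`, `metabolite`, `isotopologue_index`, `mass_fraction` (and
#'   optionally `status`, which must be `"raw"`).
#' @param registry Registry tibble (`name`, `formula`, `n_tracer`), e.g.
#'   [default_registry()].
#' @param purity Tracer isotopic purity; default 0.98.
#' @param mode Correction mode, `"tracer_only"` (default) or `"full"`.
#' @param abundances Natural abundance table.
#' @return Tibble like `data` with `mass_fraction` replaced by corrected
#'   fractions, `status = "corrected"` and an `enrichment` column (the mean
#'   fractional enrichment, repeated within each vector).
#' @export
correct_isotopologues <- function(data, registry = default_registry(),
                                  purity = 0.98,
                                  mode = c("tracer_only", "full"),
                                  abundances = natural_abundance()) {
  mode <- match.arg(mode)
  required <- c("sample_id", "leaf_rank", "replicate", "time_min",
                "metabolite", "isotopologue_index", "mass_fraction")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if ("status" %in% names(data) && any(data$status != "raw")) {
    stop("correct_isotopologues expects raw vectors (status = 'raw')",
         call. = FALSE)
  }
  specs <- registry_specs(registry)
  unknown <- setdiff(unique(data$metabolite), names(specs))
  if (length(unknown)) {
    stop("metabolite(s) absent from registry: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  matrices <- purrr::map(specs, build_correction_matrix, purity = purity,
                         mode = mode, abundances = abundances)
  data |>
    dplyr::group_by(.data$sample_id, .data$leaf_rank, .data$replicate,
                    .data$time_min, .data$metabolite) |>
    dplyr::arrange(.data$isotopologue_index, .by_group = TRUE) |>
    dplyr::group_modify(function(d, key) {
      mat <- matrices[[key$metabolite]]
      corr <- correct_vector(d$mass_fraction, mat)
      tibble::tibble(
        isotopologue_index = d$isotopologue_index,
        mass_fraction = corr,
        status = "corrected",
        enrichment = mean_enrichment(corr)
      )
    }) |>
    dplyr::ungroup()
}

#' Per-sample enrichment time courses from corrected isotopologue data
#'
#' Collapses a corrected long isotopologue table to one row per
#' (metabolite, leaf rank, replicate, time), carrying the mean fractional
#' enrichment, and joins per-sample concentrations when given.
#'
#' @param corrected Output of [correct_isotopologues()].
#' @param concentrations Optional tibble with columns `leaf_rank`,
#'   `replicate`, `time_min`, `metabolite`, `concentration`.
#' @return Tibble with columns `metabolite`, `leaf_rank`, `replicate`,
#'   `time_min`, `enrichment` (and `concentration` if supplied).
#' @export
enrichment_timecourses <- function(corrected, concentrations = NULL) {
  tc <- corrected |>
    dplyr::distinct(.data$metabolite, .data$leaf_rank, .data$replicate,
                    .data$time_min, .data$enrichment) |>
    dplyr::arrange(.data$metabolite, .data$leaf_rank, .data$replicate,
                   .data$time_min)
  if (!is.null(concentrations)) {
    tc <- dplyr::left_join(
      tc,
      dplyr::select(concentrations, "metabolite", "leaf_rank", "replicate",
                    "time_min", "concentration"),
      by = c("metabolite", "leaf_rank", "replicate", "time_min")
    )
  }
  tc
}
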