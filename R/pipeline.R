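#' Validate the three input tables of a run
#'
#' Collects (rather than fail-fasts) schema and sanity violations: required
#' columns, mass fractions in `[0, 1]`, nonnegative concentrations, registry
#' coverage of every metabolite appearing in the data, and per-replicate time
#' point consistency (a replicate without a t = 0 sample is a warning, not a
#' violation: the fit proceeds with the x0 assumption flagged).
#'
#' @param registry Registry tibble (`name`, `formula`, `n_tracer`).
#' @param raw Long raw isotopologue tibble.
#' @param concentrations Long concentration tibble.
#' @return List of class `validation_report` with `violations` and `warnings`
#'   tibbles (columns `table`, `row`, `issue`) and `ok` (no violations).
#' @export
validate_tables <- function(registry, raw, concentrations) {
  violations <- list()
  warns <- list()
  note <- function(store, table, row, issue) {
    c(store, list(tibble::tibble(table = table, row = row, issue = issue)))
  }
  req_raw <- c("sample_id", "leaf_rank", "replicate", "time_min",
               "metabolite", "isotopologue_index", "mass_fraction")
  req_conc <- c("leaf_rank", "replicate", "time_min", "metabolite",
                "concentration")
  for (col in setdiff(req_raw, names(raw))) {
    violations <- note(violations, "raw", NA_integer_,
                       paste0("missing column '", col, "'"))
  }
  for (col in setdiff(req_conc, names(concentrations))) {
    violations <- note(violations, "concentrations", NA_integer_,
                       paste0("missing column '", col, "'"))
  }
  for (col in setdiff(c("name", "formula"), names(registry))) {
    violations <- note(violations, "registry", NA_integer_,
                       paste0("missing column '", col, "'"))
  }
  if (nrow(raw) == 0L) {
    violations <- note(violations, "raw", NA_integer_, "table is empty")
  }
  if (length(violations) == 0L) {
    bad <- which(raw$mass_fraction < 0 | raw$mass_fraction > 1 |
                   is.na(raw$mass_fraction))
    for (r in bad) {
      violations <- note(violations, "raw", r, "fraction out of range")
    }
    badc <- which(concentrations$concentration < 0 |
                    is.na(concentrations$concentration))
    for (r in badc) {
      violations <- note(violations, "concentrations", r,
                         "negative or missing concentration")
    }
    uncovered <- setdiff(unique(c(raw$metabolite, concentrations$metabolite)),
                         registry$name)
    for (met in uncovered) {
      violations <- note(violations, "registry", NA_integer_,
                         paste0("metabolite '", met,
                                "' absent from registry"))
    }
    # raw vectors must sum to <= 1 + tolerance
    sums <- raw |>
      dplyr::group_by(.data$sample_id, .data$metabolite) |>
      dplyr::summarise(s = sum(.data$mass_fraction), .groups = "drop")
    for (r in which(sums$s > 1 + 1e-6)) {
      violations <- note(violations, "raw", NA_integer_,
                         paste0("mass fractions of ", sums$metabolite[r],
                                " in ", sums$sample_id[r], " sum to ",
                                signif(sums$s[r], 6), " > 1"))
    }
    t0 <- raw |>
      dplyr::distinct(.data$leaf_rank, .data$replicate, .data$time_min) |>
      dplyr::group_by(.data$leaf_rank, .data$replicate) |>
      dplyr::summarise(has_t0 = any(.data$time_min == 0), .groups = "drop")
    for (r in which(!t0$has_t0)) {
      warns <- note(warns, "raw", NA_integer_,
                    paste0("replicate ", t0$leaf_rank[r], "/",
                           t0$replicate[r],
                           " missing t = 0 (x0 assumption flagged)"))
    }
  }
  empty <- tibble::tibble(table = character(), row = integer(),
                          issue = character())
  violations <- if (length(violations)) dplyr::bind_rows(violations) else empty
  warns <- if (length(warns)) dplyr::bind_rows(warns) else empty
  structure(list(violations = violations, warnings = warns,
                 ok = nrow(violations) == 0L),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", if (x$ok) "OK" else "FAILED", ": ",
      nrow(x$violations), " violation(s), ", nrow(x$warnings),
      " warning(s)\n", sep = "")
  if (nrow(x$violations)) print(x$violations, n = 20)
  invisible(x)
}

# sigma_c rule: max(replicate SD at that time point within the rank, 5% of
# the group-mean concentration), per metabolite x rank x time.
concentration_sigmas <- function(concentrations) {
  concentrations |>
    dplyr::group_by(.data$metabolite, .data$leaf_rank, .data$time_min) |>
    dplyr::summarise(
      sd_rep = stats::sd(.data$concentration),
      mean_conc = mean(.data$concentration),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$metabolite, .data$leaf_rank) |>
    dplyr::mutate(
      sigma_c = pmax(dplyr::coalesce(.data$sd_rep, 0),
                     0.05 * mean(.data$mean_conc))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("metabolite", "leaf_rank", "time_min", "sigma_c")
}

#' Run the full labeling analysis pipeline
#'
#' Orchestrates the stages in order: validate -> correct raw isotopologues ->
#' mean enrichments -> abundance filter -> label-input fits (precursors, per
#' replicate) -> subsystem flux fits (products x replicates) -> chi-square
#' gate -> per-rank flux summaries -> ANOVA/Tukey on estimated fluxes ->
#' fingerprint statistics on the t = 0 concentrations. All stages are
#' deterministic given the inputs, so identical inputs give byte-identical
#' outputs.
#'
#' @param raw Long raw isotopologue tibble (see [correct_isotopologues()]).
#' @param concentrations Long concentration tibble (`leaf_rank`, `replicate`,
#'   `time_min`, `metabolite`, `concentration`).
#' @param registry Registry tibble; default [default_registry()].
#' @param subsystems Tibble with columns `precursor`, `product`; default the
#'   three single-nitrogen subsystems Glu->Pro, Glu->Val, Asp->Thr.
#' @param purity Tracer purity for the correction; default 0.98.
#' @param mode Correction mode; default `"tracer_only"`.
#' @param sigma_x Isotopic measurement SD; default 0.02.
#' @param alpha Level for the chi-square gate and group tests; default 0.05.
#' @param input_family Label-input family passed to [fit_label_input()].
#' @param shared_input If `TRUE`, one label-input function is fitted per
#'   rank (pooling replicates) instead of per replicate.
#' @param n_starts Multi-start count for [fit_subsystem()].
#' @param out_dir Optional output directory; when given, fits, summaries,
#'   comparisons, corrected data and a JSON run manifest are written there.
#' @return List of class `run_manifest`: `validation`, `fits` (tibble),
#'   `flux_summary`, `flux_comparisons`, `fingerprint`, `major`,
#'   `corrected`, `counts` (per-stage record counts), `warnings`, `config`.
#' @export
run_pipeline <- function(raw, concentrations, registry = default_registry(),
                         subsystems = NULL, purity = 0.98,
                         mode = c("tracer_only", "full"), sigma_x = 0.02,
                         alpha = 0.05, input_family = "auto",
                         shared_input = FALSE, n_starts = 20,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(subsystems)) {
    subsystems <- tibble::tribble(
      ~precursor, ~product,
      "Glu", "Pro",
      "Glu", "Val",
      "Asp", "Thr"
    )
  }
  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  validation <- validate_tables(registry, raw, concentrations)
  config <- list(purity = purity, mode = mode, sigma_x = sigma_x,
                 alpha = alpha, input_family = input_family,
                 shared_input = shared_input, n_starts = n_starts,
                 subsystems = subsystems)
  if (!validation$ok) {
    manifest <- structure(
      list(validation = validation, fits = NULL, flux_summary = NULL,
           flux_comparisons = NULL, fingerprint = NULL, major = NULL,
           corrected = NULL, counts = list(raw = nrow(raw)),
           warnings = paste("validation:", validation$violations$issue),
           config = config, ok = FALSE),
      class = "run_manifest")
    if (!is.null(out_dir)) write_manifest(manifest, out_dir)
    return(manifest)
  }
  miss_prec <- setdiff(subsystems$precursor, unique(raw$metabolite))
  if (length(miss_prec)) {
    stop("subsystem precursor(s) missing from data: ",
         paste(miss_prec, collapse = ", "), call. = FALSE)
  }

  corrected <- withCallingHandlers(
    correct_isotopologues(raw, registry, purity = purity, mode = mode),
    warning = log_warning)
  tc <- enrichment_timecourses(corrected, concentrations)
  major <- filter_major(concentrations)
  sig_c <- concentration_sigmas(concentrations)

  ranks <- unique(tc$leaf_rank)
  reps <- unique(tc$replicate)
  fit_list <- list()
  for (si in seq_len(nrow(subsystems))) {
    sub <- subsystems[si, ]
    for (rank in ranks) {
      input_shared <- NULL
      if (shared_input) {
        d_in <- dplyr::filter(tc, .data$metabolite == sub$precursor,
                              .data$leaf_rank == rank)
        input_shared <- withCallingHandlers(
          fit_label_input(d_in, family = input_family, sigma = sigma_x),
          warning = log_warning)
      }
      for (rep_i in reps) {
        d_in <- dplyr::filter(tc, .data$metabolite == sub$precursor,
                              .data$leaf_rank == rank,
                              .data$replicate == rep_i)
        d_out <- dplyr::filter(tc, .data$metabolite == sub$product,
                               .data$leaf_rank == rank,
                               .data$replicate == rep_i)
        if (nrow(d_out) == 0L || nrow(d_in) == 0L) next
        input <- input_shared %||% withCallingHandlers(
          fit_label_input(d_in, family = input_family, sigma = sigma_x),
          warning = log_warning)
        sc_vec <- sig_c$sigma_c[sig_c$metabolite == sub$product &
                                  sig_c$leaf_rank == rank][
                                    order(sig_c$time_min[
                                      sig_c$metabolite == sub$product &
                                        sig_c$leaf_rank == rank])]
        fit <- withCallingHandlers(
          fit_subsystem(d_out, input, subsystem = sub, sigma_x = sigma_x,
                        sigma_c = sc_vec, n_starts = n_starts,
                        leaf_rank = rank, replicate = rep_i),
          warning = log_warning)
        fit$chi2_pass <- chi_square_gate(fit, alpha = alpha)
        fit_list <- c(fit_list, list(fit))
      }
    }
  }
  fits <- fits_table(fit_list)
  flux_summary <- withCallingHandlers(
    summarize_fluxes(fits, include_failed = FALSE),
    warning = log_warning)
  # group comparison of estimated fluxes across ranks, per subsystem
  flux_comparisons <- purrr::map_dfr(unique(fits$product), function(p) {
    d <- fits |>
      dplyr::filter(.data$product == p) |>
      dplyr::rename(concentration = "v_hat")
    if (length(unique(d$leaf_rank)) < 2L ||
        any(table(d$leaf_rank) < 2L)) return(NULL)
    cmp <- anova_tukey(d, alpha = alpha)
    dplyr::mutate(tidy(cmp), metabolite = p)
  })
  fingerprint <- withCallingHandlers(
    fingerprint_stats(dplyr::filter(concentrations, .data$time_min == 0),
                      alpha = alpha),
    warning = log_warning)

  manifest <- structure(
    list(validation = validation, fits = fits, flux_summary = flux_summary,
         flux_comparisons = flux_comparisons, fingerprint = fingerprint,
         major = major, corrected = corrected,
         counts = list(raw = nrow(raw), corrected = nrow(corrected),
                       timecourses = nrow(tc), fits = nrow(fits),
                       chi2_pass = sum(fits$chi2_pass),
                       summary_groups = nrow(flux_summary)),
         warnings = warnings_log, config = config, ok = TRUE),
    class = "run_manifest")
  if (!is.null(out_dir)) write_manifest(manifest, out_dir)
  manifest
}

write_manifest <- function(manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(manifest$fits)) {
    readr::write_csv(manifest$fits, file.path(out_dir, "fits.csv"))
    readr::write_csv(manifest$flux_summary,
                     file.path(out_dir, "flux_summary.csv"))
    readr::write_csv(manifest$corrected,
                     file.path(out_dir, "corrected_isotopologues.csv"))
    if (!is.null(manifest$flux_comparisons) &&
        nrow(manifest$flux_comparisons)) {
      readr::write_csv(manifest$flux_comparisons,
                       file.path(out_dir, "flux_comparisons.csv"))
    }
    if (!is.null(manifest$fingerprint$comparisons)) {
      readr::write_csv(manifest$fingerprint$comparisons,
                       file.path(out_dir, "fingerprint_comparisons.csv"))
    }
    if (!is.null(manifest$fingerprint$pca)) {
      readr::write_csv(manifest$fingerprint$pca$scores,
                       file.path(out_dir, "pca_scores.csv"))
      readr::write_csv(manifest$fingerprint$pca$loadings_corr,
                       file.path(out_dir, "pca_loadings.csv"))
    }
  }
  json <- list(
    ok = manifest$ok,
    counts = manifest$counts,
    warnings = manifest$warnings,
    violations = if (nrow(manifest$validation$violations)) {
      manifest$validation$violations
    } else {
      NULL
    },
    config = manifest$config[setdiff(names(manifest$config), "subsystems")],
    version = as.character(utils::packageVersion("leafflux"))
  )
  jsonlite::write_json(json, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", if (x$ok) "ok" else "FAILED (validation)", "\n",
      sep = "")
  if (!is.null(x$counts$fits)) {
    cat("  fits: ", x$counts$fits, " (", x$counts$chi2_pass,
        " pass chi-square)\n", sep = "")
  }
  if (length(x$warnings)) {
    cat("  warnings: ", length(x$warnings), "\n", sep = "")
  }
  invisible(x)
}
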