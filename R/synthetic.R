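#' Default synthetic labeling scenario
#'
#' The stated world for the synthetic leaf-disc glycine-labeling experiment:
#' four leaf ranks spanning the sink-to-source transition (L15 young sink to
#' L3 old source), 3 biological replicates, sampling at 0/30/60/120 min, a
#' glycine label input plateauing near 0.80 fractional enrichment well before
#' 30 min, three single-nitrogen subsystems (Glu -> Pro, Glu -> Val,
#' Asp -> Thr) with Thr and Val fluxes three times the Pro flux in the
#' youngest rank and all fluxes declining monotonically towards the oldest
#' rank, isotopic measurement noise SD 0.02 on mass fractions, tracer purity
#' 0.98, and lognormal concentration noise (CV 0.1). Pool sizes encode the
#' fingerprint contrasts (Asn/Gln/Pro/SMCSO highest in L15, Thr rising with
#' leaf age, Val peaking at L7).
#'
#' @param seed Integer seed; the scenario embeds it so [generate_dataset()]
#'   is deterministic.
#' @return Object of class `synthetic_scenario`.
#' @export
#' @examples
#' sc <- default_scenario(seed = 1)
#' sc$true_fluxes
default_scenario <- function(seed = 1L) {
  ranks <- c("L15", "L11", "L7", "L3")
  subsystems <- tibble::tribble(
    ~precursor, ~product,
    "Glu",      "Pro",
    "Glu",      "Val",
    "Asp",      "Thr"
  )
  true_fluxes <- tibble::tibble(
    product = rep(c("Pro", "Val", "Thr"), each = 4),
    leaf_rank = rep(ranks, times = 3),
    flux = c(30, 22, 14, 10,    # Pro, nmol g-1 DW min-1
             90, 66, 42, 30,    # Val = 3 x Pro in L15
             90, 66, 42, 30)    # Thr = 3 x Pro in L15
  )
  pools <- tibble::tribble(
    ~metabolite, ~L15, ~L11, ~L7, ~L3,
    "Gly",    4.0,  6.0,  9.0, 12.0,
    "Ala",    2.5,  2.4,  2.3,  2.2,
    "Ser",    3.0,  3.0,  3.0,  3.0,
    "Pro",    3.0,  1.5,  1.2,  1.0,
    "Val",    1.5,  1.6,  2.6,  1.8,
    "Thr",    1.5,  2.2,  2.5,  2.6,
    "Glu",    6.0,  5.5,  5.0,  4.5,
    "Asp",    4.0,  3.8,  3.6,  3.4,
    "Asn",    5.0,  2.0,  1.5,  1.2,
    "Gln",    6.0,  2.5,  2.0,  1.8,
    "SMCSO", 12.0,  7.0,  6.0,  5.0,
    "Trp",    0.4,  0.4,  0.4,  0.4
  ) |>
    tidyr::pivot_longer(-"metabolite", names_to = "leaf_rank",
                        values_to = "pool")
  # Precursor and bystander enrichment curves: plateau/rate per rank.
  # Nitrogen incorporation slows with source status.
  curve <- function(met, plateaus, rate) {
    tibble::tibble(metabolite = met, leaf_rank = ranks, plateau = plateaus,
                   rate = rate)
  }
  precursor_curves <- dplyr::bind_rows(
    curve("Gly", rep(0.80, 4), 0.2),
    curve("Glu", c(0.45, 0.40, 0.35, 0.30), 0.04),
    curve("Asp", c(0.50, 0.45, 0.40, 0.35), 0.05),
    curve("Ser", c(0.40, 0.35, 0.30, 0.25), 0.05),
    curve("Ala", c(0.35, 0.32, 0.30, 0.28), 0.06),
    curve("Asn", c(0.12, 0.10, 0.08, 0.06), 0.02),
    curve("Gln", c(0.35, 0.30, 0.25, 0.20), 0.03),
    curve("SMCSO", c(0.03, 0.02, 0.015, 0.01), 0.005),
    curve("Trp", rep(0.05, 4), 0.01)
  )
  structure(
    list(
      leaf_ranks = ranks,
      n_replicates = 3L,
      times = c(0, 30, 60, 120),
      input_plateau = 0.80,
      input_rate = 0.2,
      subsystems = subsystems,
      true_fluxes = true_fluxes,
      pools = pools,
      precursor_curves = precursor_curves,
      sigma_x = 0.02,
      conc_cv = 0.1,
      purity = 0.98,
      gly_t0_conc = 0.2,
      registry = default_registry(),
      seed = as.integer(seed)
    ),
    class = "synthetic_scenario"
  )
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("<synthetic_scenario> ", length(x$leaf_ranks), " ranks x ",
      x$n_replicates, " replicates x ", length(x$times), " times; ",
      nrow(x$subsystems), " subsystems; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

validate_scenario <- function(sc) {
  stopifnot(inherits(sc, "synthetic_scenario"))
  if (any(sc$true_fluxes$flux < 0)) stop("fluxes must be >= 0", call. = FALSE)
  if (any(sc$pools$pool <= 0)) stop("pools must be > 0", call. = FALSE)
  if (sc$input_plateau <= 0 || sc$input_plateau > 1) {
    stop("input_plateau must lie in (0, 1]", call. = FALSE)
  }
  if (sc$sigma_x < 0 || sc$conc_cv < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (sc$purity <= 0 || sc$purity > 1) {
    stop("purity must lie in (0, 1]", call. = FALSE)
  }
  need <- unique(c(sc$subsystems$precursor, sc$subsystems$product, "Gly"))
  have <- unique(sc$precursor_curves$metabolite)
  miss <- setdiff(setdiff(need, sc$subsystems$product), have)
  if (length(miss)) {
    stop("no enrichment curve for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  invisible(sc)
}

# true (noiseless) enrichment of a metabolite at given times within one rank
scenario_enrichment <- function(sc, metabolite, rank, times) {
  sub <- sc$subsystems[sc$subsystems$product == metabolite, ]
  if (nrow(sub) == 1L) {
    # flux-modeled product: integrate the subsystem ODE from its precursor
    pc <- sc$precursor_curves[sc$precursor_curves$metabolite == sub$precursor &
                                sc$precursor_curves$leaf_rank == rank, ]
    inp <- label_input_curve(pc$plateau, pc$rate, t_max = max(times))
    v <- sc$true_fluxes$flux[sc$true_fluxes$product == metabolite &
                               sc$true_fluxes$leaf_rank == rank]
    M <- sc$pools$pool[sc$pools$metabolite == metabolite &
                         sc$pools$leaf_rank == rank]
    simulate_enrichment(inp, times, v, M)
  } else {
    pc <- sc$precursor_curves[sc$precursor_curves$metabolite == metabolite &
                                sc$precursor_curves$leaf_rank == rank, ]
    pc$plateau * (1 - exp(-pc$rate * times))
  }
}

#' Generate a complete synthetic leaf-disc labeling dataset
#'
#' Simulates the experiment a scenario describes: for every rank, replicate
#' and time point, precursor enrichments follow their saturating input
#' curves, product enrichments follow the two-reaction subsystem model at the
#' scenario's true `(v, M)`, and concentrations sit at the pseudo-steady-state
#' pools. Corrected isotopologue distributions (binomial over the nitrogen
#' positions at the metabolite's enrichment) are pushed forward through the
#' correction matrix — embedding tracer impurity and natural 15N abundance —
#' to give raw mass fractions, to which Gaussian noise of SD `sigma_x` is
#' added (clipped at 0, renormalized). Concentrations get lognormal noise of
#' CV `conc_cv`, mean-preserving. Deterministic given `scenario$seed`.
#'
#' @param scenario A `synthetic_scenario`, e.g. [default_scenario()].
#' @return List of class `synthetic_dataset`: `raw_isotopologues` (long raw
#'   table), `concentrations` (long table), `registry`, and `truth` (the
#'   scenario).
#' @export
#' @examples
#' ds <- generate_dataset(default_scenario(seed = 42))
#' head(ds$raw_isotopologues)
generate_dataset <- function(scenario) {
  validate_scenario(scenario)
  sc <- scenario
  set.seed(sc$seed)
  specs <- registry_specs(sc$registry)
  matrices <- purrr::map(specs, build_correction_matrix, purity = sc$purity)
  mets <- sc$registry$name
  sdlog <- sqrt(log(1 + sc$conc_cv^2))

  grid <- tidyr::expand_grid(
    leaf_rank = sc$leaf_ranks,
    replicate = seq_len(sc$n_replicates),
    metabolite = mets
  )
  raw_rows <- vector("list", nrow(grid))
  conc_rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rank <- grid$leaf_rank[i]
    rep_i <- grid$replicate[i]
    met <- grid$metabolite[i]
    n <- specs[[met]]$n_tracer
    enr <- scenario_enrichment(sc, met, rank, sc$times)
    pool <- sc$pools$pool[sc$pools$metabolite == met &
                            sc$pools$leaf_rank == rank]
    conc_true <- rep(pool, length(sc$times))
    if (met == "Gly") conc_true[sc$times == 0] <- sc$gly_t0_conc
    raw_i <- purrr::map_dfr(seq_along(sc$times), function(ti) {
      x_corr <- stats::dbinom(0:n, n, enr[ti])
      raw <- as.numeric(matrices[[met]]$entries %*% x_corr)
      if (sc$sigma_x > 0) {
        raw <- raw + stats::rnorm(n + 1L, 0, sc$sigma_x)
        raw <- pmax(raw, 0)
        if (sum(raw) > 0) raw <- raw / sum(raw)
      }
      tibble::tibble(
        sample_id = paste0(rank, "_r", rep_i, "_t", sc$times[ti]),
        leaf_rank = rank, replicate = rep_i, time_min = sc$times[ti],
        metabolite = met, isotopologue_index = 0:n,
        mass_fraction = raw, status = "raw"
      )
    })
    conc_noise <- if (sc$conc_cv > 0) {
      exp(stats::rnorm(length(sc$times), -sdlog^2 / 2, sdlog))
    } else {
      rep(1, length(sc$times))
    }
    conc_i <- tibble::tibble(
      sample_id = paste0(rank, "_r", rep_i, "_t", sc$times),
      leaf_rank = rank, replicate = rep_i, time_min = sc$times,
      metabolite = met, concentration = conc_true * conc_noise
    )
    raw_rows[[i]] <- raw_i
    conc_rows[[i]] <- conc_i
  }
  structure(
    list(
      raw_isotopologues = dplyr::bind_rows(raw_rows),
      concentrations = dplyr::bind_rows(conc_rows),
      registry = sc$registry,
      truth = sc
    ),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$raw_isotopologues),
      " raw isotopologue rows, ", nrow(x$concentrations),
      " concentration rows (seed ", x$truth$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to CSV/JSON files
#'
#' Emits `raw_isotopologues.csv`, `concentrations.csv`, `registry.csv` and
#' `truth.json` (scenario scalars plus the true flux/pool tables) into a
#' directory.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("raw_isotopologues.csv", "concentrations.csv",
                            "registry.csv", "truth.json"))
  readr::write_csv(dataset$raw_isotopologues, paths[1])
  readr::write_csv(dataset$concentrations, paths[2])
  readr::write_csv(dataset$registry, paths[3])
  sc <- dataset$truth
  truth <- list(
    leaf_ranks = sc$leaf_ranks, n_replicates = sc$n_replicates,
    times = sc$times, input_plateau = sc$input_plateau,
    input_rate = sc$input_rate, sigma_x = sc$sigma_x, conc_cv = sc$conc_cv,
    purity = sc$purity, seed = sc$seed,
    subsystems = sc$subsystems, true_fluxes = sc$true_fluxes,
    pools = sc$pools, precursor_curves = sc$precursor_curves
  )
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
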