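#' Fit a two-reaction subsystem flux model to one replicate
#'
#' Estimates the flux `v` (nmol g-1 DW min-1) and pool size `M` (µmol g-1 DW)
#' of a single-nitrogen biosynthesis subsystem (precursor -> product with an
#' equal-rate sink) by minimizing the sum of squared weighted differences
#' between measured and simulated enrichment and concentration dynamics:
#'
#' `SSR(v, M) = sum(((x_sim(t) - x_obs(t)) / sigma_x)^2) +
#'             sum(((M - c_obs(t)) / sigma_c(t))^2)`
#'
#' with `x_sim` from [simulate_enrichment()]. The optimizer is bounded
#' L-BFGS-B with multi-start (log-spaced starts for `v`, `M` started at the
#' mean observed concentration) followed by a derivative-free polish; the best
#' minimum is reported.
#'
#' @param data Tibble with one product time course: columns `time_min`,
#'   `enrichment`, `concentration`.
#' @param input Label input: a `label_input` object (typically from
#'   [fit_label_input()] on the precursor).
#' @param subsystem Optional list/row with `precursor` and `product` names,
#'   recorded in the fit.
#' @param sigma_x Enrichment measurement SD; default 0.02.
#' @param sigma_c Concentration SD, scalar or per time point; default 5% of
#'   the mean observed concentration.
#' @param x0 Product enrichment at `t = 0`; default 0.
#' @param n_starts Number of log-spaced multi-start values for `v`; default 20.
#' @param fix_M If `TRUE`, `M` is fixed at the mean observed concentration and
#'   only `v` is fitted.
#' @param leaf_rank,replicate Optional labels carried into the fit.
#' @return Object of class `subsystem_fit` with `v_hat`, `M_hat`, `ssr`,
#'   `dof`, `chi2_pass` (at alpha = 0.05), `boundary` flag,
#'   `n_restarts_used`, the data and labels.
#' @export
#' @examples
#' inp <- label_input_curve(0.5, 0.04)
#' tms <- c(0, 30, 60, 120)
#' tc <- tibble::tibble(time_min = tms,
#'                      enrichment = simulate_enrichment(inp, tms, 30, 2),
#'                      concentration = 2)
#' fit_subsystem(tc, inp)
fit_subsystem <- function(data, input, subsystem = NULL, sigma_x = 0.02,
                          sigma_c = NULL, x0 = 0, n_starts = 20,
                          fix_M = FALSE, leaf_rank = NA_character_,
                          replicate = NA) {
  stopifnot(all(c("time_min", "enrichment", "concentration") %in% names(data)))
  data <- dplyr::arrange(data, .data$time_min)
  times <- as.numeric(data$time_min)
  x_obs <- as.numeric(data$enrichment)
  c_obs <- as.numeric(data$concentration)
  stopifnot(sigma_x > 0)
  informative <- sum(!is.na(x_obs) & !is.na(times))
  if (informative < 3L || length(unique(times)) < 3L) {
    stop("non-identifiable: need >= 3 informative time points (got ",
         length(unique(times)), ")", call. = FALSE)
  }
  if (max(times) <= 0) {
    stop("non-identifiable: only t = 0 data", call. = FALSE)
  }
  if (is.null(sigma_c)) sigma_c <- 0.05 * mean(c_obs)
  sigma_c <- rep_len(sigma_c, length(c_obs))
  stopifnot(all(sigma_c > 0))
  M_start <- mean(c_obs)

  objective <- function(theta) {
    # clamp: finite-difference gradient probes may step just outside bounds
    v <- max(theta[1], 0)
    M <- if (fix_M) M_start else max(theta[2], 1e-9)
    x_sim <- simulate_enrichment(input, times, v, M, x0 = x0)
    sum(((x_sim - x_obs) / sigma_x)^2) + sum(((M - c_obs) / sigma_c)^2)
  }

  v_starts <- 10^seq(-2, 3, length.out = n_starts)
  lower <- if (fix_M) 0 else c(0, 1e-6)
  upper <- if (fix_M) 1e6 else c(1e6, 1e4)
  best <- NULL
  for (v0 in v_starts) {
    par0 <- if (fix_M) v0 else c(v0, M_start)
    fit <- tryCatch(
      stats::optim(par0, objective, method = "L-BFGS-B", lower = lower,
                   upper = upper, control = list(factr = 1e3, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    stop("flux estimation failed to converge for replicate ", replicate,
         call. = FALSE)
  }
  # polish: Nelder-Mead needs >= 2 parameters
  if (!fix_M) {
    pol <- stats::optim(best$par, objective,
                        control = list(reltol = 1e-14, maxit = 5000))
    if (pol$value <= best$value) best <- pol
  }
  pol2 <- tryCatch(
    stats::optim(best$par, objective, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(factr = 1, maxit = 2000)),
    error = function(e) NULL)
  if (!is.null(pol2) && pol2$value < best$value) best <- pol2

  theta <- pmin(pmax(best$par, lower), upper)
  v_hat <- theta[1]
  M_hat <- if (fix_M) M_start else theta[2]
  n_par <- if (fix_M) 1L else 2L
  dof <- length(x_obs) + length(c_obs) - n_par
  if (dof < 1L) stop("residual degrees of freedom < 1", call. = FALSE)
  ssr <- best$value
  boundary <- v_hat >= upper[1] * (1 - 1e-8)
  if (boundary) {
    warning("flux estimate pinned at its upper bound", call. = FALSE)
  }
  fit <- structure(
    list(precursor = if (!is.null(subsystem)) subsystem$precursor else NA_character_,
         product = if (!is.null(subsystem)) subsystem$product else NA_character_,
         leaf_rank = leaf_rank, replicate = replicate,
         v_hat = unname(v_hat), M_hat = unname(M_hat),
         ssr = ssr, dof = dof, chi2_pass = NA,
         boundary = boundary, n_restarts_used = n_starts,
         sigma_x = sigma_x, sigma_c = sigma_c, x0 = x0,
         input = input, data = data),
    class = "subsystem_fit"
  )
  fit$chi2_pass <- chi_square_gate(fit)
  fit
}

#' Chi-square goodness-of-fit gate for a subsystem fit
#'
#' Upper-tail test: the fit passes iff its weighted SSR does not exceed the
#' `1 - alpha` chi-square quantile at the fit's residual degrees of freedom.
#' Overdispersion rejects; a suspiciously small SSR only warns (at the
#' `alpha`-quantile lower tail) and still passes.
#'
#' @param fit A `subsystem_fit`, or anything with `ssr` and `dof` fields.
#' @param alpha Test level; default 0.05.
#' @return `TRUE` (pass) or `FALSE` (reject).
#' @export
chi_square_gate <- function(fit, alpha = 0.05) {
  ssr <- fit$ssr
  dof <- fit$dof
  stopifnot(dof >= 1, alpha > 0, alpha < 1)
  if (ssr > 0 && ssr < stats::qchisq(alpha, dof) && dof >= 2) {
    # suspiciously good fit; do not reject
    rlang::warn("SSR below the lower-tail chi-square quantile (suspiciously small)",
                .frequency = "once", .frequency_id = "leafflux_chi2_low")
  }
  ssr <= stats::qchisq(1 - alpha, dof)
}

#' @export
print.subsystem_fit <- function(x, ...) {
  cat("<subsystem_fit> ", x$precursor, " -> ", x$product,
      if (!is.na(x$leaf_rank)) paste0(" [", x$leaf_rank, ", rep ",
                                      x$replicate, "]"), "\n",
      "  v = ", signif(x$v_hat, 5), " nmol g-1 DW min-1, M = ",
      signif(x$M_hat, 5), " umol g-1 DW\n",
      "  SSR = ", signif(x$ssr, 4), " on ", x$dof,
      " dof; chi-square ", if (isTRUE(x$chi2_pass)) "pass" else "REJECT",
      "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.subsystem_fit <- function(x, ...) {
  tibble::tibble(
    term = c("v", "M"),
    estimate = c(x$v_hat, x$M_hat),
    unit = c("nmol g-1 DW min-1", "umol g-1 DW")
  )
}

#' @exportS3Method generics::glance
glance.subsystem_fit <- function(x, ...) {
  tibble::tibble(
    precursor = x$precursor, product = x$product,
    leaf_rank = x$leaf_rank, replicate = x$replicate,
    v_hat = x$v_hat, M_hat = x$M_hat, ssr = x$ssr, dof = x$dof,
    chi2_pass = x$chi2_pass, boundary = x$boundary,
    n_restarts_used = x$n_restarts_used
  )
}

#' Collapse a list of subsystem fits to one row per fit
#'
#' @param fits List of `subsystem_fit` objects.
#' @return Tibble with one [glance()] row per fit.
#' @export
fits_table <- function(fits) {
  purrr::map_dfr(fits, glance)
}

#' Summarize replicate fluxes per leaf rank
#'
#' Mean and sample SD of the estimated flux across biological replicates,
#' per subsystem and leaf rank. By default only fits that passed the
#' chi-square gate enter the summary; excluded fits are reported in the
#' `n_excluded` column, and groups left with no passing fit are dropped with
#' a warning.
#'
#' @param fits Tibble of fits (as from [fits_table()]) with columns
#'   `precursor`, `product`, `leaf_rank`, `v_hat`, `chi2_pass`; or a list of
#'   `subsystem_fit` objects.
#' @param include_failed Include fits that failed the chi-square gate.
#' @return Tibble with columns `precursor`, `product`, `leaf_rank`,
#'   `mean_flux`, `sd_flux` (`NA` when `n = 1`), `n`, `n_excluded`.
#' @export
summarize_fluxes <- function(fits, include_failed = FALSE) {
  if (!is.data.frame(fits)) fits <- fits_table(fits)
  grouped <- fits |>
    dplyr::group_by(.data$precursor, .data$product, .data$leaf_rank)
  out <- grouped |>
    dplyr::summarise(
      n_excluded = sum(!.data$chi2_pass & !include_failed),
      mean_flux = mean(.data$v_hat[.data$chi2_pass | include_failed]),
      sd_flux = stats::sd(.data$v_hat[.data$chi2_pass | include_failed]),
      n = sum(.data$chi2_pass | include_failed),
      .groups = "drop"
    )
  empty <- out$n == 0
  if (any(empty)) {
    warning("dropping group(s) with no passing fit: ",
            paste(out$product[empty], out$leaf_rank[empty], sep = "/",
                  collapse = ", "), call. = FALSE)
    out <- out[!empty, , drop = FALSE]
  }
  dplyr::relocate(out, "n_excluded", .after = "n")
}
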