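test_that("constant data fit to a constant input with zero residual", {
  tc <- tibble::tibble(time_min = c(0, 30, 60, 120), enrichment = 0.8)
  f <- fit_label_input(tc)
  expect_equal(unname(predict(f, c(0, 15, 120))), rep(0.8, 3),
               tolerance = 1e-6)
  expect_lt(f$fit_rss, 1e-10)
})

test_that("noise-free single-exponential data are recovered to 1e-6", {
  tms <- c(0, 30, 60, 120)
  tc <- tibble::tibble(time_min = tms,
                       enrichment = 0.8 * (1 - exp(-0.2 * tms)))
  f <- fit_label_input(tc)
  expect_equal(f$form, "single_exp")
  expect_equal(unname(f$params[["a1"]]), 0.8, tolerance = 1e-6)
  expect_equal(unname(f$params[["k1"]]), 0.2, tolerance = 1e-6)
  expect_equal(unname(f$params[["x0"]]), 0, tolerance = 1e-6)
})

test_that("a glycine-like plateau is tracked near 0.80", {
  tc <- tibble::tibble(time_min = c(0, 30, 60, 120),
                       enrichment = c(0, 0.79, 0.80, 0.81))
  f <- fit_label_input(tc)
  expect_lt(abs(predict(f, 120) - 0.80), 0.02)
})

test_that("input-fit preconditions and fallbacks behave as specified", {
  expect_error(
    fit_label_input(tibble::tibble(time_min = c(0, 30),
                                   enrichment = c(0, 0.5))),
    ">= 3 distinct time points")
  expect_error(
    fit_label_input(tibble::tibble(time_min = c(30, 60, 120),
                                   enrichment = c(0.1, 0.2, 0.3))),
    "t = 0")
  expect_error(
    fit_label_input(tibble::tibble(time_min = c(0, 30, 60),
                                   enrichment = c(0, 0.5, 1.4))),
    "\\[0, 1\\]")
  # requesting double_exp with 4 points falls back with a warning
  tms <- c(0, 30, 60, 120)
  tc <- tibble::tibble(time_min = tms,
                       enrichment = 0.6 * (1 - exp(-0.1 * tms)))
  expect_warning(f <- fit_label_input(tc, family = "double_exp"),
                 "falling back")
  expect_true(f$form %in% c("single_exp", "constant"))
  # wildly non-monotone data are flagged, not fatal
  bad <- tibble::tibble(time_min = c(0, 30, 60, 120),
                        enrichment = c(0, 0.9, 0.05, 0.95))
  expect_warning(fb <- fit_label_input(bad), "10 sigma")
  expect_true(fb$flagged)
})

test_that("double-exponential family is selected with enough points", {
  tms <- c(0, 10, 20, 40, 60, 90, 120)
  u <- 0.1 + 0.4 * (1 - exp(-0.03 * tms)) + 0.3 * (1 - exp(-0.5 * tms))
  f <- fit_label_input(tibble::tibble(time_min = tms, enrichment = u))
  expect_equal(f$form, "double_exp")
  expect_equal(unname(predict(f, tms)), u, tolerance = 1e-4)
})

test_that("zero flux freezes product labeling", {
  inp <- label_input_curve(0.8, 0.2)
  expect_equal(simulate_enrichment(inp, c(0, 30, 60), v = 0, M = 2, x0 = 0.1),
               rep(0.1, 3))
})

test_that("constant input matches the closed-form one-pool solution", {
  set.seed(3)
  for (rep_i in 1:100) {
    u <- stats::runif(1, 0.1, 1)
    v <- stats::runif(1, 1, 200)
    M <- stats::runif(1, 0.5, 10)
    k <- v / (1000 * M)
    inp <- label_input_curve(u, rate = 0) # plateau u from x0 = u
    inp$params["x0"] <- u; inp$params["a1"] <- 0
    tms <- c(0, 30, 60, 120, M * 1000 / v)
    expect_equal(simulate_enrichment(inp, sort(tms), v, M),
                 u * (1 - exp(-k * sort(tms))), tolerance = 1e-6)
  }
})

test_that("closed form matches a fine-step Euler oracle on a two-exponential input", {
  params <- c(x0 = 0.05, a1 = 0.4, k1 = 0.03, a2 = 0.3, k2 = 0.5)
  inp <- structure(list(form = "double_exp", params = params, fit_rss = 0,
                        t_domain = c(0, 120), n_obs = 0L, flagged = FALSE),
                   class = "label_input")
  ufun <- function(t) {
    0.05 + 0.4 * (1 - exp(-0.03 * t)) + 0.3 * (1 - exp(-0.5 * t))
  }
  tms <- c(0, 30, 60, 120)
  v <- 30; M <- 2
  got <- simulate_enrichment(inp, tms, v, M)
  oracle <- euler_enrichment(ufun, tms, v / (1000 * M), 0, dt = 0.001)
  expect_equal(got, oracle, tolerance = 1e-6)
  # RK4 path (plain function input) agrees too
  expect_equal(simulate_enrichment(ufun, tms, v, M), oracle,
               tolerance = 1e-6)
})

test_that("repeated-eigenvalue case (k equals input rate) is finite and correct", {
  inp <- label_input_curve(0.8, rate = 0.015)
  v <- 30; M <- 2 # k = 0.015 exactly
  got <- simulate_enrichment(inp, c(0, 30, 60, 120), v, M)
  oracle <- euler_enrichment(function(t) 0.8 * (1 - exp(-0.015 * t)),
                             c(0, 30, 60, 120), 0.015, 0, dt = 0.0005)
  expect_equal(got, oracle, tolerance = 1e-5)
})

test_that("simulated enrichment is bounded and monotone for monotone input", {
  set.seed(9)
  for (rep_i in 1:20) {
    inp <- label_input_curve(stats::runif(1, 0.2, 1),
                             stats::runif(1, 0.01, 0.5))
    v <- stats::runif(1, 1, 300)
    M <- stats::runif(1, 0.5, 10)
    tms <- seq(0, 120, by = 5)
    x <- simulate_enrichment(inp, tms, v, M)
    expect_true(all(x >= -1e-12 & x <= max(predict(inp, tms)) + 1e-12))
    expect_true(all(diff(x) >= -1e-10))
  }
})

test_that("as v grows the product tracks the input pointwise", {
  inp <- label_input_curve(0.8, 0.2)
  tms <- c(10, 30, 60, 120)
  x <- simulate_enrichment(inp, tms, v = 1e7, M = 2)
  expect_equal(x, unname(predict(inp, tms)), tolerance = 1e-3)
})

test_that("steady-state concentration is constant and flux-independent", {
  expect_equal(simulate_concentration(2, c(0, 30, 60, 120)), rep(2, 4))
  expect_equal(simulate_concentration(0.5, 0), 0.5)
})
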