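# Independent oracles used by the tests. These deliberately avoid the code
# paths of the implementation: enumeration instead of convolution, explicit
# Euler stepping instead of the closed-form ODE solution.

# Brute-force isotopic envelope: enumerate every atom's isotope state and sum
# the probability of each total nominal mass shift. `atom_dists` is a list of
# per-atom shift distributions (index 1 = shift 0), one entry per atom.
enumerate_envelope <- function(atom_dists, max_shift) {
  states <- lapply(atom_dists, function(d) seq_along(d) - 1L)
  grid <- expand.grid(states)
  probs <- vapply(seq_len(nrow(grid)), function(i) {
    prod(vapply(seq_along(atom_dists),
                function(a) atom_dists[[a]][grid[i, a] + 1L], numeric(1)))
  }, numeric(1))
  shift <- rowSums(grid)
  out <- numeric(max_shift + 1L)
  for (s in 0:max_shift) out[s + 1L] <- sum(probs[shift == s])
  out
}

# Per-atom distribution list for a molecule carrying j labeled N atoms.
molecule_atom_dists <- function(counts, j, purity, ab, mode) {
  dists <- list()
  add <- function(dists, d, n) c(dists, rep(list(d), n))
  dists <- add(dists, c(1 - purity, purity), j)              # labeled N
  dists <- add(dists, ab$N, counts[["N"]] - j)               # unlabeled N
  if (mode == "full") {
    for (el in c("C", "H", "O", "S")) {
      if (counts[[el]] > 0) dists <- add(dists, ab[[el]], counts[[el]])
    }
  }
  dists
}

# Fine-step explicit (Heun) integration of dx/dt = k (u(t) - x); independent
# of the package's closed-form and RK4 paths.
euler_enrichment <- function(u, times, k, x0, dt = 0.001) {
  out <- numeric(length(times))
  x <- x0
  t <- 0
  for (i in seq_along(times)) {
    while (t < times[i] - 1e-12) {
      h <- min(dt, times[i] - t)
      f1 <- k * (u(t) - x)
      f2 <- k * (u(t + h) - (x + h * f1))
      x <- x + h / 2 * (f1 + f2)
      t <- t + h
    }
    out[i] <- x
  }
  out
}

# Random valid metabolite formula with n_tracer nitrogens and a few light
# atoms (small enough for the enumeration oracle).
random_formula <- function(n_tracer = sample(1:3, 1)) {
  nc <- sample(0:3, 1)
  nh <- sample(0:3, 1)
  no <- sample(0:2, 1)
  ns <- sample(0:1, 1)
  paste0(
    if (nc > 0) paste0("C", nc) else "",
    if (nh > 0) paste0("H", nh) else "",
    "N", n_tracer,
    if (no > 0) paste0("O", no) else "",
    if (ns > 0) paste0("S", ns) else ""
  )
}

# Random point on the probability simplex.
random_simplex <- function(n) {
  x <- stats::rexp(n)
  x / sum(x)
}

# Minimal noise-free product time course for flux-fit tests.
make_product_tc <- function(input, v, M, times = c(0, 30, 60, 120)) {
  tibble::tibble(
    time_min = times,
    enrichment = simulate_enrichment(input, times, v, M),
    concentration = rep(M, length(times))
  )
}
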