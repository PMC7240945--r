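make_conc_table <- function(values_by_met, ranks = c("A", "B"), reps = 3) {
  grid <- tidyr::expand_grid(leaf_rank = ranks, replicate = seq_len(reps),
                             metabolite = names(values_by_met))
  grid$concentration <- unlist(lapply(seq_len(nrow(grid)), function(i) {
    v <- values_by_met[[grid$metabolite[i]]]
    v[(match(grid$leaf_rank[i], ranks) - 1) * reps + grid$replicate[i]]
  }))
  grid
}

test_that("filter_major applies the strict >threshold in >=half rule", {
  n <- 12
  tbl <- tibble::tibble(
    metabolite = rep(c("always2", "five_of_12", "exactly1"), each = n),
    concentration = c(rep(2, n),
                      c(rep(1.5, 5), rep(0.5, n - 5)),
                      rep(1, n))
  )
  expect_equal(filter_major(tbl), "always2")
})

test_that("filter_major is permutation-invariant and monotone in threshold", {
  set.seed(5)
  tbl <- tibble::tibble(
    metabolite = rep(letters[1:6], each = 10),
    concentration = stats::runif(60, 0, 3)
  )
  shuf <- tbl[sample(nrow(tbl)), ]
  expect_setequal(filter_major(tbl), filter_major(shuf))
  for (th in c(0.5, 1, 1.5, 2)) {
    expect_true(all(filter_major(tbl, threshold = th + 0.5) %in%
                      filter_major(tbl, threshold = th)))
  }
})

test_that("normality screen keeps normal draws and drops degenerate ones", {
  set.seed(101)
  keep_count <- 0L
  for (s in 1:20) {
    tbl <- tibble::tibble(metabolite = "m",
                          concentration = stats::rnorm(20, 5, 1))
    keep_count <- keep_count + ("m" %in% normality_screen(tbl))
  }
  expect_gte(keep_count, 18L) # ~1 - alpha of seeded normal draws retained
  two_point <- tibble::tibble(metabolite = "m",
                              concentration = rep(c(0, 10), 10))
  expect_equal(stats::shapiro.test(rep(c(0, 10), 10))$p.value < 0.05, TRUE)
  expect_length(normality_screen(two_point), 0L)
  constant <- tibble::tibble(metabolite = "m", concentration = rep(1, 10))
  expect_warning(out <- normality_screen(constant), "constant")
  expect_length(out, 0L)
})

test_that("PCA handles collinear and isotropic cases", {
  # two perfectly correlated metabolites -> one component, |loadings| = 1
  base <- c(1, 2, 3, 4, 5, 6)
  tbl <- make_conc_table(list(m1 = base, m2 = 2 * base + 1))
  expect_message(p <- run_pca(tbl), "rank-deficient")
  expect_equal(p$var_explained[1], 1, tolerance = 1e-10)
  expect_equal(abs(p$loadings_corr$PC1), c(1, 1), tolerance = 1e-10)
  # orthogonal standardized columns -> equal variance shares
  set.seed(2)
  # orthogonal to the intercept so centering keeps the columns orthogonal
  X <- qr.Q(qr(cbind(1, matrix(stats::rnorm(36), 12, 3))))[, 2:4]
  tbl3 <- tibble::tibble(
    leaf_rank = rep(c("A", "B"), each = 6)[rep(1:12, 3)],
    replicate = rep(rep(1:6, 2), 3),
    metabolite = rep(c("m1", "m2", "m3"), each = 12),
    concentration = as.numeric(X)
  )
  p3 <- run_pca(tbl3)
  expect_equal(p3$var_explained, rep(1 / 3, 3), tolerance = 1e-10)
})

test_that("correlation loadings match the definitional Pearson oracle", {
  set.seed(8)
  tbl <- tibble::tibble(
    leaf_rank = rep(c("A", "B", "C"), each = 4)[rep(1:12, 8)],
    replicate = rep(rep(1:4, 3), 8),
    metabolite = rep(paste0("m", 1:8), each = 12),
    concentration = stats::rnorm(96, 10, 2)
  )
  p <- run_pca(tbl)
  wide <- tidyr::pivot_wider(tbl, id_cols = c("leaf_rank", "replicate"),
                             names_from = "metabolite",
                             values_from = "concentration")
  for (m in paste0("m", 1:8)) {
    for (k in seq_along(p$var_explained)) {
      oracle <- stats::cor(wide[[m]], p$scores[[paste0("PC", k)]])
      got <- p$loadings_corr[p$loadings_corr$metabolite == m,
                             paste0("PC", k)][[1]]
      expect_equal(got, oracle, tolerance = 1e-10)
    }
  }
  # scores have diagonal covariance; variance shares match eigenvalues/trace
  S <- stats::cov(as.matrix(p$scores[, -(1:2)]))
  expect_equal(S - diag(diag(S)), matrix(0, nrow(S), ncol(S)),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(p$var_explained, diag(S) / sum(diag(S)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("ANOVA + Tukey separates far-apart groups and handles null cases", {
  d <- tibble::tibble(leaf_rank = rep(c("g1", "g2"), each = 3),
                      concentration = c(1, 2, 3, 101, 102, 103))
  cmp <- anova_tukey(d)
  # closed-form F: MSB = 3*50^2 * 2 / 1... compute from sums of squares
  ssb <- 3 * ((2 - 52)^2 + (102 - 52)^2)
  ssw <- sum((c(1, 2, 3) - 2)^2) + sum((c(101, 102, 103) - 102)^2)
  f_oracle <- (ssb / 1) / (ssw / 4)
  expect_equal(cmp$anova_F, f_oracle, tolerance = 1e-10)
  expect_lt(cmp$anova_p, 1e-6)
  expect_false(cmp$letters[["g1"]] == cmp$letters[["g2"]])
  # identical values: zero-variance path, one shared letter
  d0 <- tibble::tibble(leaf_rank = rep(c("g1", "g2"), each = 3),
                       concentration = 5)
  cmp0 <- anova_tukey(d0)
  expect_equal(unname(cmp0$letters), c("a", "a"))
})

test_that("two-group ANOVA F equals the squared pooled-variance t", {
  set.seed(12)
  for (rep_i in 1:10) {
    d <- tibble::tibble(leaf_rank = rep(c("a", "b"), each = 4),
                        concentration = stats::rnorm(8, 5, 1))
    cmp <- anova_tukey(d)
    tt <- stats::t.test(concentration ~ leaf_rank, data = d,
                        var.equal = TRUE)
    expect_equal(cmp$anova_F, unname(tt$statistic)^2, tolerance = 1e-10)
  }
})

test_that("Tukey letters are symmetric under group relabeling", {
  set.seed(33)
  vals <- c(stats::rnorm(3, 0), stats::rnorm(3, 0.2), stats::rnorm(3, 8),
            stats::rnorm(3, 8.4))
  d <- tibble::tibble(leaf_rank = rep(c("w", "x", "y", "z"), each = 3),
                      concentration = vals)
  cmp <- anova_tukey(d)
  relabel <- c(w = "z", x = "y", y = "x", z = "w")
  d2 <- dplyr::mutate(d, leaf_rank = unname(relabel[leaf_rank]))
  cmp2 <- anova_tukey(d2)
  for (g in c("w", "x", "y", "z")) {
    partners1 <- names(cmp$letters)[cmp$letters == cmp$letters[[g]]]
    partners2 <- names(cmp2$letters)[cmp2$letters == cmp2$letters[[relabel[[g]]]]]
    expect_setequal(unname(relabel[partners1]), partners2)
  }
})

test_that("compact letters encode exactly the non-significant pairs", {
  groups <- c("g1", "g2", "g3", "g4")
  sig <- matrix(FALSE, 4, 4, dimnames = list(groups, groups))
  # g1 != g3, g1 != g4, g2 != g4; all else shared
  for (pr in list(c(1, 3), c(1, 4), c(2, 4))) {
    sig[pr[1], pr[2]] <- sig[pr[2], pr[1]] <- TRUE
  }
  cld <- leafflux:::compact_letters(groups, sig)
  share <- function(a, b) {
    any(strsplit(cld[[a]], "")[[1]] %in% strsplit(cld[[b]], "")[[1]])
  }
  for (i in 1:3) {
    for (j in (i + 1):4) {
      expect_equal(share(groups[i], groups[j]), !sig[i, j],
                   label = paste(groups[i], groups[j]))
    }
  }
})

test_that("requested pairwise Student tests are reported", {
  set.seed(4)
  d <- tibble::tibble(
    leaf_rank = rep(c("L15", "L11", "L7", "L3"), each = 3),
    concentration = c(stats::rnorm(3, 10), stats::rnorm(3, 9),
                      stats::rnorm(3, 8), stats::rnorm(3, 7))
  )
  cmp <- anova_tukey(d, pairwise = list(c("L15", "L7"), c("L15", "L3")))
  expect_equal(cmp$pairwise_t$pair, c("L15-L7", "L15-L3"))
  tt <- stats::t.test(d$concentration[d$leaf_rank == "L15"],
                      d$concentration[d$leaf_rank == "L7"], var.equal = TRUE)
  expect_equal(cmp$pairwise_t$p[1], tt$p.value, tolerance = 1e-12)
})

test_that("group preconditions are enforced", {
  d <- tibble::tibble(leaf_rank = c("a", "a", "b"),
                      concentration = c(1, 2, 3))
  expect_error(anova_tukey(d), "< 2 replicates")
  d1 <- tibble::tibble(leaf_rank = "a", concentration = c(1, 2))
  expect_error(anova_tukey(d1), ">= 2 groups")
})

test_that("fingerprint_stats chains filter, screen, PCA and comparisons", {
  set.seed(21)
  ranks <- c("L15", "L11", "L7", "L3")
  mets <- list(big1 = 10, big2 = 5, small = 0.2)
  tbl <- tidyr::expand_grid(leaf_rank = ranks, replicate = 1:5,
                            metabolite = names(mets))
  tbl$concentration <- vapply(seq_len(nrow(tbl)), function(i) {
    base <- mets[[tbl$metabolite[i]]]
    shift <- match(tbl$leaf_rank[i], ranks) * 0.3
    stats::rnorm(1, base + shift, 0.5 * base + 0.05)
  }, numeric(1))
  tbl$concentration <- abs(tbl$concentration)
  fs <- fingerprint_stats(tbl)
  expect_setequal(fs$major, c("big1", "big2"))
  expect_true(all(fs$normal %in% fs$major))
  expect_equal(sort(unique(fs$comparisons$metabolite)), c("big1", "big2"))
  if (!is.null(fs$pca)) {
    expect_equal(sum(fs$pca$var_explained), 1, tolerance = 1e-10)
  }
})
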