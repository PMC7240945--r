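#' Filter metabolites found in major quantities
#'
#' Retains metabolites whose concentration strictly exceeds `threshold` in at
#' least `min_fraction` of the samples — the abundance rule used to focus the
#' analysis on major free amino acids (> 1 µmol g-1 DW in at least half of
#' the samples).
#'
#' @param data Long tibble with columns `metabolite` and `concentration`
#'   (one row per sample x metabolite).
#' @param threshold Concentration threshold, µmol g-1 DW; default 1.
#' @param min_fraction Minimum fraction of samples above threshold; default
#'   0.5.
#' @return Character vector of retained metabolite names.
#' @export
#' @examples
#' tbl <- tidyr::expand_grid(sample = 1:4, metabolite = c("A", "B"))
#' tbl$concentration <- c(2, 0.5, 2, 0.5, 2, 0.5, 2, 0.5)
#' filter_major(tbl)
filter_major <- function(data, threshold = 1, min_fraction = 0.5) {
  stopifnot(nrow(data) > 0,
            all(c("metabolite", "concentration") %in% names(data)))
  data |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(frac = mean(.data$concentration > threshold),
                     .groups = "drop") |>
    dplyr::filter(.data$frac >= min_fraction) |>
    dplyr::pull("metabolite")
}

#' Screen metabolites for normally distributed values
#'
#' Shapiro-Wilk test per metabolite; metabolites whose values are not
#' rejected at `alpha` are retained (they "show a normal distribution of
#' their values" and enter the PCA). Constant columns are excluded with a
#' warning.
#'
#' @param data Long tibble with columns `metabolite` and `concentration`.
#' @param alpha Test level; default 0.05.
#' @return Character vector of retained metabolite names. The test name and
#'   level are attached as attributes `method` and `alpha` so exclusion lists
#'   are auditable.
#' @export
normality_screen <- function(data, alpha = 0.05) {
  stopifnot(all(c("metabolite", "concentration") %in% names(data)))
  res <- data |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(
      n = dplyr::n(),
      constant = diff(range(.data$concentration)) == 0,
      p = if (dplyr::n() < 3L || diff(range(.data$concentration)) == 0) {
        NA_real_
      } else {
        stats::shapiro.test(.data$concentration)$p.value
      },
      .groups = "drop"
    )
  if (any(res$n < 3L)) {
    stop("need >= 3 values per metabolite for the normality screen",
         call. = FALSE)
  }
  if (any(res$constant)) {
    warning("excluding constant metabolite(s): ",
            paste(res$metabolite[res$constant], collapse = ", "),
            call. = FALSE)
  }
  kept <- res$metabolite[!res$constant & res$p >= alpha]
  structure(kept, method = "shapiro.test", alpha = alpha)
}

#' Principal component analysis of an amino-acid concentration table
#'
#' PCA on unit-variance-standardized concentrations (correlation form), with
#' loadings reported as Pearson correlations between each metabolite's values
#' and the component scores — the representation used for fingerprint loading
#' plots.
#'
#' @param data Long tibble with columns `leaf_rank`, `replicate`,
#'   `metabolite`, `concentration`, one value per sample x metabolite.
#' @param metabolites Metabolites to include (e.g. the output of
#'   [normality_screen()]); default all.
#' @return Object of class `pca_fingerprint`: list with `scores` (tibble:
#'   `leaf_rank`, `replicate`, `PC1`, ...), `loadings_corr` (tibble:
#'   `metabolite` x components), `var_explained`, `included`.
#' @export
run_pca <- function(data, metabolites = NULL) {
  stopifnot(all(c("leaf_rank", "replicate", "metabolite", "concentration")
                %in% names(data)))
  if (is.null(metabolites)) metabolites <- unique(data$metabolite)
  if (length(metabolites) < 2L) stop("need >= 2 metabolites", call. = FALSE)
  wide <- data |>
    dplyr::filter(.data$metabolite %in% metabolites) |>
    tidyr::pivot_wider(id_cols = c("leaf_rank", "replicate"),
                       names_from = "metabolite",
                       values_from = "concentration")
  if (nrow(wide) < 3L) stop("need >= 3 samples", call. = FALSE)
  X <- as.matrix(wide[, metabolites, drop = FALSE])
  if (anyNA(X)) stop("concentration table has missing cells", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant metabolite column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  eig <- pc$sdev^2
  keep <- eig > 1e-12 * eig[1]
  if (!all(keep)) {
    message("rank-deficient table: returning ", sum(keep), " component(s)")
  }
  scores <- pc$x[, keep, drop = FALSE]
  loadings_corr <- suppressWarnings(stats::cor(X, scores))
  loadings_corr[!is.finite(loadings_corr)] <- 0
  structure(
    list(
      scores = dplyr::bind_cols(wide[c("leaf_rank", "replicate")],
                                tibble::as_tibble(scores)),
      loadings_corr = dplyr::bind_cols(
        tibble::tibble(metabolite = colnames(X)),
        tibble::as_tibble(loadings_corr)),
      var_explained = eig[keep] / sum(eig),
      included = metabolites
    ),
    class = "pca_fingerprint"
  )
}

#' @export
print.pca_fingerprint <- function(x, ...) {
  cat("<pca_fingerprint> ", length(x$included), " metabolites, ",
      nrow(x$scores), " samples\n  variance explained: ",
      paste0(round(100 * x$var_explained[seq_len(min(3, length(x$var_explained)))], 1),
             "%", collapse = ", "), " ...\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pca_fingerprint <- function(x, ...) {
  tidyr::pivot_longer(x$loadings_corr, -"metabolite",
                      names_to = "component", values_to = "correlation")
}

#' @exportS3Method generics::glance
glance.pca_fingerprint <- function(x, ...) {
  tibble::tibble(
    n_metabolites = length(x$included),
    n_samples = nrow(x$scores),
    var_pc1 = x$var_explained[1],
    var_pc2 = if (length(x$var_explained) >= 2) x$var_explained[2] else NA_real_
  )
}

#' 95% confidence ellipse for one group's scores
#'
#' Returns the 2-D normal-quantile ellipse outline for a group of samples in
#' a score plane; used by the score-plot method, exported for custom plots.
#'
#' @param xy Two-column matrix of scores.
#' @param level Confidence level; default 0.95.
#' @param n_points Points on the outline.
#' @return Tibble with columns `x`, `y`.
#' @export
score_ellipse <- function(xy, level = 0.95, n_points = 100) {
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  ctr <- colMeans(xy)
  S <- stats::cov(xy)
  r <- sqrt(stats::qchisq(level, df = 2))
  theta <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(cos(theta), sin(theta))
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  pts <- r * circ %*% diag(sqrt(lam), 2) %*% t(ev$vectors)
  tibble::tibble(x = pts[, 1] + ctr[1], y = pts[, 2] + ctr[2])
}

# Compact letter display by insert-and-absorb over the significant-pair set.
# groups: character vector in display order; sig: logical matrix (TRUE where
# the pair differs significantly).
compact_letters <- function(groups, sig) {
  m <- length(groups)
  cols <- list(rep(TRUE, m)) # start: one letter containing every group
  for (i in seq_len(m - 1)) {
    for (j in seq((i + 1), m)) {
      if (!sig[i, j]) next
      new_cols <- list()
      changed <- FALSE
      for (col in cols) {
        if (col[i] && col[j]) {
          a <- col; a[i] <- FALSE
          b <- col; b[j] <- FALSE
          new_cols <- c(new_cols, list(a, b))
          changed <- TRUE
        } else {
          new_cols <- c(new_cols, list(col))
        }
      }
      cols <- new_cols
      if (changed) {
        # absorb columns that are subsets of another
        keep <- rep(TRUE, length(cols))
        for (p in seq_along(cols)) {
          for (q in seq_along(cols)) {
            if (p != q && keep[p] && keep[q] &&
                all(cols[[p]] <= cols[[q]]) && any(cols[[p]] < cols[[q]])) {
              keep[p] <- FALSE
            }
          }
        }
        # drop duplicates
        sig_cols <- cols[keep]
        sig_key <- vapply(sig_cols, paste, character(1), collapse = "")
        cols <- sig_cols[!duplicated(sig_key)]
      }
    }
  }
  # order letters by first member group
  first <- vapply(cols, function(col) which(col)[1], integer(1))
  cols <- cols[order(first)]
  letters_out <- vapply(seq_len(m), function(g) {
    paste(letters[which(vapply(cols, function(col) col[g], logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(letters_out, groups)
}

#' One-way ANOVA with Tukey HSD letters and optional Student tests
#'
#' Compares one metabolite's values across leaf-rank groups: one-way ANOVA F
#' test, all-pairs Tukey HSD on the studentized-range distribution, a compact
#' letter display (groups sharing a letter are not significantly different at
#' `alpha`), and — when requested — pairwise two-sample Student t tests, as
#' used for follow-up contrasts when the ANOVA is borderline.
#'
#' @param data Long tibble with columns `leaf_rank` and a value column.
#' @param metabolite Optional metabolite name to filter on (requires a
#'   `metabolite` column) and to record in the result.
#' @param value Name of the value column; default `"concentration"`.
#' @param alpha Significance level; default 0.05.
#' @param pairwise Optional list of 2-vectors of group labels for Student
#'   tests, e.g. `list(c("L15", "L7"), c("L15", "L3"))`.
#' @return Object of class `group_comparison`: list with `metabolite`,
#'   `anova_F`, `anova_p`, `letters` (named by group), `tukey` (tibble of
#'   pairs) and `pairwise_t` (tibble or NULL).
#' @export
#' @examples
#' d <- tibble::tibble(leaf_rank = rep(c("A", "B"), each = 3),
#'                     concentration = c(1, 2, 3, 101, 102, 103))
#' anova_tukey(d)
anova_tukey <- function(data, metabolite = NULL, value = "concentration",
                        alpha = 0.05, pairwise = NULL) {
  stopifnot("leaf_rank" %in% names(data), value %in% names(data))
  if (!is.null(metabolite) && "metabolite" %in% names(data)) {
    data <- dplyr::filter(data, .data$metabolite == !!metabolite)
  }
  y <- data[[value]]
  g <- factor(data$leaf_rank, levels = unique(data$leaf_rank))
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("group(s) with < 2 replicates: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  groups <- levels(g)
  m <- length(groups)
  if (diff(range(y)) == 0) {
    # degenerate zero-variance path: nothing distinguishes the groups
    return(structure(
      list(metabolite = metabolite, anova_F = NA_real_, anova_p = NA_real_,
           letters = stats::setNames(rep("a", m), groups),
           tukey = tibble::tibble(pair = character(), diff = numeric(),
                                  p_adj = numeric()),
           pairwise_t = NULL, alpha = alpha),
      class = "group_comparison"))
  }
  fit <- stats::aov(y ~ g)
  an <- summary(fit)[[1]]
  anova_F <- an[["F value"]][1]
  anova_p <- an[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- rownames(tk)
  tukey <- tibble::tibble(pair = pairs, diff = tk[, "diff"],
                          p_adj = tk[, "p adj"])
  sig <- matrix(FALSE, m, m, dimnames = list(groups, groups))
  for (r in seq_along(pairs)) {
    ab <- strsplit(pairs[r], "-", fixed = TRUE)[[1]]
    if (tukey$p_adj[r] < alpha) {
      sig[ab[1], ab[2]] <- TRUE
      sig[ab[2], ab[1]] <- TRUE
    }
  }
  letters_cld <- compact_letters(groups, sig)
  pw <- NULL
  if (!is.null(pairwise)) {
    pw <- purrr::map_dfr(pairwise, function(pr) {
      tt <- stats::t.test(y[g == pr[1]], y[g == pr[2]], var.equal = TRUE)
      tibble::tibble(pair = paste(pr, collapse = "-"),
                     t = unname(tt$statistic), p = tt$p.value)
    })
  }
  structure(
    list(metabolite = metabolite, anova_F = anova_F, anova_p = anova_p,
         letters = letters_cld, tukey = tukey, pairwise_t = pw,
         alpha = alpha),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>",
      if (!is.null(x$metabolite)) paste0(" ", x$metabolite), "\n",
      "  ANOVA F = ", signif(x$anova_F, 5), ", p = ", signif(x$anova_p, 4),
      "\n  letters: ",
      paste(names(x$letters), x$letters, sep = ": ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    metabolite = x$metabolite %||% NA_character_,
    leaf_rank = names(x$letters),
    letter = unname(x$letters),
    anova_F = x$anova_F,
    anova_p = x$anova_p
  )
}

#' Fingerprint statistics for a concentration table
#'
#' Convenience wrapper chaining the fingerprint steps on a long concentration
#' table (typically the t = 0 samples): abundance filter, normality screen,
#' PCA on the retained metabolites, and per-metabolite ANOVA + Tukey letters
#' on the major metabolites.
#'
#' @param data Long tibble with columns `leaf_rank`, `replicate`,
#'   `metabolite`, `concentration`.
#' @param threshold,min_fraction Passed to [filter_major()].
#' @param alpha Level for the normality screen and group tests.
#' @return List with `major` (metabolites kept by the abundance filter),
#'   `normal` (metabolites passing the normality screen among the major
#'   ones), `pca` (a `pca_fingerprint` or NULL), and `comparisons` (tibble of
#'   tidied ANOVA/Tukey results per major metabolite).
#' @export
fingerprint_stats <- function(data, threshold = 1, min_fraction = 0.5,
                              alpha = 0.05) {
  major <- filter_major(data, threshold, min_fraction)
  d_major <- dplyr::filter(data, .data$metabolite %in% major)
  normal <- tryCatch(normality_screen(d_major, alpha),
                     warning = function(w) {
                       suppressWarnings(normality_screen(d_major, alpha))
                     })
  pca <- if (length(normal) >= 2L) run_pca(d_major, normal) else NULL
  sizes <- table(unique(data[c("leaf_rank", "replicate")])$leaf_rank)
  comparisons <- if (length(sizes) >= 2L && all(sizes >= 2L)) {
    purrr::map_dfr(major, function(met) {
      tidy(anova_tukey(d_major, metabolite = met, alpha = alpha))
    })
  } else {
    tibble::tibble() # group tests need >= 2 ranks with >= 2 replicates
  }
  list(major = major, normal = as.character(normal), pca = pca,
       comparisons = comparisons)
}
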