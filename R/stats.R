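#' Distribution-gated two-group comparison
#'
#' The study's statistical workhorse: each metric is compared between
#' genotypes with an independent two-sample test chosen by a distribution
#' gate. Both groups are checked for normality (Shapiro-Wilk) and the pair
#' for equal variances (Brown-Forsythe/Levene, median-centred); when all
#' three p-values exceed `alpha_gate` a pooled-variance two-sided t-test is
#' used, otherwise a two-sided Mann-Whitney (Wilcoxon rank-sum) test with
#' mid-rank ties, exact when the combined sample size is at most 20 and
#' there are no ties. A constant group counts as non-normal. The gate
#' diagnostics are reported alongside the result so every test choice is
#' auditable.
#'
#' @param x,y Numeric samples for the two groups (each n >= 3).
#' @param alpha_gate Gate level for the normality/variance checks.
#' @param method `"auto"` applies the gate; `"t"`, `"wilcoxon"` or
#'   `"kruskal"` force that test (Kruskal-Wallis on two groups is offered
#'   as an alternative rank test only).
#' @param metric Optional metric id carried into the result.
#' @return One-row tibble of class `group_comparison`: `metric`,
#'   `test_used`, `statistic`, `p`, `n_x`, `n_y`, `normality_p_x`,
#'   `normality_p_y`, `variance_p`.
#' @examples
#' gated_two_group_test(rnorm(9), rnorm(5) + 2)
#' @export
gated_two_group_test <- function(x, y, alpha_gate = 0.05,
                                 method = c("auto", "t", "wilcoxon", "kruskal"),
                                 metric = NA_character_) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    stop("each group needs at least 3 values (gate undefined below that)",
         call. = FALSE)
  }
  shapiro_p <- function(v) {
    if (stats::sd(v) == 0) return(0)     # constant: certainly not normal
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }
  np_x <- shapiro_p(x)
  np_y <- shapiro_p(y)
  vp <- tryCatch({
    g <- factor(rep(c("x", "y"), c(length(x), length(y))))
    car::leveneTest(c(x, y) ~ g, center = stats::median)[1, "Pr(>F)"]
  }, error = function(e) 0)

  use_t <- np_x > alpha_gate && np_y > alpha_gate && vp > alpha_gate
  test <- switch(method,
    auto = if (use_t) "t-test" else "Mann-Whitney",
    t = "t-test", wilcoxon = "Mann-Whitney", kruskal = "Kruskal-Wallis")

  res <- switch(test,
    "t-test" = {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      list(stat = unname(tt$statistic), p = tt$p.value)
    },
    "Mann-Whitney" = {
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = length(x) + length(y) <= 20,
                           correct = TRUE))
      list(stat = unname(wt$statistic), p = wt$p.value)
    },
    "Kruskal-Wallis" = {
      kt <- stats::kruskal.test(list(x, y))
      list(stat = unname(kt$statistic), p = kt$p.value)
    })

  out <- tibble::tibble(
    metric = metric, test_used = test, statistic = res$stat, p = res$p,
    n_x = length(x), n_y = length(y),
    normality_p_x = np_x, normality_p_y = np_y, variance_p = vp
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' Bonferroni correction
#'
#' Multiplies each p-value by the family size `m` and clips at 1. `m`
#' defaults to the number of p-values but may be larger (a family with
#' tests reported elsewhere); it may not be smaller.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param m Family size.
#' @return Adjusted p-values, same length as `p`.
#' @examples
#' bonferroni(c(0.01, 0.2))
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]", call. = FALSE)
  if (m < length(p)) stop("family size m cannot be smaller than the number of p-values", call. = FALSE)
  pmin(1, m * p)
}

#' Chi-square test of a genotype-by-sex table
#'
#' Pearson chi-square without continuity correction on a 2x2 count table
#' (1 degree of freedom), as used to check that the sexes are balanced
#' across genotypes.
#'
#' @param counts 2x2 matrix of nonnegative integer counts
#'   (genotype x sex).
#' @return One-row tibble `test_used`, `statistic`, `p`.
#' @examples
#' sex_ratio_test(matrix(c(5, 5, 6, 7), nrow = 2))
#' @export
sex_ratio_test <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero marginal in the 2x2 table", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  out <- tibble::tibble(metric = "sex_ratio", test_used = "chi-square",
                        statistic = unname(ct$statistic), p = ct$p.value)
  class(out) <- c("group_comparison", class(out))
  out
}

#' Run the full genotype comparison suite
#'
#' One gated two-group test per metric: every architecture metric
#' (total time, percent of total sleep time, bout count, mean bout
#' duration) per state, every mean normalized band power per state, site
#' and band, and the REM theta peak frequency per site. Bonferroni
#' families follow the figure-panel structure: one family per architecture
#' metric (across states), one family per state for the band powers
#' (bands x sites), and one family for the theta peaks.
#'
#' @param arch Long architecture table from [cohort_table()].
#' @param band_summary Optional per-animal band summaries: a tibble with
#'   columns `animal`, `genotype`, `state`, `role`, `band`,
#'   `mean_norm_power` (stacked [state_band_summary()] results).
#' @param theta_peaks Optional tibble `animal`, `genotype`, `role`,
#'   `peak_hz`.
#' @param alpha Significance level reported in the `significant` column
#'   (applied to the Bonferroni-adjusted p).
#' @param method Passed to [gated_two_group_test()].
#' @return Tibble of class `comparison_suite`: `family`, `metric`,
#'   `state`, `role`, `band`, `test_used`, `statistic`, `p`, `p_adj`,
#'   `significant`, `direction` (sign of mutant minus wild-type median),
#'   group sizes and gate diagnostics.
#' @export
run_comparison_suite <- function(arch, band_summary = NULL,
                                 theta_peaks = NULL, alpha = 0.05,
                                 method = "auto") {
  pieces <- list()
  if (!is.null(arch)) {
    need <- c("animal", "genotype", "state", "metric", "value")
    miss <- setdiff(need, names(arch))
    if (length(miss)) stop("architecture table lacks column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    pieces$arch <- arch |>
      dplyr::mutate(family = .data$metric, role = NA_character_,
                    band = NA_character_)
  }
  if (!is.null(band_summary)) {
    need <- c("animal", "genotype", "state", "role", "band", "mean_norm_power")
    miss <- setdiff(need, names(band_summary))
    if (length(miss)) stop("band summary lacks column(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    pieces$bands <- band_summary |>
      dplyr::mutate(metric = "mean_norm_power",
                    family = paste0("power_", .data$state),
                    value = .data$mean_norm_power) |>
      dplyr::select(-"mean_norm_power")
  }
  if (!is.null(theta_peaks)) {
    pieces$theta <- theta_peaks |>
      dplyr::mutate(metric = "theta_peak_hz", family = "theta_peak",
                    state = "REM", band = "theta", value = .data$peak_hz) |>
      dplyr::select(-"peak_hz")
  }
  long <- dplyr::bind_rows(pieces)
  if (!nrow(long)) stop("nothing to compare", call. = FALSE)

  one <- function(d) {
    wt <- d$value[d$genotype == "WT"]
    mut <- d$value[d$genotype == "MUT"]
    if (sum(is.finite(wt)) < 3 || sum(is.finite(mut)) < 3) {
      return(tibble::tibble())
    }
    gc <- gated_two_group_test(wt, mut, method = method)
    gc$metric <- NULL                  # carried by the grouping keys
    gc$direction <- sign(stats::median(mut, na.rm = TRUE) -
                           stats::median(wt, na.rm = TRUE))
    tibble::as_tibble(gc)
  }
  out <- long |>
    dplyr::group_by(.data$family, .data$metric, .data$state, .data$role,
                    .data$band) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
  if (!nrow(out) || !"p" %in% names(out)) {
    stop("no metric had at least 3 animals per genotype", call. = FALSE)
  }
  out <- out |>
    dplyr::filter(!is.na(.data$p)) |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_adj = bonferroni(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_adj < alpha)
  class(out) <- c("comparison_suite", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' @export
tidy.comparison_suite <- function(x, ...) {
  tibble::as_tibble(x)[, c("family", "metric", "state", "role", "band",
                           "test_used", "statistic", "p", "p_adj",
                           "direction", "significant", "n_x", "n_y")]
}

#' @export
glance.comparison_suite <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_families = dplyr::n_distinct(x$family),
    n_significant = sum(x$significant),
    alpha = attr(x, "alpha") %||% 0.05
  )
}

#' @export
tidy.group_comparison <- function(x, ...) tibble::as_tibble(x)
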