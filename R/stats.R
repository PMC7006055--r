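#' Standard error of the mean
#'
#' Sample standard deviation divided by the square root of the sample size.
#'
#' @param x Numeric vector (NAs dropped).
#' @return SEM.
#' @export
sem <- function(x) {
  x <- x[!is.na(x)]
  stats::sd(x) / sqrt(length(x))
}

iqr_outliers <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
}

#' Two-group comparison with an independent-samples t-test
#'
#' The standard group comparison of the analysis pipeline: a classic
#' equal-variance independent two-sample t-test (Welch's correction
#' available via `var_equal = FALSE`), reported with group means and SEMs.
#' Normality of each group is screened (Shapiro-Wilk) and reported, never
#' auto-switched on; outliers beyond 1.5 IQR from the quartiles are flagged
#' but retained. No multiple-testing correction is applied by default.
#'
#' @param values_a,values_b Numeric vectors, n >= 2 per group.
#' @param metric_name Label carried into the result.
#' @param var_equal Pool variances (classic Student test; default `TRUE`).
#' @param alpha Significance level (default 0.05, two-sided).
#' @param screen Run normality screening and outlier flagging (default
#'   `TRUE`).
#' @return A `group_comparison` list: `metric`, `mean_a`, `mean_b`, `sem_a`,
#'   `sem_b`, `n_a`, `n_b`, `t`, `df`, `p`, `significant`,
#'   `normality_p_a/b`, `outliers_a/b` (logical flags).
#' @export
compare_groups <- function(values_a, values_b, metric_name = "",
                           var_equal = TRUE, alpha = 0.05, screen = TRUE) {
  values_a <- values_a[!is.na(values_a)]
  values_b <- values_b[!is.na(values_b)]
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  norm_p <- function(x) {
    if (!screen || length(x) < 3 || stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }
  structure(list(metric = metric_name,
                 mean_a = mean(values_a), mean_b = mean(values_b),
                 sem_a = sem(values_a), sem_b = sem(values_b),
                 n_a = length(values_a), n_b = length(values_b),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value,
                 significant = tt$p.value <= alpha,
                 normality_p_a = norm_p(values_a),
                 normality_p_b = norm_p(values_b),
                 outliers_a = if (screen) iqr_outliers(values_a) else NULL,
                 outliers_b = if (screen) iqr_outliers(values_b) else NULL),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %.3f +/- %.3f (n=%d) vs %.3f +/- %.3f (n=%d); t=%.3f, p=%.4g%s\n",
              if (nzchar(x$metric)) x$metric else "comparison",
              x$mean_a, x$sem_a, x$n_a, x$mean_b, x$sem_b, x$n_b,
              x$t, x$p, if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-way ANOVA for bilateral morphometric measurements
#'
#' Genotype-by-side analysis of variance with interaction, using type-II
#' sums of squares (equivalent to the sequential decomposition in the
#' balanced layouts these experiments use). Bilateral structures contribute
#' a left and a right measurement per animal, so side enters as a second
#' factor.
#'
#' @param values Numeric measurements (e.g. landmark distances, mm).
#' @param genotype Factor (or coercible), 2+ levels.
#' @param side Factor (or coercible), e.g. left/right.
#' @return An `anova_result` with a `table` data.frame (rows `genotype`,
#'   `side`, `interaction`; columns `F`, `p`, `df`) and the fitted `model`.
#' @export
two_way_anova <- function(values, genotype, side) {
  genotype <- factor(genotype); side <- factor(side)
  if (length(values) != length(genotype) || length(values) != length(side)) {
    stop("values, genotype and side must have equal length", call. = FALSE)
  }
  cell_n <- table(genotype, side)
  if (any(cell_n == 0)) stop("empty genotype x side cell", call. = FALSE)
  if (any(cell_n < 2)) {
    stop("each genotype x side cell needs at least 2 observations", call. = FALSE)
  }
  df <- data.frame(value = values, genotype = genotype, side = side)
  fit <- stats::lm(value ~ genotype * side, data = df)
  aov2 <- car::Anova(fit, type = 2)
  rows <- c("genotype", "side", "genotype:side")
  tab <- data.frame(term = c("genotype", "side", "interaction"),
                    F = aov2[rows, "F value"],
                    p = aov2[rows, "Pr(>F)"],
                    df = aov2[rows, "Df"])
  structure(list(table = tab, model = fit), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Tidy group-comparison table across metrics
#'
#' Runs [compare_groups()] for every metric column of a per-mouse data.frame
#' against a two-level group factor and returns one tidy row per metric:
#' `metric`, `<A>_mean`, `<A>_sem`, `<B>_mean`, `<B>_sem`, `t`, `p`,
#' `significant`. Group labels are kept in a separate column (merged only at
#' this stage), mirroring a blinded workflow where genotypes are attached
#' after all measurements are collected.
#'
#' @param data Data.frame, one row per mouse.
#' @param group Name of the two-level grouping column in `data`.
#' @param metrics Character vector of metric column names; default all
#'   numeric columns except `group`.
#' @param ... Passed to [compare_groups()] (e.g. `var_equal`).
#' @return Data.frame, one row per metric.
#' @export
group_metrics_table <- function(data, group, metrics = NULL, ...) {
  g <- factor(data[[group]])
  if (nlevels(g) != 2) stop("group must have exactly two levels", call. = FALSE)
  if (is.null(metrics)) {
    metrics <- names(data)[vapply(data, is.numeric, logical(1))]
    metrics <- setdiff(metrics, group)
  }
  lv <- levels(g)
  rows <- lapply(metrics, function(m) {
    cmp <- compare_groups(data[[m]][g == lv[1]], data[[m]][g == lv[2]],
                          metric_name = m, screen = FALSE, ...)
    out <- data.frame(metric = m,
                      a_mean = cmp$mean_a, a_sem = cmp$sem_a,
                      b_mean = cmp$mean_b, b_sem = cmp$sem_b,
                      t = cmp$t, p = cmp$p, significant = cmp$significant)
    names(out)[2:5] <- c(paste0(lv[1], c("_mean", "_sem")),
                         paste0(lv[2], c("_mean", "_sem")))
    out
  })
  do.call(rbind, rows)
}
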