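#' Welch's two-sample t-test on per-cell lifetimes
#'
#' Two-sided, unpaired t-test with Welch--Satterthwaite degrees of freedom
#' (robust to unequal group variances), as used to compare donor-only and
#' donor+acceptor lifetime distributions.
#'
#' @param a,b Numeric vectors (each `n >= 2`, non-degenerate variance in at
#'   least one group).
#' @return A `comparison_result`: `kind = "welch_t"`, `statistic` (t),
#'   `df` (Welch--Satterthwaite), `p` (two-sided), `mean_diff`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("welch_t_test: each group needs n >= 2", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(structure(list(kind = "welch_t", statistic = 0,
                            df = length(a) + length(b) - 2, p = 1,
                            mean_diff = 0),
                       class = "comparison_result"))
    stop("welch_t_test: both groups have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(
    list(kind = "welch_t", statistic = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value,
         mean_diff = mean(a) - mean(b)),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  if (x$kind == "welch_t") {
    cat(sprintf("<comparison_result> Welch t = %.4g, df = %.4g, p = %.4g\n",
                x$statistic, x$df, x$p))
  } else {
    cat(sprintf("<comparison_result> one-way ANOVA F = %.4g (df %d, %d), p = %.4g\n",
                x$statistic, x$df1, x$df2, x$p))
    tab <- data.frame(comparison = names(x$p_adjusted),
                      t = x$t_statistics, p_adjusted = x$p_adjusted)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Simulate the Dunnett max-|t| null distribution
#'
#' Draws from the joint null of the treatment-vs-control t statistics that
#' share the pooled variance estimate: `t_i = (Z_i/sqrt(n_i) -
#' Z_c/sqrt(n_c)) / (S sqrt(1/n_i + 1/n_c))` with independent standard
#' normal group means and `S^2 ~ chi^2_df / df`, `df = N - k`. Returns the
#' per-replicate maximum of `|t_i|`, the reference distribution for
#' Dunnett-adjusted per-comparison p-values. Precompute once and pass to
#' [oneway_anova_dunnett()] when running many experiments with identical
#' group sizes.
#'
#' @param n_per_group Integer vector of group sizes.
#' @param control_index Which group is the control.
#' @param n_sim Number of null replicates (default 1e5).
#' @param seed Seed.
#' @return Numeric vector of length `n_sim` (max |t| per replicate).
#' @export
dunnett_null_maxt <- function(n_per_group, control_index = 1L, n_sim = 1e5,
                              seed = 1L) {
  k <- length(n_per_group)
  if (k < 2) stop("dunnett_null_maxt: need >= 2 groups", call. = FALSE)
  df <- sum(n_per_group) - k
  restore <- local_seed(seed)
  on.exit(restore(), add = TRUE)
  z <- matrix(stats::rnorm(n_sim * k), n_sim, k)
  s <- sqrt(stats::rchisq(n_sim, df) / df)
  others <- setdiff(seq_len(k), control_index)
  nc <- n_per_group[control_index]
  maxt <- rep(0, n_sim)
  for (i in others) {
    ni <- n_per_group[i]
    ti <- (z[, i] / sqrt(ni) - z[, control_index] / sqrt(nc)) /
      (s * sqrt(1 / ni + 1 / nc))
    maxt <- pmax(maxt, abs(ti))
  }
  maxt
}

#' One-way ANOVA with Dunnett comparisons to a control
#'
#' Fits an ordinary one-way ANOVA across all groups (via [stats::aov()]),
#' then compares each treatment group with the designated control using
#' pooled-variance t statistics whose per-comparison p-values are adjusted
#' for multiplicity against a simulated max-|t| null (family-wise control
#' in the Dunnett style). With `method = "bonferroni"` the adjusted values
#' are plain Bonferroni instead.
#'
#' @param groups Non-empty list (>= 2) of numeric vectors, each `n >= 2`.
#' @param control_index Index of the control group in `groups`.
#' @param method `"dunnett"` (simulation-adjusted, default) or `"bonferroni"`.
#' @param n_sim Null replicates for the Dunnett simulation.
#' @param seed Seed for the simulation.
#' @param null_maxt Optional precomputed [dunnett_null_maxt()] sample for
#'   these group sizes (overrides `n_sim`/`seed`).
#' @return A `comparison_result`: `kind = "anova_dunnett"`, ANOVA
#'   `statistic` (F), `df1`, `df2`, `p`, plus `t_statistics` and
#'   `p_adjusted` (named by comparison) and `df_error`.
#' @export
oneway_anova_dunnett <- function(groups, control_index = 1L,
                                 method = c("dunnett", "bonferroni"),
                                 n_sim = 1e5, seed = 1L, null_maxt = NULL) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2)
    stop("oneway_anova_dunnett: need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 0L) < 2))
    stop("oneway_anova_dunnett: every group needs n >= 2", call. = FALSE)
  if (control_index < 1 || control_index > length(groups))
    stop("oneway_anova_dunnett: 'control_index' out of range", call. = FALSE)
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  labels <- names(groups)
  if (is.null(labels)) labels <- paste0("group", seq_len(k))

  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(labels, n), levels = labels)
  df_err <- length(y) - k
  if (stats::var(y) == 0) {  # literally identical data: F is exactly 0
    Fstat <- 0; pF <- 1; ms_err <- 0
  } else {
    an <- summary(stats::aov(y ~ g))[[1]]
    Fstat <- an[["F value"]][1]
    pF <- an[["Pr(>F)"]][1]
    ms_err <- an[["Mean Sq"]][2]
    if (!is.finite(ms_err) || ms_err <= 0)
      stop("oneway_anova_dunnett: degenerate within-group variance", call. = FALSE)
  }

  means <- vapply(groups, mean, 0)
  others <- setdiff(seq_len(k), control_index)
  se <- sqrt(ms_err * (1 / n[others] + 1 / n[control_index]))
  tstat <- (means[others] - means[control_index]) / ifelse(se > 0, se, Inf)
  tstat[!is.finite(tstat)] <- 0
  names(tstat) <- sprintf("%s - %s", labels[others], labels[control_index])

  if (method == "dunnett") {
    if (is.null(null_maxt))
      null_maxt <- dunnett_null_maxt(n, control_index, n_sim = n_sim, seed = seed)
    p_adj <- vapply(abs(tstat), function(t0) mean(null_maxt >= t0), 0)
  } else {
    p_raw <- 2 * stats::pt(-abs(tstat), df_err)
    p_adj <- pmin(1, length(others) * p_raw)
  }
  names(p_adj) <- names(tstat)

  structure(
    list(kind = "anova_dunnett", statistic = Fstat,
         df1 = k - 1L, df2 = df_err, p = pF,
         t_statistics = tstat, p_adjusted = p_adj,
         df_error = df_err, method = method),
    class = "comparison_result"
  )
}

#' Group mean with a 95% confidence interval
#'
#' `mean +/- t_{0.975, n-1} * sd / sqrt(n)`, the per-group summary overlaid
#' on lifetime scatter plots.
#'
#' @param values Numeric vector, `n >= 2`.
#' @param label Optional group label.
#' @return A `group_result`: `label`, `values`, `n`, `mean`,
#'   `ci95_half_width`.
#' @export
group_ci95 <- function(values, label = NA_character_) {
  n <- length(values)
  if (n < 2) stop("group_ci95: need n >= 2", call. = FALSE)
  hw <- stats::qt(0.975, n - 1) * stats::sd(values) / sqrt(n)
  structure(
    list(label = label, values = values, n = n, mean = mean(values),
         ci95_half_width = hw),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf("<group_result> %s: n = %d, mean = %.4g +/- %.3g (95%% CI)\n",
              if (is.na(x$label)) "(unlabeled)" else x$label,
              x$n, x$mean, x$ci95_half_width))
  invisible(x)
}
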