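# Group summaries and the significance machinery used for slice
# electrophysiology tables: one-way ANOVA with Levene's homogeneity test and
# Tukey's post hoc comparisons, mean +/- SEM presentation with star
# annotations. The omnibus tests delegate to the standard fitters (stats::aov,
# stats::TukeyHSD, car::leveneTest); this module owns the degenerate-input
# handling and the publication-style assembly.

#' Mean, SEM and n of one group
#'
#' @param values Numeric vector, n >= 2.
#' @return Named numeric `c(n, mean, sem)` with
#'   `sem = sd(values)/sqrt(n)` (sample SD, n - 1 denominator).
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("group summary: need n >= 2", call. = FALSE)
  c(n = n, mean = mean(values), sem = stats::sd(values) / sqrt(n))
}

as_group_frame <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), ns), levels = names(groups)))
}

#' One-way analysis of variance
#'
#' Standard between/within decomposition over k groups. Degenerate inputs are
#' handled explicitly: all observations identical gives an undefined F
#' (`NA`); zero within-group variance with unequal means gives `F = Inf`,
#' `p = 0`.
#'
#' @param groups List of numeric vectors (k >= 2, each n >= 2).
#' @return List with `F`, `p`, `df` (numerator, denominator) and `ms_within`.
#' @export
one_way_anova <- function(groups) {
  df <- as_group_frame(groups)
  k <- nlevels(df$group)
  N <- nrow(df)
  dfs <- c(k - 1L, N - k)
  within_var <- vapply(split(df$value, df$group), stats::var, numeric(1))
  means <- vapply(split(df$value, df$group), mean, numeric(1))
  if (all(within_var == 0)) {
    if (max(means) - min(means) == 0)
      return(list(F = NA_real_, p = NA_real_, df = dfs, ms_within = 0))
    return(list(F = Inf, p = 0, df = dfs, ms_within = 0))
  }
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  list(F = tab$`F value`[1], p = tab$`Pr(>F)`[1], df = dfs,
       ms_within = tab$`Mean Sq`[2])
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations from group centers. The classic
#' (mean-centered) form is the default; `center = "median"` gives the
#' Brown-Forsythe variant.
#'
#' @param groups List of numeric vectors (k >= 2, each n >= 2).
#' @param center `"mean"` (classic Levene) or `"median"` (Brown-Forsythe).
#' @return List with `W` (the F-distributed statistic), `p` and `df`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  df <- as_group_frame(groups)
  centers <- vapply(split(df$value, df$group),
                    if (center == "mean") mean else stats::median,
                    numeric(1))
  dev <- abs(df$value - centers[as.integer(df$group)])
  if (all(dev == 0))
    return(list(W = NA_real_, p = NA_real_,
                df = c(nlevels(df$group) - 1L,
                       nrow(df) - nlevels(df$group))))
  fun <- if (center == "mean") mean else stats::median
  tab <- car::leveneTest(df$value, df$group, center = fun)
  list(W = tab$`F value`[1], p = tab$`Pr(>F)`[1],
       df = c(tab$Df[1], tab$Df[2]))
}

#' Tukey's honestly-significant-difference post hoc test
#'
#' Studentized-range-based pairwise adjusted p values using the within-group
#' mean square of the omnibus ANOVA; unbalanced designs use the Tukey-Kramer
#' correction (as implemented by [stats::TukeyHSD()]).
#'
#' @param groups Named list of numeric vectors (k >= 2, each n >= 2).
#' @return Named numeric vector of adjusted p values, names `"a-b"` per pair.
#' @export
tukey_hsd <- function(groups) {
  df <- as_group_frame(groups)
  labs <- levels(df$group)
  pairs <- utils::combn(labs, 2)
  pair_names <- paste(pairs[2, ], pairs[1, ], sep = "-")
  within_var <- vapply(split(df$value, df$group), stats::var, numeric(1))
  means <- vapply(split(df$value, df$group), mean, numeric(1))
  if (all(within_var == 0)) {
    p <- ifelse(abs(means[pairs[2, ]] - means[pairs[1, ]]) == 0, 1, 0)
    names(p) <- pair_names
    return(p)
  }
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  p <- tk[, "p adj"]
  names(p) <- rownames(tk)
  p[pair_names]
}

#' Significance stars from p values
#'
#' Conventional thresholds: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param p Numeric vector of p values.
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`.
#' @export
stars_from_p <- function(p) {
  out <- ifelse(is.na(p), "",
                ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  names(out) <- names(p)
  out
}

#' Compare groups on one parameter
#'
#' Assembles per-group summaries (n, mean, SEM), runs Levene's homogeneity
#' test, the omnibus one-way ANOVA and Tukey's post hoc comparisons on one
#' feature column of a labeled per-cell table, and assigns significance
#' stars per pair. With two labels this reproduces the conventional
#' control-versus-treated comparison within one sex and age.
#'
#' @param data `data.frame` with one row per cell/slice.
#' @param parameter Name of the feature column to compare.
#' @param groups Optional character vector restricting (and ordering) the
#'   labels compared; default: all labels present.
#' @param group_col Name of the label column (default `"group"`).
#' @param levene_center Passed to [levene_test()].
#' @return An object of class `"group_comparison"`: summaries, ANOVA,
#'   Levene, Tukey p values, stars, and publication-style
#'   `"mean +/- sem"` strings.
#' @export
compare_groups <- function(data, parameter, groups = NULL,
                           group_col = "group", levene_center = "mean") {
  if (!parameter %in% names(data))
    stop("parameter column '", parameter, "' not found", call. = FALSE)
  if (!group_col %in% names(data))
    stop("group column '", group_col, "' not found", call. = FALSE)
  labs <- if (is.null(groups)) unique(as.character(data[[group_col]]))
          else groups
  vals <- lapply(labs, function(l) {
    v <- data[data[[group_col]] == l, parameter]
    v[!is.na(v)]
  })
  names(vals) <- labs
  summaries <- lapply(vals, summarize_group)
  an <- one_way_anova(vals)
  lev <- levene_test(vals, center = levene_center)
  tk <- tukey_hsd(vals)
  st <- stars_from_p(tk)
  pretty <- vapply(seq_along(labs), function(i) {
    s <- summaries[[i]]
    star <- ""
    if (i > 1) {
      pair <- paste(labs[i], labs[1], sep = "-")
      if (pair %in% names(st)) star <- st[[pair]]
    }
    sprintf("%.2f ± %.2f%s", s[["mean"]], s[["sem"]], star)
  }, character(1))
  names(pretty) <- labs
  structure(list(parameter = parameter, groups = summaries,
                 anova_F = an$F, anova_p = an$p, anova_df = an$df,
                 levene_W = lev$W, levene_p = lev$p,
                 tukey = tk, stars = st, formatted = pretty),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Group comparison:", x$parameter, "\n")
  for (l in names(x$groups)) {
    s <- x$groups[[l]]
    cat(sprintf("  %-12s n = %2d   %s\n", l, as.integer(s[["n"]]),
                x$formatted[[l]]))
  }
  cat(sprintf("  ANOVA      F(%d,%d) = %.3f, p = %.4g\n",
              x$anova_df[1], x$anova_df[2], x$anova_F, x$anova_p))
  cat(sprintf("  Levene     W = %.3f, p = %.4g\n", x$levene_W, x$levene_p))
  for (pr in names(x$tukey))
    cat(sprintf("  Tukey %-14s p = %.4g %s\n", pr, x$tukey[[pr]],
                x$stars[[pr]]))
  invisible(x)
}
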