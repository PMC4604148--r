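# Cohort hypothesis tests used for per-cell score comparisons.
# Thin, validated wrappers over base stats::aov / stats::TukeyHSD with the
# degenerate (zero-variance) cases pinned down explicitly.

canonical_groups <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("group", "value") %in% names(groups)))
      stop("data frame input needs columns 'group' and 'value'")
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  for (g in groups) {
    if (length(g) < 2L) stop("every group needs at least 2 values")
    if (!all(is.finite(g))) stop("group values must be finite")
  }
  groups
}

groups_to_df <- function(groups) {
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups)),
                            levels = names(groups)))
}

#' One-way fixed-effects ANOVA over per-cell scores
#'
#' Classical one-way analysis of variance:
#' `F = (SS_between / df_between) / (SS_within / df_within)` with
#' `df_between = n_groups - 1`, `df_within = sum(n_g) - n_groups`, and the
#' p value from the upper tail of the F distribution. When both the
#' between- and within-group sums of squares are zero (all values
#' identical) F is defined as 0 with p = 1; zero within-group variance with
#' real separation gives `F = Inf`, p = 0.
#'
#' @param groups Named list of numeric vectors (one per group, each with
#'   >= 2 finite values), or a data frame with columns `group` and `value`.
#' @return List: `F`, `df_between`, `df_within`, `p`, `group_means`, `n`.
#' @export
one_way_anova <- function(groups) {
  groups <- canonical_groups(groups)
  df <- groups_to_df(groups)
  k <- length(groups)
  df_b <- k - 1L
  df_w <- nrow(df) - k
  grand <- mean(df$value)
  ss_b <- sum(lengths(groups) *
                (vapply(groups, mean, numeric(1)) - grand)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ss_w <= 0) {
    f <- if (ss_b <= 0) 0 else Inf
    p <- if (ss_b <= 0) 1 else 0
  } else {
    fit <- stats::aov(value ~ group, data = df)
    s <- summary(fit)[[1]]
    f <- s[["F value"]][1]
    p <- s[["Pr(>F)"]][1]
  }
  list(F = f, df_between = df_b, df_within = df_w, p = p,
       group_means = vapply(groups, mean, numeric(1)), n = lengths(groups))
}

#' Tukey's honestly-significant-difference multiple comparison
#'
#' All-pairs post-ANOVA comparison using the studentized range
#' distribution; unequal group sizes are handled with the Tukey-Kramer
#' harmonic term (`1/n_i + 1/n_j`), so equal-sized cohorts reduce to the
#' classical HSD. With exactly two groups the adjusted p equals the
#' pooled-variance two-sample t-test p. Significance stars follow the
#' convention `***` p < 0.0001, `**` p < 0.001, `*` p < 0.05, `ns`
#' otherwise.
#'
#' @inheritParams one_way_anova
#' @param alpha Family-wise significance level (used for the confidence
#'   intervals and reported in the result).
#' @return Data frame, one row per unordered pair: `group_i`, `group_j`,
#'   `diff` (mean_j - mean_i), `lwr`, `upr`, `p_adj`, `stars`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- canonical_groups(groups)
  df <- groups_to_df(groups)
  labs <- names(groups)
  pairs <- utils::combn(labs, 2L)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  if (ss_w <= 0) {
    means <- vapply(groups, mean, numeric(1))
    diff <- means[pairs[2L, ]] - means[pairs[1L, ]]
    out <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                      diff = unname(diff), lwr = unname(diff),
                      upr = unname(diff),
                      p_adj = ifelse(diff == 0, 1, 0))
  } else {
    fit <- stats::aov(value ~ group, data = df)
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
    # TukeyHSD labels rows "j-i" in factor-level order matching combn
    out <- data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"])
  }
  rownames(out) <- NULL
  out$stars <- significance_stars(out$p_adj)
  attr(out, "alpha") <- alpha
  out
}

significance_stars <- function(p) {
  ifelse(p < 1e-4, "***", ifelse(p < 1e-3, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Full cohort comparison: ANOVA plus Tukey pairwise tests
#'
#' @inheritParams tukey_hsd
#' @return An object of class `group_comparison`: `groups` (the input),
#'   `anova` (see [one_way_anova()]), `pairwise` (see [tukey_hsd()]),
#'   `alpha`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  groups <- canonical_groups(groups)
  structure(list(groups = groups,
                 anova = one_way_anova(groups),
                 pairwise = tukey_hsd(groups, alpha = alpha),
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  a <- x$anova
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              a$df_between, a$df_within, a$F, a$p))
  cat("Tukey multiple comparison:\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}
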