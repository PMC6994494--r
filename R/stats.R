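#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness (D'Agostino's transformed
#' `sqrt(b1)`) and kurtosis (Anscombe-Glynn's transformed `b2`) into the
#' omnibus statistic `K2 = Z_skew^2 + Z_kurt^2`, chi-squared with 2 degrees
#' of freedom under normality. Requires `n >= 8`.
#'
#' @param x Numeric vector, `n >= 8`, non-constant.
#' @return A list of class `htest` with `statistic` (K2), `p.value`, and
#'   the two component z-scores in `parameter`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) nb_stop("insufficient_n", "D'Agostino-Pearson requires n >= 8")
  if (sd(x) < 1e-12) nb_stop("degenerate_group", "constant sample")
  m <- mean(x)
  m2 <- mean((x - m)^2); m3 <- mean((x - m)^3); m4 <- mean((x - m)^4)
  b1 <- m3 / m2^1.5
  b2 <- m4 / m2^2

  # skewness: D'Agostino (1970)
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_skew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis: Anscombe & Glynn (1983)
  e_b2 <- 3 * (n - 1) / (n + 1)
  var_b2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - e_b2) / sqrt(var_b2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z_kurt <- ((1 - 2 / (9 * a)) -
               ((1 - 2 / a) / (1 + xk * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z_skew^2 + z_kurt^2
  structure(list(statistic = c(K2 = k2),
                 parameter = c(z_skew = z_skew, z_kurt = z_kurt),
                 p.value = pchisq(k2, df = 2, lower.tail = FALSE),
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Dunn's rank-based post-hoc test
#'
#' Pairwise z-tests on mean ranks following a Kruskal-Wallis test, with tie
#' correction and Holm adjustment of the pairwise p-values.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group labels.
#' @param p_adjust_method Passed to [stats::p.adjust()] (default `"holm"`).
#' @return data.frame with `group1`, `group2`, `z`, `p`, `p_adj`.
#' @export
dunn_test <- function(values, groups, p_adjust_method = "holm") {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(groups)
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  combs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(combs))
  for (i in seq_len(ncol(combs))) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[i] <- (mean_ranks[[a]] - mean_ranks[[b]]) / se
    p[i] <- 2 * pnorm(-abs(z[i]))
  }
  data.frame(group1 = combs[1, ], group2 = combs[2, ], z = z, p = p,
             p_adj = p.adjust(p, p_adjust_method))
}

significance_marks <- function(p, parametric) {
  sym <- if (parametric) "*" else "#"
  vapply(p, function(pp) {
    if (is.na(pp)) return(NA_character_)
    if (pp < 0.0001) strrep(sym, 4)
    else if (pp < 0.001) strrep(sym, 3)
    else if (pp < 0.01) strrep(sym, 2)
    else if (pp < 0.05) sym
    else "n.s."
  }, "")
}

#' Normality-gated group comparison
#'
#' Applies the comparison procedure used throughout the nuclear-body
#' quantitation: every group is first checked with the D'Agostino-Pearson
#' omnibus normality test. If all groups look normal (p > `alpha_normality`)
#' the comparison is parametric: an unpaired two-tailed t-test for two
#' groups, or one-way ANOVA with Tukey's multiple comparisons for more.
#' If any group deviates, the comparison is non-parametric: Mann-Whitney
#' for two groups, or Kruskal-Wallis with Dunn-Holm pairwise follow-up for
#' more. Groups smaller than 8 (where the omnibus test is undefined) route
#' to the non-parametric branch with a note. Pairwise significance marks
#' use star tiers for the parametric branch and hash tiers for the
#' non-parametric branch (0.05, 0.01, 0.001, 0.0001).
#'
#' @param data Named list of numeric vectors (>= 2 groups, each `n >= 3`),
#'   or a data.frame with columns `group` and `value`.
#' @param alpha_normality Normality-gate level (default 0.05).
#' @return An object of class `nb_comparison`: `test_used`, `parametric`,
#'   `p_overall`, `pairwise` (with marks), `normality`, `group_summaries`
#'   (mean, SEM, n) and `notes`.
#' @examples
#' set.seed(1)
#' compare_groups(list(ctrl = rnorm(20, 10), treated = rnorm(20, 12)))
#' @export
compare_groups <- function(data, alpha_normality = 0.05) {
  if (is.data.frame(data)) {
    data <- split(data$value, data$group)
  }
  if (length(data) < 2) nb_stop("insufficient_n", "need at least 2 groups")
  if (is.null(names(data)) || any(names(data) == "")) {
    names(data) <- paste0("group", seq_along(data))
  }
  ns <- vapply(data, length, 0L)
  if (any(ns < 3)) nb_stop("insufficient_n", "every group needs n >= 3")
  if (any(vapply(data, function(g) sd(g) < 1e-12, TRUE))) {
    nb_stop("degenerate_group", "a group is constant-valued")
  }
  notes <- character(0)
  small <- ns < 8
  if (any(small)) {
    notes <- c(notes, paste0("groups below n = 8 (",
                             paste(names(data)[small], collapse = ", "),
                             "): normality test undefined, non-parametric branch used"))
    norm_p <- rep(NA_real_, length(data))
    parametric <- FALSE
  } else {
    norm_p <- vapply(data, function(g) dagostino_pearson(g)$p.value, 0)
    parametric <- all(norm_p > alpha_normality)
  }
  k <- length(data)
  df_long <- data.frame(
    value = unlist(data, use.names = FALSE),
    group = factor(rep(names(data), ns), levels = names(data))
  )
  if (parametric) {
    if (k == 2) {
      test_used <- "t_test"
      ht <- t.test(data[[1]], data[[2]], var.equal = TRUE)
      p_overall <- ht$p.value
      pairwise <- data.frame(group1 = names(data)[1], group2 = names(data)[2],
                             p = ht$p.value, p_adj = ht$p.value)
    } else {
      test_used <- "anova_tukey"
      fit <- aov(value ~ group, data = df_long)
      p_overall <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk <- TukeyHSD(fit)$group
      cmp <- strsplit(rownames(tk), "-", fixed = TRUE)
      pairwise <- data.frame(group1 = vapply(cmp, `[`, "", 2),
                             group2 = vapply(cmp, `[`, "", 1),
                             p = tk[, "p adj"], p_adj = tk[, "p adj"],
                             row.names = NULL)
    }
  } else {
    if (k == 2) {
      test_used <- "mann_whitney"
      ht <- suppressWarnings(wilcox.test(data[[1]], data[[2]]))
      p_overall <- ht$p.value
      pairwise <- data.frame(group1 = names(data)[1], group2 = names(data)[2],
                             p = ht$p.value, p_adj = ht$p.value)
    } else {
      test_used <- "kruskal_wallis"
      ht <- kruskal.test(value ~ group, data = df_long)
      p_overall <- ht$p.value
      dn <- dunn_test(df_long$value, df_long$group)
      pairwise <- dn[, c("group1", "group2", "p", "p_adj")]
    }
  }
  pairwise$marks <- significance_marks(pairwise$p_adj, parametric)
  summaries <- data.frame(
    group = names(data), n = ns,
    mean = vapply(data, mean, 0),
    sem = vapply(data, function(g) sd(g) / sqrt(length(g)), 0),
    row.names = NULL
  )
  structure(
    list(test_used = test_used, parametric = parametric,
         p_overall = p_overall, pairwise = pairwise,
         normality = data.frame(group = names(data), p = norm_p,
                                row.names = NULL),
         group_summaries = summaries, alpha_normality = alpha_normality,
         notes = notes),
    class = "nb_comparison"
  )
}

#' @export
print.nb_comparison <- function(x, ...) {
  cat(sprintf("<nb_comparison> %s (%s branch), overall p = %.4g\n",
              x$test_used, if (x$parametric) "parametric" else "non-parametric",
              x$p_overall))
  print(x$pairwise, row.names = FALSE)
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}
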