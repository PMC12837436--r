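#' Normality gate: parametric or nonparametric route
#'
#' Shapiro-Wilk normality of every group decides the family of the
#' between-group test: the parametric route is taken only when every group's
#' Shapiro-Wilk p-value is at least `alpha`. Groups too small for the test
#' (n < 3) or with zero spread route the comparison to the nonparametric
#' family with a warning — conservative and reproducible.
#'
#' @param groups named list of numeric vectors, one per group.
#' @param alpha significance level of the gate (default 0.05).
#' @return A list: `route` (`"parametric"` / `"nonparametric"`) and
#'   `gate_trace` (per-group Shapiro p-values, `alpha`, names of groups that
#'   were degenerate for the test).
#' @export
normality_gate <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 1L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  shapiro_p <- vapply(groups, function(x) {
    if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  degenerate <- names(groups)[is.na(shapiro_p)]
  if (length(degenerate)) {
    warning("group(s) too small or constant for Shapiro-Wilk (",
            paste(degenerate, collapse = ", "),
            "): routed to nonparametric tests", call. = FALSE)
  }
  route <- if (length(degenerate) == 0L && all(shapiro_p >= alpha)) {
    "parametric"
  } else {
    "nonparametric"
  }
  list(route = route,
       gate_trace = list(shapiro_p = shapiro_p, alpha = alpha,
                         degenerate_groups = degenerate))
}

#' Dunn's rank-based post-hoc test
#'
#' All-pairs Dunn z-tests on the pooled ranks (tie-corrected), following a
#' Kruskal-Wallis omnibus. Two-sided p-values with Bonferroni adjustment over
#' all pairs, so adjusted p-values are never smaller than unadjusted ones.
#'
#' @param groups named list of numeric vectors.
#' @return data.frame `(comparison, z, p_unadjusted, p_adjusted)`.
#' @export
dunn_test <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  mean_rank <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(names(groups), 2)
  n_pairs <- ncol(pairs)
  res <- apply(pairs, 2, function(p) {
    i <- p[1]; j <- p[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n[[i]] + 1 / n[[j]]))
    z <- (mean_rank[[i]] - mean_rank[[j]]) / se
    p_un <- 2 * stats::pnorm(-abs(z))
    c(z = z, p_unadjusted = p_un)
  })
  data.frame(comparison = paste(pairs[1, ], pairs[2, ], sep = " vs "),
             z = res["z", ],
             p_unadjusted = res["p_unadjusted", ],
             p_adjusted = pmin(1, res["p_unadjusted", ] * n_pairs),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Brown-Forsythe one-way ANOVA (F* statistic)
#'
#' The Brown-Forsythe modification of one-way ANOVA for unequal variances:
#' the between-group sum of squares is referenced against
#' `sum((1 - n_i/N) s_i^2)` with Satterthwaite-type denominator degrees of
#' freedom.
#'
#' @param groups named list of numeric vectors.
#' @return list: `statistic`, `df1`, `df2`, `p.value`.
#' @export
brown_forsythe_anova <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2L)
  n <- lengths(groups)
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, stats::var, numeric(1))
  grand <- sum(n * means) / N
  num <- sum(n * (means - grand)^2)
  denom_terms <- (1 - n / N) * vars
  fstar <- num / sum(denom_terms)
  ci <- denom_terms / sum(denom_terms)
  df2 <- 1 / sum(ci^2 / (n - 1))
  list(statistic = fstar, df1 = k - 1, df2 = df2,
       p.value = stats::pf(fstar, k - 1, df2, lower.tail = FALSE))
}

#' Normality-gated between-group comparison
#'
#' The full decision tree used for every between-group comparison in the
#' pipeline:
#' \itemize{
#'   \item parametric route (all groups Shapiro-Wilk normal at `alpha`):
#'     two groups get an unpaired two-tailed Student's t-test; more than two
#'     groups first pass a variance gate (Brown-Forsythe test of equal
#'     spread, i.e. a Levene test on deviations from group medians) — equal
#'     spread gives one-way ANOVA with Tukey's all-pairs post hoc, unequal
#'     spread gives Brown-Forsythe and Welch ANOVA with Dunnett's post hoc
#'     against the first (control) group;
#'   \item nonparametric route: two groups get a two-sided unpaired
#'     Mann-Whitney test; more than two get Kruskal-Wallis with Dunn's
#'     all-pairs post hoc (Bonferroni-adjusted).
#' }
#' Test statistics are delegated to standard routines
#' ([stats::t.test()], [stats::aov()]/[stats::TukeyHSD()],
#' [stats::oneway.test()], [multcomp::glht()], [stats::wilcox.test()],
#' [stats::kruskal.test()]); gating, orchestration and the Dunn and
#' Brown-Forsythe statistics live here, and the full gate trace is returned
#' so any choice can be replayed.
#'
#' @param groups named list of numeric vectors (first group is the control
#'   reference for Dunnett contrasts), or a data.frame with columns `group`
#'   and `value`.
#' @param alpha significance level for the gates (default 0.05).
#' @return A list of class `comparison_result`: `test_chosen` (one of
#'   `"T_TEST"`, `"ONEWAY_ANOVA_TUKEY"`, `"BF_WELCH_ANOVA_DUNNETT"`,
#'   `"MANN_WHITNEY"`, `"KRUSKAL_WALLIS_DUNN"`), `omnibus_p`, `posthoc`
#'   (data.frame of pairwise adjusted p-values, `NULL` for two-group tests),
#'   `gate_trace`, and `details` (auxiliary statistics, e.g. the
#'   Brown-Forsythe omnibus alongside Welch).
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, factor(groups$group,
                                         levels = unique(groups$group)))
  }
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)",
                                      call. = FALSE)
  k <- length(groups)
  gate <- normality_gate(groups, alpha)
  trace <- gate$gate_trace
  details <- list()
  posthoc <- NULL

  if (gate$route == "parametric" && k == 2L) {
    test_chosen <- "T_TEST"
    tt <- stats::t.test(groups[[1]], groups[[2]], var.equal = TRUE,
                        alternative = "two.sided")
    omnibus_p <- tt$p.value
    details$t <- unname(tt$statistic)
  } else if (gate$route == "parametric") {
    df <- data.frame(value = unlist(groups, use.names = FALSE),
                     group = factor(rep(names(groups), lengths(groups)),
                                    levels = names(groups)))
    lev <- car::leveneTest(value ~ group, data = df, center = stats::median)
    trace$variance_gate_p <- lev[["Pr(>F)"]][1]
    if (trace$variance_gate_p >= alpha) {
      test_chosen <- "ONEWAY_ANOVA_TUKEY"
      fit <- stats::aov(value ~ group, data = df)
      omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
      tk <- stats::TukeyHSD(fit)$group
      posthoc <- data.frame(
        comparison = gsub("-", " vs ", rownames(tk), fixed = TRUE),
        diff = tk[, "diff"], p_adjusted = tk[, "p adj"],
        stringsAsFactors = FALSE, row.names = NULL)
    } else {
      test_chosen <- "BF_WELCH_ANOVA_DUNNETT"
      welch <- stats::oneway.test(value ~ group, data = df,
                                  var.equal = FALSE)
      bf <- brown_forsythe_anova(groups)
      omnibus_p <- welch$p.value
      details$welch_p <- welch$p.value
      details$brown_forsythe_p <- bf$p.value
      fit <- stats::aov(value ~ group, data = df)
      dn <- summary(multcomp::glht(
        fit, linfct = multcomp::mcp(group = "Dunnett")))
      posthoc <- data.frame(
        comparison = gsub(" - ", " vs ", names(dn$test$coefficients),
                          fixed = TRUE),
        diff = unname(dn$test$coefficients),
        p_adjusted = unname(dn$test$pvalues),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  } else if (k == 2L) {
    test_chosen <- "MANN_WHITNEY"
    mw <- stats::wilcox.test(groups[[1]], groups[[2]], exact = FALSE,
                             alternative = "two.sided")
    omnibus_p <- mw$p.value
    details$U <- unname(mw$statistic)
  } else {
    test_chosen <- "KRUSKAL_WALLIS_DUNN"
    kw <- stats::kruskal.test(groups)
    omnibus_p <- kw$p.value
    posthoc <- dunn_test(groups)
  }

  structure(list(test_chosen = test_chosen, omnibus_p = omnibus_p,
                 posthoc = posthoc, gate_trace = trace, details = details,
                 alpha = alpha, group_n = lengths(groups)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("between-group comparison\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(x$group_n), x$group_n),
                    collapse = ", ")))
  sp <- x$gate_trace$shapiro_p
  cat(sprintf("  Shapiro-Wilk p: %s\n",
              paste(sprintf("%s %.3g", names(sp), sp), collapse = ", ")))
  if (!is.null(x$gate_trace$variance_gate_p)) {
    cat(sprintf("  variance gate (Brown-Forsythe spread) p: %.3g\n",
                x$gate_trace$variance_gate_p))
  }
  cat(sprintf("  test chosen: %s\n  omnibus p: %.4g\n",
              x$test_chosen, x$omnibus_p))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (adjusted p):\n")
    for (i in seq_len(nrow(x$posthoc))) {
      cat(sprintf("    %-28s %.4g\n", x$posthoc$comparison[i],
                  x$posthoc$p_adjusted[i]))
    }
  }
  invisible(x)
}

#' Per-day group comparisons of a longitudinal table
#'
#' Runs [compare_groups()] once per day of a long-format trajectory table
#' (the per-day omnibus + post-hoc reading of cross-sectional group
#' contrasts).
#'
#' @param trajectories long table `(group, subject_id, day, volume_mL)`.
#' @param alpha gate significance level.
#' @param control optional group name placed first (Dunnett reference).
#' @return Named list of `comparison_result`, one per day.
#' @export
compare_by_day <- function(trajectories, alpha = 0.05, control = NULL) {
  lev <- unique(trajectories$group)
  if (!is.null(control)) {
    stopifnot(control %in% lev)
    lev <- c(control, setdiff(lev, control))
  }
  days <- sort(unique(trajectories$day))
  out <- lapply(days, function(d) {
    sub <- trajectories[trajectories$day == d, ]
    groups <- split(sub$volume_mL, factor(sub$group, levels = lev))
    groups <- groups[lengths(groups) > 0L]
    compare_groups(groups, alpha = alpha)
  })
  names(out) <- paste0("day_", days)
  out
}
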