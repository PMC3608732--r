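#' Holm-Sidak step-down multiple-comparison adjustment
#'
#' Sorts the p values ascending and sets
#' `adjusted_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforces monotone
#' nondecreasing adjusted values down the ordering, and maps them back to
#' the input order. Rejections are made where the adjusted p is below
#' `alpha`.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @param alpha significance level (default 0.05).
#' @return list with `adjusted` (same order as input) and logical `reject`.
#' @export
holm_sidak_adjust <- function(p, alpha = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  padj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  padj <- cummax(padj)
  padj <- pmin(padj, 1)
  out <- numeric(m)
  out[ord] <- padj
  out <- pmax(out, p)   # guard the adjusted >= raw invariant against rounding
  list(adjusted = out, reject = out < alpha)
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Compare groups of per-animal values
#'
#' Replicates the study's statistical workflow: each group is screened for
#' normality (Shapiro-Wilk); two normal groups are compared by a two-sample
#' t test, more than two by one-way ANOVA followed by all-pairs Welch t
#' tests with Holm-Sidak adjustment. When any group fails the normality
#' screen the rank-based analogue is used instead (Wilcoxon / Kruskal-
#' Wallis with pairwise Wilcoxon) and the report is flagged.
#'
#' @param groups named list of numeric vectors, one per group (each
#'   `n >= 2`).
#' @param alpha significance level (default 0.05).
#' @param shapiro_alpha level of the normality screen.
#' @return An object of class `group_comparison`: a list with `summary`
#'   (per-group n, mean, SEM, Shapiro p), `method`, `statistic`, `p_value`,
#'   `pairwise` (data.frame with raw and Holm-Sidak adjusted p values and
#'   rejections) and `nonparametric` flag.
#' @export
group_compare <- function(groups, alpha = 0.05, shapiro_alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  n <- vapply(groups, length, 0L)
  if (any(n < 2L)) stop("every group needs n >= 2")
  sw_p <- vapply(groups, function(x) {
    if (length(unique(x)) < 3L) return(1)  # Shapiro needs variation
    stats::shapiro.test(x)$p.value
  }, 0)
  nonpar <- any(sw_p < shapiro_alpha)
  summary <- data.frame(group = names(groups), n = n,
                        mean = vapply(groups, mean, 0),
                        sem = vapply(groups, sem, 0),
                        shapiro_p = sw_p, row.names = NULL)
  k <- length(groups)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), n), levels = names(groups))
  if (k == 2L) {
    ht <- if (nonpar) stats::wilcox.test(groups[[1L]], groups[[2L]], exact = FALSE)
    else stats::t.test(groups[[1L]], groups[[2L]])
    method <- if (nonpar) "wilcoxon" else "t"
    statistic <- unname(ht$statistic); p_global <- ht$p.value
  } else if (nonpar) {
    ht <- stats::kruskal.test(values, fac)
    method <- "kruskal"
    statistic <- unname(ht$statistic); p_global <- ht$p.value
  } else {
    fit <- stats::aov(values ~ fac)
    tab <- summary(fit)[[1L]]
    method <- "anova"
    statistic <- tab[["F value"]][1L]; p_global <- tab[["Pr(>F)"]][1L]
  }
  pairs <- utils::combn(names(groups), 2L)
  praw <- apply(pairs, 2L, function(gp) {
    a <- groups[[gp[1L]]]; b <- groups[[gp[2L]]]
    if (nonpar) stats::wilcox.test(a, b, exact = FALSE)$p.value
    else stats::t.test(a, b)$p.value
  })
  adj <- holm_sidak_adjust(praw, alpha = alpha)
  pairwise <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                         p_raw = praw, p_adjusted = adj$adjusted,
                         reject = adj$reject, row.names = NULL)
  structure(list(summary = summary, method = method, statistic = statistic,
                 p_value = p_global, pairwise = pairwise,
                 nonparametric = nonpar, alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("group comparison (%s%s): p = %.4g\n", x$method,
              if (x$nonparametric) ", non-normal fallback" else "",
              x$p_value))
  print(x$summary, digits = 4)
  cat("pairwise (Holm-Sidak adjusted):\n")
  print(x$pairwise, digits = 4)
  invisible(x)
}
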