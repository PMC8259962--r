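# Group-comparison layer: classical two-sample t tests and one-way ANOVA
# with mean +/- SEM reporting.  No multiple-testing correction is applied
# anywhere in the package.

#' Summarize a measurement group
#'
#' @param label Group label.
#' @param values Numeric measurements (n >= 2).
#' @return Object of class `group_summary` with `label`, `values`,
#'   `mean`, `sem` (sd/sqrt(n)) and `n`.
#' @export
group_summary <- function(label, values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values))
    stop("a group needs >= 2 non-missing values")
  structure(list(label = as.character(label), values = values,
                 mean = mean(values),
                 sem = stats::sd(values) / sqrt(length(values)),
                 n = length(values)),
            class = "group_summary")
}

#' @exportS3Method base::print
print.group_summary <- function(x, digits = 4, ...) {
  cat(sprintf("%s: %s +/- %s (mean +/- SEM), n = %d\n", x$label,
              format(x$mean, digits = digits), format(x$sem, digits = digits),
              x$n))
  invisible(x)
}

#' Two-sample comparison of group summaries
#'
#' Classical (pooled-variance) unpaired or paired two-sided t test, the
#' standard analysis for two-condition electrophysiology readouts.  Welch
#' correction is available but off by default.
#'
#' @param a,b [group_summary()] objects.
#' @param test `"unpaired_t"` or `"paired_t"` (paired requires equal n
#'   with ordered pairing).
#' @param welch Use the Welch degrees-of-freedom correction (unpaired
#'   only).
#' @return Object of class `group_comparison`: `statistic` (t), `df`,
#'   `p_value`, `method` and the two summaries.
#' @examples
#' compare_groups(group_summary("a", c(1, 2, 3)),
#'                group_summary("b", c(4, 5, 6)))
#' @export
compare_groups <- function(a, b, test = c("unpaired_t", "paired_t"),
                           welch = FALSE) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  test <- match.arg(test)
  if (test == "paired_t") {
    if (a$n != b$n) stop("paired test requires equal n with ordered pairing")
    ht <- stats::t.test(a$values, b$values, paired = TRUE)
  } else {
    ht <- stats::t.test(a$values, b$values, var.equal = !welch)
  }
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, method = test, welch = welch,
                 a = a, b = b),
            class = "group_comparison")
}

#' @exportS3Method base::print
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("%s vs %s (%s%s): t = %s, df = %s, p = %s\n",
              x$a$label, x$b$label, x$method,
              if (x$welch) ", Welch" else "",
              format(x$statistic, digits = digits),
              format(x$df, digits = digits),
              format(x$p_value, digits = digits)))
  print(x$a); print(x$b)
  invisible(x)
}

#' One-way ANOVA across group summaries
#'
#' Classical one-way fixed-effects ANOVA.  Degenerate inputs are handled
#' explicitly: all groups identical gives F = 0, p = 1; zero
#' within-group variance with differing means gives an infinite F with a
#' `"degenerate"` flag.
#'
#' @param groups List of [group_summary()] objects (>= 2).
#' @return Object of class `anova_result`: `F`, `df` (between, within),
#'   `p_value`, per-group summaries and `flags`.
#' @examples
#' anova_oneway(list(group_summary("a", 1:3), group_summary("b", 2:4),
#'                   group_summary("c", 3:5)))
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups")
  stopifnot(all(vapply(groups, inherits, TRUE, "group_summary")))
  values <- unlist(lapply(groups, `[[`, "values"))
  g <- factor(rep(vapply(groups, `[[`, "", "label"),
                  vapply(groups, `[[`, 0L, "n")),
              levels = vapply(groups, `[[`, "", "label"))
  n <- length(values)
  k <- length(groups)
  grand <- mean(values)
  ssb <- sum(vapply(groups, function(x) x$n * (x$mean - grand)^2, 0))
  ssw <- sum(vapply(groups, function(x) sum((x$values - x$mean)^2), 0))
  df1 <- k - 1; df2 <- n - k
  flags <- character(0)
  if (ssw == 0) {
    if (ssb <= 1e-12 * max(abs(values), 1)) {
      Fv <- 0; p <- 1
    } else {
      Fv <- Inf; p <- 0; flags <- "degenerate"
    }
  } else {
    Fv <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = Fv, df = c(between = df1, within = df2), p_value = p,
                 groups = groups, flags = flags),
            class = "anova_result")
}

#' @exportS3Method base::print
print.anova_result <- function(x, digits = 4, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %s, p = %s%s\n",
              x$df[1], x$df[2], format(x$F, digits = digits),
              format(x$p_value, digits = digits),
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  for (g in x$groups) print(g, digits = digits)
  invisible(x)
}
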