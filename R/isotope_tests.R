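#' Two-sample t test on isotope values
#'
#' Defaults to the unequal-variance (Welch) statistic with
#' Welch-Satterthwaite fractional degrees of freedom; the pooled-variance
#' test is available by flag. In paired mode the test is the one-sample t
#' on within-pair differences with `df = n - 1`; pairing is driven by
#' explicit pairing ids when supplied (e.g. consumer and plant samples
#' collected from the same tree), never inferred.
#'
#' @param a,b Numeric vectors (per-mil delta values), each of length >= 2.
#' @param paired Pair observations (by position, or by id when `ids_a` /
#'   `ids_b` are given).
#' @param pooled Use the pooled-variance statistic instead of Welch.
#'   Ignored when `paired = TRUE`.
#' @param ids_a,ids_b Optional pairing ids; in paired mode every id must
#'   appear in both groups, and unmatched ids are an error listing them.
#' @return A one-row `test_result` data frame (`method`, `statistic`,
#'   `df`, `p_value`, `groups`, `adjusted`). Identical groups give
#'   `t = 0`, `p = 1`.
#' @export
welch_t <- function(a, b, paired = FALSE, pooled = FALSE,
                    ids_a = NULL, ids_b = NULL) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (paired) {
    if (!is.null(ids_a) || !is.null(ids_b)) {
      if (is.null(ids_a) || is.null(ids_b)) {
        stop("paired mode needs ids for both groups (or neither)",
             call. = FALSE)
      }
      unmatched <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
      if (length(unmatched) > 0) {
        stop("unmatched pairing id(s): ",
             paste(unique(unmatched), collapse = ", "), call. = FALSE)
      }
      b <- b[match(ids_a, ids_b)]
    } else if (length(a) != length(b)) {
      stop("paired mode needs equal-length groups", call. = FALSE)
    }
    d <- a - b
    if (length(d) < 2) stop("need >= 2 pairs", call. = FALSE)
    if (stats::var(d) == 0) {
      # constant differences: t is 0 (all zero) or diverges
      stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      return(test_result("Paired t test", stat, length(d) - 1,
                         if (stat == 0) 1 else 0, "a vs b"))
    }
    fit <- stats::t.test(d)
    return(test_result("Paired t test", unname(fit$statistic),
                       unname(fit$parameter), fit$p.value, "a vs b"))
  }
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs >= 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    # both groups constant: t is 0 (equal means) or diverges
    stat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    return(test_result(if (pooled) "Two-sample t test (pooled)"
                       else "Welch two-sample t test",
                       stat, length(a) + length(b) - 2,
                       if (stat == 0) 1 else 0, "a vs b"))
  }
  fit <- stats::t.test(a, b, var.equal = pooled)
  test_result(if (pooled) "Two-sample t test (pooled)"
              else "Welch two-sample t test",
              unname(fit$statistic), unname(fit$parameter), fit$p.value,
              "a vs b")
}

#' One-way ANOVA across roles
#'
#' F test that group means are equal, with (k - 1, N - k) degrees of
#' freedom — used to check, e.g., that ant larvae, pupae and workers share
#' a delta15N signature. When the within-group sum of squares is exactly
#' zero while group means differ, the F ratio diverges; the statistic is
#' reported as `Inf` with p = 0 rather than erroring.
#'
#' @param groups Named list mapping group label to a numeric vector of
#'   length >= 2 (at least 2 groups).
#' @return A one-row `test_result` data frame; `df` holds
#'   `"df1,df2"` as a comma-joined pair.
#' @export
oneway_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  if (any(lengths(groups) < 2)) {
    stop("every group needs >= 2 observations", call. = FALSE)
  }
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  k <- nlevels(g)
  n <- length(values)
  df1 <- k - 1
  df2 <- n - k
  if (df2 < 1) stop("degenerate design: no residual df", call. = FALSE)
  group_mu <- tapply(values, g, mean)
  ss_within <- sum((values - group_mu[as.character(g)])^2)
  if (ss_within <= .Machine$double.eps * max(1, sum(values^2))) {
    # zero within-group variance: F diverges unless means are also equal
    ss_between <- sum(tapply(values, g, length) *
                        (group_mu - mean(values))^2)
    degenerate <- ss_between <= .Machine$double.eps * max(1, sum(values^2))
    stat <- if (degenerate) 0 else Inf
    p <- if (degenerate) 1 else 0
  } else {
    tab <- stats::anova(stats::lm(values ~ g))
    stat <- tab$`F value`[1]
    p <- tab$`Pr(>F)`[1]
  }
  test_result("One-way ANOVA", stat, paste(df1, df2, sep = ","), p,
              paste(levels(g), collapse = "|"))
}
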