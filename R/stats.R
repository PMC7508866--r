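#' Measurement group
#'
#' A labelled set of per-sample measurements of one variable, the unit of
#' the nonparametric group comparisons.
#'
#' @param label Group label (e.g. `"MMT_OA"`, `"MIA_Healthy"`).
#' @param values Numeric vector of finite measurements, length >= 1.
#' @return An `oat_group` list with `label`, `values`, `n`.
#' @export
measurement_group <- function(label, values) {
  oat_check(is.character(label) && length(label) == 1L,
            "'label' must be a single string")
  oat_check(length(values) >= 1L && all(is.finite(values)),
            "'values' must be finite and non-empty")
  structure(list(label = label, values = as.numeric(values),
                 n = length(values)),
            class = "oat_group")
}

check_groups <- function(groups, min_groups = 2L) {
  oat_check(is.list(groups) && length(groups) >= min_groups &&
              all(vapply(groups, inherits, logical(1), "oat_group")),
            sprintf("need a list of >= %d measurement_group objects", min_groups))
  invisible(groups)
}

#' Kruskal-Wallis omnibus test
#'
#' Rank-based H statistic with tie correction and the chi-square
#' approximation on k - 1 degrees of freedom (via [stats::kruskal.test()]).
#' The chi-square approximation is used, not an exact permutation law: the
#' smallest attainable p for two tie-free groups of three is 0.0495, the
#' working floor of a 3 + 3 contralateral design.
#'
#' @param groups List of [measurement_group()] objects (>= 2, total n >= 3).
#' @return List with `H`, `df`, `p`.
#' @section Errors: all values identical across every group leaves the
#'   tie-corrected H undefined and raises `oatopo_degenerate_ranks`.
#' @examples
#' kruskal_wallis(list(measurement_group("a", c(1, 2, 3)),
#'                     measurement_group("b", c(4, 5, 6))))
#' @export
kruskal_wallis <- function(groups) {
  check_groups(groups)
  x <- unlist(lapply(groups, `[[`, "values"))
  g <- factor(rep(vapply(groups, `[[`, character(1), "label"),
                  vapply(groups, `[[`, integer(1), "n")),
              levels = vapply(groups, `[[`, character(1), "label"))
  oat_check(length(x) >= 3L, "need at least 3 observations in total")
  if (length(unique(x)) == 1L) {
    oat_stop("all observations identical: ranks are degenerate and H is undefined",
             "oatopo_degenerate_ranks")
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Dunn post-hoc pairwise tests with Bonferroni correction
#'
#' Pairwise z statistics on the pooled ranks with the standard tie
#' correction in the variance term; two-sided p-values multiplied by the
#' number of comparisons and capped at 1. With two groups the multiplier
#' is 1 and the adjusted p equals the raw p.
#'
#' @param groups List of [measurement_group()] objects (>= 2).
#' @param alpha Significance level used for the `significant` flags.
#' @return A data frame with one row per pair: `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_adj`, `significant`.
#' @export
dunn_bonferroni <- function(groups, alpha = 0.05) {
  check_groups(groups)
  x <- unlist(lapply(groups, `[[`, "values"))
  labels <- vapply(groups, `[[`, character(1), "label")
  sizes <- vapply(groups, `[[`, integer(1), "n")
  if (length(unique(x)) == 1L) {
    oat_stop("all observations identical: ranks are degenerate",
             "oatopo_degenerate_ranks")
  }
  N <- length(x)
  r <- rank(x)
  gi <- rep(seq_along(groups), sizes)
  rbar <- tapply(r, gi, mean)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  if (s2 <= 0) {
    oat_stop("tie correction exhausted the rank variance",
             "oatopo_degenerate_ranks")
  }
  pairs <- utils::combn(seq_along(groups), 2)
  m <- ncol(pairs)
  out <- do.call(rbind, lapply(seq_len(m), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    z <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / sizes[i] + 1 / sizes[j]))
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group_a = labels[i], group_b = labels[j], z = unname(z),
               p_raw = unname(p), p_adj = min(1, unname(p) * m),
               stringsAsFactors = FALSE)
  }))
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Per-group summary in "mean (SD)" style
#'
#' Arithmetic mean and sample (n - 1) standard deviation per group, with
#' the rendered cell strings used by the report tables. The SD cell is an
#' em dash for n = 1.
#'
#' @param groups List of [measurement_group()] objects (>= 1).
#' @param digits Decimal places in the rendered strings.
#' @return Data frame: `label`, `n`, `mean`, `sd`, `rendered`.
#' @examples
#' summarize_groups(list(measurement_group("a", c(3, 4, 5))))$rendered
#' @export
summarize_groups <- function(groups, digits = 2) {
  check_groups(groups, min_groups = 1L)
  do.call(rbind, lapply(groups, function(g) {
    m <- mean(g$values)
    s <- if (g$n > 1L) stats::sd(g$values) else NA_real_
    data.frame(
      label = g$label, n = g$n, mean = m, sd = s,
      rendered = sprintf("%s (%s)", formatC(m, digits = digits, format = "f"),
                         if (is.na(s)) "—"
                         else formatC(s, digits = digits, format = "f")),
      stringsAsFactors = FALSE)
  }))
}
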