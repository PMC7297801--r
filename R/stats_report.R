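#' Descriptive summary of one condition
#'
#' Box-plot statistics as conventionally displayed for per-GUV binding
#' efficiencies: median, 25th/75th percentiles and min/max whiskers.
#' Quartiles use linear interpolation between order statistics (R's default
#' type 7); the dialect is recorded in the output because conventions differ.
#'
#' @param values numeric vector of binding efficiencies (non-empty).
#' @param condition label (e.g. "Gb3-C24:0 / phase-separated / lo").
#' @return One-row data.frame: `condition`, `n`, `median`, `q25`, `q75`,
#'   `min`, `max`, `quartile_dialect`.
#' @export
summarize_condition <- function(values, condition = "condition") {
  if (!length(values)) stopf("empty condition")
  if (anyNA(values)) stopf("condition contains missing values")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(condition = condition, n = length(values), median = q[2],
             q25 = q[1], q75 = q[3], min = min(values), max = max(values),
             quartile_dialect = "linear_interpolation_type7",
             stringsAsFactors = FALSE)
}

#' Summarise many conditions at once
#'
#' @param values numeric vector.
#' @param condition factor/character of the same length grouping `values`.
#' @return Data.frame with one [summarize_condition()] row per condition.
#' @export
summarize_conditions <- function(values, condition) {
  stopifnot(length(values) == length(condition))
  groups <- split(values, condition)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    summarize_condition(groups[[g]], g)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise significance analysis across conditions
#'
#' Two-sided Mann-Whitney U tests (exact when samples are small and tie-free)
#' for every requested pair of conditions, with Holm adjustment across the
#' family. Welch's t-test is available as an alternative. Pairs in which a
#' group has fewer than 3 values are flagged rather than silently dropped;
#' flagged pairs carry no p-value and do not enter the adjustment family.
#'
#' @param groups named list of numeric vectors, one per condition.
#' @param pairs optional 2-column character matrix (or list of length-2
#'   vectors) of condition pairs; default: all unordered pairs.
#' @param method `"wilcoxon"` (Mann-Whitney U) or `"welch"`.
#' @param p_adjust adjustment method passed to [stats::p.adjust()].
#' @return Data.frame: `group_a`, `group_b`, `statistic`, `p`, `p_adj`,
#'   `flagged`, `method`.
#' @export
pairwise_significance <- function(groups, pairs = NULL,
                                  method = c("wilcoxon", "welch"),
                                  p_adjust = "holm") {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L || is.null(names(groups))) {
    stopf("`groups` must be a named list with at least two conditions")
  }
  if (is.null(pairs)) {
    cmb <- utils::combn(names(groups), 2)
    pairs <- t(cmb)
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    if (!a %in% names(groups) || !b %in% names(groups)) {
      stopf("unknown condition in pair (%s, %s)", a, b)
    }
    xa <- groups[[a]]; xb <- groups[[b]]
    if (length(xa) < 3L || length(xb) < 3L) {
      return(data.frame(group_a = a, group_b = b, statistic = NA_real_,
                        p = NA_real_, flagged = TRUE, stringsAsFactors = FALSE))
    }
    res <- if (method == "wilcoxon") {
      ht <- suppressWarnings(stats::wilcox.test(xa, xb, alternative = "two.sided"))
      c(unname(ht$statistic), min(ht$p.value, 1))
    } else {
      ht <- stats::t.test(xa, xb, alternative = "two.sided", var.equal = FALSE)
      c(unname(ht$statistic), ht$p.value)
    }
    data.frame(group_a = a, group_b = b, statistic = res[1], p = res[2],
               flagged = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$p_adj[!out$flagged] <- stats::p.adjust(out$p[!out$flagged], method = p_adjust)
  out$method <- ifelse(out$flagged, NA_character_,
                       if (method == "wilcoxon") "mann_whitney_u" else "welch_t")
  rownames(out) <- NULL
  out[, c("group_a", "group_b", "statistic", "p", "p_adj", "flagged", "method")]
}

#' Box plot of binding efficiencies by condition
#'
#' Whiskers span the full min-max range, the box the 25th-75th percentiles
#' and the middle line the median, matching the package's condition
#' summaries.
#'
#' @param values numeric vector of binding efficiencies.
#' @param condition grouping vector.
#' @param ylab y-axis label.
#' @param ... passed to [graphics::boxplot()].
#' @return The boxplot statistics, invisibly.
#' @export
plot_condition_boxplot <- function(values, condition,
                                   ylab = "binding efficiency", ...) {
  graphics::boxplot(values ~ condition, range = 0, ylab = ylab, ...)
}
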