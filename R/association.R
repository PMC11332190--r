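#' Pearson correlation with t-based or permutation p-value
#'
#' Product-moment correlation after pairwise deletion of missing values.
#' The default two-sided p-value comes from `t = r * sqrt((n-2)/(1-r^2))`
#' on `n - 2` degrees of freedom (via [stats::cor.test()]); with only a
#' handful of communities the t approximation is marginal, so an exact-style
#' permutation p-value (proportion of `|r|` under random pairings at least
#' as large as observed, with the +1 continuity correction) is available.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `method = "permutation"`.
#' @return list with `r`, `p`, `n` (pairs used). Zero variance or fewer
#'   than 3 complete pairs gives `r = NA, p = NA`.
#' @export
pearson_cor <- function(x, y, method = c("t", "permutation"), n_perm = 10000) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  if (method == "t") {
    ct <- stats::cor.test(x, y, method = "pearson")
    return(list(r = unname(ct$estimate), p = ct$p.value, n = n))
  }
  r <- stats::cor(x, y)
  rp <- replicate(n_perm, abs(stats::cor(x, sample(y))))
  list(r = r, p = (1 + sum(rp >= abs(r))) / (n_perm + 1), n = n)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` with `m` fixed at the full indicator count (33) by
#' default, regardless of how many indicators could actually be computed.
#'
#' @param p numeric p-values.
#' @param m number of tests.
#' @return adjusted p-values, capped at 1.
#' @export
bonferroni <- function(p, m = 33) pmin(1, p * m)

#' Screen offtake indicators against the faunal degradation gradient
#'
#' Correlates each of the 33 indicators (community-level values) with the
#' community median Bray-Curtis degradation scores, ranks indicators by
#' `|r|`, and applies a Bonferroni adjustment with `m` fixed at 33 (set
#' `m = NULL` to use the number of indicators actually tested instead).
#' Communities missing an indicator are dropped pairwise for that
#' indicator; indicators with fewer than 3 usable communities are reported
#' as missing with a reason.
#'
#' @param indicators an `"indicator_table"` from [compute_indicators()].
#' @param scores a `"degradation_scores"` from [pairwise_degradation()].
#' @param m Bonferroni multiplier (default 33; `NULL` = number tested).
#' @param alpha significance level, default 0.05.
#' @param method p-value method passed to [pearson_cor()].
#' @param n_perm permutations when `method = "permutation"`.
#' @return object of class `"indicator_screen"`: data.frame with one row
#'   per indicator (`id`, `name`, `expected_trend`, `n`, `r`, `p`,
#'   `p_bonferroni`, `significant_raw`, `significant_adjusted`, `reason`),
#'   ranked by `|r|`; attribute `"scores"` keeps the community ordering.
#' @export
screen_indicators <- function(indicators, scores, m = 33, alpha = 0.05,
                              method = c("t", "permutation"), n_perm = 10000) {
  method <- match.arg(method)
  meta <- indicator_meta()
  med <- setNames(scores$median_bc, scores$community)
  usable <- names(med)[is.finite(med)]
  if (length(usable) < 3)
    stopf("need at least 3 communities with degradation scores, got %d",
          length(usable))
  rows <- lapply(meta$id, function(id) {
    sub <- indicators[indicators$id == id, ]
    val <- setNames(sub$value, sub$community)[usable]
    res <- pearson_cor(val, med[usable], method = method, n_perm = n_perm)
    data.frame(id = id, name = meta$name[meta$id == id],
               expected_trend = meta$expected_trend[meta$id == id],
               n = res$n, r = res$r, p = res$p,
               reason = if (is.na(res$r))
                 sprintf("fewer than 3 usable communities or zero variance (n=%d)", res$n)
               else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m_used <- m %||% sum(!is.na(out$p))
  out$p_bonferroni <- bonferroni(out$p, m_used)
  out$significant_raw <- !is.na(out$p) & out$p <= alpha
  out$significant_adjusted <- !is.na(out$p_bonferroni) & out$p_bonferroni <= alpha
  out <- out[order(-abs(out$r), out$id, na.last = TRUE), ]
  rownames(out) <- NULL
  structure(out, scores = scores, m = m_used, alpha = alpha,
            class = c("indicator_screen", "data.frame"))
}

#' @export
print.indicator_screen <- function(x, digits = 3, max_rows = 10, ...) {
  cat(sprintf("Indicator screen vs faunal degradation (m = %d, alpha = %g)\n",
              attr(x, "m"), attr(x, "alpha")))
  cat(sprintf("  %d significant before adjustment, %d after Bonferroni\n",
              sum(x$significant_raw, na.rm = TRUE),
              sum(x$significant_adjusted, na.rm = TRUE)))
  cols <- c("id", "name", "n", "r", "p", "p_bonferroni", "significant_adjusted")
  print.data.frame(utils::head(as.data.frame(x)[, cols], max_rows),
                   digits = digits, row.names = FALSE)
  if (nrow(x) > max_rows) cat(sprintf("  ... %d more indicators\n", nrow(x) - max_rows))
  invisible(x)
}

#' Screening report
#'
#' Deterministic human- and machine-readable summary of an indicator
#' screen: per-indicator correlation, raw and adjusted p-values, and
#' whether the observed direction matches the hypothesized trend along the
#' gradient; communities are listed in increasing degradation order.
#'
#' @param results an `"indicator_screen"`.
#' @param indicators optionally, the `"indicator_table"` used, echoed into
#'   the report.
#' @return list with `indicators` (data.frame incl. `direction_matches`),
#'   `communities` (ascending median degradation) and `summary` counts.
#' @export
screen_report <- function(results, indicators = NULL) {
  if (nrow(results) == 0) stopf("empty indicator screen")
  scr <- as.data.frame(results)
  scr$direction <- ifelse(is.na(scr$r), NA, ifelse(scr$r > 0, "up", "down"))
  scr$direction_matches <- scr$direction == scr$expected_trend
  scores <- attr(results, "scores")
  list(indicators = scr,
       communities = as.data.frame(scores)[order(scores$median_bc), ],
       summary = c(n_tested = sum(!is.na(scr$p)),
                   n_significant_raw = sum(scr$significant_raw, na.rm = TRUE),
                   n_significant_adjusted = sum(scr$significant_adjusted, na.rm = TRUE)),
       table = if (!is.null(indicators)) as.data.frame(indicators))
}
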