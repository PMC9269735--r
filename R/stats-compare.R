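#' Exclude extreme upper outliers
#'
#' Removes values strictly greater than `Q3 + 3 * IQR` — the extreme-outlier
#' rule, applied to the upper side only. Quartiles use linear interpolation
#' between order statistics (`stats::quantile` type 7); the convention is
#' recorded on the result since reasonable conventions differ.
#'
#' @param values Numeric vector; fewer than 4 values is a no-op with a
#'   warning.
#' @return A list with `kept`, `removed`, `cutoff` and `quantile_type`.
#' @export
exclude_extreme_outliers <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4L) {
    warning("fewer than 4 values: outlier rule not applied")
    return(list(kept = values, removed = numeric(0), cutoff = NA_real_,
                quantile_type = 7L))
  }
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE,
                       na.rm = TRUE)
  cutoff <- q[2] + 3 * (q[2] - q[1])
  out <- values > cutoff
  out[is.na(out)] <- FALSE
  list(kept = values[!out], removed = values[out], cutoff = cutoff,
       quantile_type = 7L)
}

#' Shapiro-Wilk normality check
#'
#' @param values Numeric vector, 3 to 5000 values.
#' @param alpha Significance level; `is_normal` is `p >= alpha`.
#' @return A list with `p`, `is_normal`, `degenerate` (constant input, for
#'   which normality is rejected with `p = NA`).
#' @export
normality_check <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0) {
    return(list(p = NA_real_, is_normal = FALSE, degenerate = TRUE))
  }
  p <- stats::shapiro.test(values)$p.value
  list(p = p, is_normal = p >= alpha, degenerate = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`, with a reporting form rounded half-away-from-zero to three
#' decimals (0.05/4 -> 0.0125, reported 0.013; 0.05/3 -> 0.0167, reported
#' 0.017). Decisions use the exact threshold.
#'
#' @param alpha Family-wise level.
#' @param m Number of comparisons, at least 1.
#' @return A list with `threshold` (exact) and `reported` (3 decimals).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (m < 1) stop("`m` must be at least 1")
  thr <- alpha / m
  list(threshold = thr, reported = round_half_away(thr, 3L))
}

round_half_away <- function(x, digits) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Normality-gated paired pre/post test
#'
#' Tests the change between two visits: the paired differences are checked
#' for normality (Shapiro-Wilk); normal differences get an ordinary paired
#' t-test, non-normal ones a Wilcoxon signed-rank test. Significance is
#' judged against the Bonferroni-corrected level `alpha / m_comparisons`.
#' All-zero differences are reported as statistic 0, p = 1, not
#' significant.
#'
#' @param values_t1,values_t2 Paired measurements at the two visits;
#'   incomplete pairs are dropped, at least 3 complete pairs required.
#' @param m_comparisons Number of comparisons in the family.
#' @param alpha Family-wise level.
#' @return Object of class `prepost_result`: list with `test`
#'   (`"paired-t"` or `"wilcoxon"`), `statistic`, `p`, `alpha_corrected`,
#'   `alpha_reported`, `significant`, `normality_p`, `n`.
#' @export
paired_change_test <- function(values_t1, values_t2, m_comparisons = 1,
                               alpha = 0.05) {
  ok <- stats::complete.cases(values_t1, values_t2)
  x <- as.numeric(values_t1[ok]); y <- as.numeric(values_t2[ok])
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  corr <- bonferroni_alpha(alpha, m_comparisons)
  d <- y - x
  if (all(d == 0)) {
    res <- list(test = "paired-t", statistic = 0, p = 1,
                normality_p = NA_real_)
  } else {
    nc <- normality_check(d, alpha = alpha)
    if (!nc$degenerate && nc$is_normal) {
      tt <- stats::t.test(y, x, paired = TRUE)
      res <- list(test = "paired-t", statistic = unname(tt$statistic),
                  p = tt$p.value, normality_p = nc$p)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(y, x, paired = TRUE,
                                                exact = FALSE))
      res <- list(test = "wilcoxon", statistic = unname(wt$statistic),
                  p = wt$p.value, normality_p = nc$p)
    }
  }
  structure(
    c(res, list(alpha_corrected = corr$threshold,
                alpha_reported = corr$reported,
                significant = res$p < corr$threshold, n = length(x))),
    class = "prepost_result")
}

#' @export
print.prepost_result <- function(x, ...) {
  cat(sprintf("<prepost_result> %s: statistic %.3f, p %.4g (alpha %.4g)%s, n=%d\n",
              x$test, x$statistic, x$p, x$alpha_corrected,
              if (x$significant) " *" else "", x$n))
  invisible(x)
}

classify_strength <- function(r) {
  a <- abs(r)
  if (a < 0.10) "negligible"
  else if (a < 0.40) "weak"
  else if (a < 0.70) "moderate"
  else "strong"
}

#' Pearson agreement between two systems
#'
#' Pearson correlation with a two-tailed p-value, plus a strength label on
#' `|r|`: below 0.10 negligible, 0.10-0.39 weak, 0.40-0.69 moderate,
#' 0.70-1.00 strong.
#'
#' @param x,y Paired numeric vectors; incomplete pairs dropped; at least 3
#'   pairs and non-constant inputs required.
#' @return Object of class `agreement_result`: list with `r`, `p`, `n`,
#'   `strength`.
#' @export
pearson_agreement <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
         strength = classify_strength(unname(ct$estimate))),
    class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("<agreement_result> r=%.3f (%s), p=%.4g, n=%d\n",
              x$r, x$strength, x$p, x$n))
  invisible(x)
}

#' Between-system agreement tables
#'
#' For every task, every unordered pair of systems and every variable
#' shared by both systems, computes the Pearson agreement over
#' pairwise-complete subjects. Variables absent from a system (e.g. step
#' width on the smartphone) simply produce no cell for pairs involving that
#' system. Significance stars: `*` p < 0.05, `**` p < 0.01.
#'
#' @param features Data frame with columns `subject`, `system`, `task`,
#'   `variable`, `value` (long format, one row per measurement).
#' @return A data frame with columns `task`, `system_a`, `system_b`,
#'   `variable`, `n`, `r`, `p`, `strength`, `stars`; class
#'   `agreement_table`.
#' @export
build_agreement_tables <- function(features) {
  needed <- c("subject", "system", "task", "variable", "value")
  if (!all(needed %in% names(features))) {
    stop("`features` must have columns ", paste(needed, collapse = ", "))
  }
  out <- list()
  for (task in unique(features$task)) {
    ft <- features[features$task == task, ]
    systems <- sort(unique(ft$system))
    if (length(systems) < 2L) next
    for (i in seq_len(length(systems) - 1L)) for (j in (i + 1L):length(systems)) {
      sa <- systems[i]; sb <- systems[j]
      va <- unique(ft$variable[ft$system == sa])
      vb <- unique(ft$variable[ft$system == sb])
      for (v in intersect(va, vb)) {
        da <- ft[ft$system == sa & ft$variable == v, c("subject", "value")]
        db <- ft[ft$system == sb & ft$variable == v, c("subject", "value")]
        m <- merge(da, db, by = "subject", suffixes = c("_a", "_b"))
        m <- m[stats::complete.cases(m$value_a, m$value_b), ]
        row <- data.frame(task = task, system_a = sa, system_b = sb,
                          variable = v, n = nrow(m), r = NA_real_,
                          p = NA_real_, strength = NA_character_,
                          stars = "", stringsAsFactors = FALSE)
        if (nrow(m) >= 3L && stats::sd(m$value_a) > 0 && stats::sd(m$value_b) > 0) {
          ag <- pearson_agreement(m$value_a, m$value_b)
          row$r <- ag$r; row$p <- ag$p; row$strength <- ag$strength
          row$stars <- if (ag$p < 0.01) "**" else if (ag$p < 0.05) "*" else ""
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(task = character(0), system_a = character(0),
               system_b = character(0), variable = character(0),
               n = integer(0), r = numeric(0), p = numeric(0),
               strength = character(0), stars = character(0))
  class(res) <- c("agreement_table", class(res))
  res
}
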