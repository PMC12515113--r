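#' Shapiro-Wilk normality check
#'
#' Thin wrapper over the standard Shapiro-Wilk test with the degenerate cases
#' made explicit: fewer than 3 values or an (effectively) constant vector is
#' an error rather than an undefined p-value.
#'
#' @param values numeric vector, n >= 3.
#' @return list with `statistic` and `p`.
#' @export
normality_check <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) stop("normality check needs at least 3 values")
  if (stats::sd(values) == 0)
    stop("normality check undefined for a constant sample")
  r <- stats::shapiro.test(values)
  list(statistic = unname(r$statistic), p = unname(r$p.value))
}

#' Non-parametric two-sample tests
#'
#' `paired_test` is the two-sided Wilcoxon signed-rank test on matched
#' samples; zero differences are discarded (the standard convention) and an
#' all-zero difference vector is a degenerate-case error. `unpaired_test` is
#' the two-sided Mann-Whitney U test for independent groups. Exact p-values
#' are used for n <= 25 when no ties are present, the normal approximation
#' otherwise.
#'
#' @param x,y numeric samples; equal length (matched order) for the paired
#'   test.
#' @return two-sided p-value.
#' @export
paired_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired test needs equal-length samples")
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L)
    stop("degenerate paired comparison: all differences are zero")
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  suppressWarnings(
    stats::wilcox.test(x, y, paired = TRUE, exact = exact)$p.value)
}

#' @rdname paired_test
#' @export
unpaired_test <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("empty sample")
  exact <- length(x) <= 25L && length(y) <= 25L &&
    !any(duplicated(c(x, y)))
  suppressWarnings(stats::wilcox.test(x, y, exact = exact)$p.value)
}

#' Bonferroni-Holm multiple-comparison correction
#'
#' Step-down Holm procedure: monotone adjusted p-values plus rejection
#' decisions at level `alpha`.
#'
#' @param pvalues vector of p-values in \[0, 1\].
#' @param alpha family-wise error level.
#' @return list with `adjusted` (same order as input) and `reject` (logical).
#' @export
holm_adjust <- function(pvalues, alpha = 0.05) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "holm")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Grouped mean +/- sd summary table
#'
#' Summarizes per-case metric values into the standard cohort layout: one
#' row per model variant, one column per dental status plus an overall
#' column, each cell `mean +/- sd` (sample sd, n-1 denominator). Missing
#' groups yield a blank cell with a warning.
#'
#' @param results data.frame with columns `variant`, `dental_status`, and
#'   the metric named by `metric`.
#' @param metric column to summarise.
#' @param digits formatting digits for the text table.
#' @return list with `table` (character matrix, formatted) and `stats`
#'   (data.frame of group n, mean, sd).
#' @export
summarize_results <- function(results, metric = "dsc", digits = 3) {
  if (nrow(results) == 0L) stop("empty result set")
  if (!metric %in% names(results)) stop("no column '", metric, "' in results")
  variants <- unique(results$variant)
  statuses <- unique(results$dental_status)
  cols <- c(as.character(statuses), "overall")
  tab <- matrix("", length(variants), length(cols),
                dimnames = list(as.character(variants), cols))
  rows <- list()
  for (v in variants) {
    for (s in cols) {
      vals <- if (s == "overall") {
        results[[metric]][results$variant == v]
      } else {
        results[[metric]][results$variant == v & results$dental_status == s]
      }
      vals <- vals[is.finite(vals)]
      if (length(vals) == 0L) {
        warning("empty group: variant ", v, ", status ", s)
        next
      }
      m <- mean(vals)
      sdv <- if (length(vals) > 1L) stats::sd(vals) else NA_real_
      tab[as.character(v), s] <- if (is.na(sdv)) {
        formatC(m, digits = digits, format = "f")
      } else {
        paste0(formatC(m, digits = digits, format = "f"), " ± ",
               formatC(sdv, digits = digits, format = "f"))
      }
      rows[[length(rows) + 1L]] <- data.frame(variant = v, dental_status = s,
                                              n = length(vals), mean = m,
                                              sd = sdv)
    }
  }
  list(table = tab, stats = do.call(rbind, rows))
}
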