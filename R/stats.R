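#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (the same convention mainstream statistics
#' software applies), tied absolute differences receive mid-ranks, and the
#' p-value is exact (full null distribution of the signed-rank sum) when at
#' most 15 non-zero differences remain and none are tied; otherwise the
#' normal approximation with tie and continuity correction is used.
#'
#' @param x,y Paired numeric vectors; with `y = NULL`, `x` is taken as the
#'   differences.
#' @return A list: `statistic` (V, the positive-rank sum), `p_value`
#'   (two-tailed, in `[0, 1]`), `n` (non-zero pairs), `exact`, and
#'   `degenerate` (`TRUE` when every difference was zero, in which case
#'   `p_value = 1`).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) as.numeric(x) else {
    stopifnot(length(x) == length(y))
    as.numeric(x) - as.numeric(y)
  }
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1, n = 0L, exact = TRUE,
                degenerate = TRUE))
  }
  ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- n <= 15L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = use_exact, correct = TRUE))
  list(statistic = unname(ht$statistic),
       p_value = min(1, max(0, ht$p.value)),
       n = n, exact = use_exact, degenerate = FALSE)
}

#' Paired t-test
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A list: `t`, `df`, `p_value` (two-tailed), `mean_diff`.
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  d <- as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) stop("differences must be finite", call. = FALSE)
  if (stats::sd(d) == 0) {
    stop("zero-variance differences: the paired t-test is undefined (all pairwise differences equal)",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = mean(d))
}

#' Two-way consistency intraclass correlation
#'
#' ICC from a two-way mixed-effects model without interaction (items
#' random, raters fixed), consistency definition. For the average of the
#' `k` raters, `ICC(C,k) = (MS_items - MS_error) / MS_items`; for a single
#' rater, `ICC(C,1) = (MS_items - MS_error) / (MS_items + (k-1) MS_error)`.
#' Consistency ignores fixed rater offsets: adding a constant to one
#' rater's column leaves the ICC unchanged.
#'
#' @param scores A numeric items x raters matrix, or a [reader_scores()]
#'   object (its sessions are then treated via `session`).
#' @param unit `"average"` (reliability of the mean rating, the default) or
#'   `"single"`.
#' @param session For a `reader_scores` input, which session's item x
#'   reader matrix to use.
#' @return A list: `icc`, `k`, `n`, `unit`, `ms_items`, `ms_error`, and
#'   `classification` (`"poor"` < 0.5, `"moderate"` 0.5-0.75, `"good"`
#'   0.75-0.9, `"excellent"` > 0.9). When there is no between-item variance
#'   the ICC is undefined and returned as flagged `NaN`.
#' @export
icc_consistency <- function(scores, unit = c("average", "single"),
                            session = 1L) {
  unit <- match.arg(unit)
  if (inherits(scores, "reader_scores")) {
    scores <- scores$scores[, , session, drop = TRUE]
  }
  m <- as.matrix(scores)
  storage.mode(m) <- "double"
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("need at least 2 items and 2 raters", call. = FALSE)
  }
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  ms_items <- ssr / (n - 1)
  ms_error <- sse / ((n - 1) * (k - 1))
  if (ms_items <= 0) {
    return(list(icc = NaN, k = k, n = n, unit = unit, ms_items = ms_items,
                ms_error = ms_error, classification = NA_character_,
                undefined = TRUE))
  }
  icc <- if (unit == "average") {
    (ms_items - ms_error) / ms_items
  } else {
    (ms_items - ms_error) / (ms_items + (k - 1) * ms_error)
  }
  cls <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate" else
    if (icc <= 0.9) "good" else "excellent"
  list(icc = icc, k = k, n = n, unit = unit, ms_items = ms_items,
       ms_error = ms_error, classification = cls, undefined = FALSE)
}

#' Shapiro-Wilk normality screen
#'
#' @param x Numeric vector, 3 <= n <= 5000, non-constant.
#' @return A list: `W`, `p_value`.
#' @export
normality_check <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L || length(x) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("constant vector: normality undefined", call. = FALSE)
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p_value = ht$p.value)
}

#' Summary comparison report
#'
#' Builds a per-metric comparison table between two systems, in the layout
#' of the study report: continuous measurements as mean +/- SD with a
#' paired t-test, ordinal reader scores as median and Q1-Q3 IQR (linear
#' interpolation quantiles) with a Wilcoxon signed-rank test; significance
#' flagged at two-tailed p < 0.05.
#'
#' @param measurements Tibble of continuous per-location values with
#'   columns `metric`, `fov`, `system`, `stent`, `location`, `value`;
#'   both systems must cover identical (stent, location) pairs.
#' @param scores Tibble of ordinal scores with columns `metric`, `fov`,
#'   `system`, `item`, `reader`, `session`, `score`; paired on
#'   (item, reader, session).
#' @return A tibble with one row per (metric, fov, system): summary
#'   statistics, test name, two-tailed `p_value` and `significant` flag.
#' @export
summarize_comparison <- function(measurements = NULL, scores = NULL) {
  out <- list()
  if (!is.null(measurements)) {
    for (key in unique(paste(measurements$metric, measurements$fov, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      d <- measurements[measurements$metric == parts[1] &
                          measurements$fov == parts[2], , drop = FALSE]
      out[[length(out) + 1L]] <- .summarize_continuous(d)
    }
  }
  if (!is.null(scores)) {
    for (key in unique(paste(scores$metric, scores$fov, sep = "\r"))) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      d <- scores[scores$metric == parts[1] & scores$fov == parts[2], ,
                  drop = FALSE]
      out[[length(out) + 1L]] <- .summarize_ordinal(d)
    }
  }
  if (length(out) == 0L) stop("nothing to summarize", call. = FALSE)
  do.call(rbind, out)
}

.summarize_continuous <- function(d) {
  systems <- sort(unique(d$system))
  if (length(systems) != 2L) {
    stop("pairing error: expected exactly 2 systems, got ",
         paste(systems, collapse = ", "), call. = FALSE)
  }
  a <- d[d$system == systems[1], ]
  b <- d[d$system == systems[2], ]
  ka <- paste(a$stent, a$location)
  kb <- paste(b$stent, b$location)
  if (nrow(a) != nrow(b) || !setequal(ka, kb) || anyDuplicated(ka)) {
    stop("pairing error: systems do not share identical (stent, location) pairs",
         call. = FALSE)
  }
  b <- b[match(ka, kb), ]
  diffs <- a$value - b$value
  p <- if (stats::sd(diffs) == 0) 1 else paired_t(a$value, b$value)$p_value
  tibble::tibble(
    metric = d$metric[1], fov = d$fov[1], system = systems,
    summary_type = "mean_sd",
    mean = c(mean(a$value), mean(b$value)),
    sd = c(stats::sd(a$value), stats::sd(b$value)),
    median = NA_real_, q1 = NA_real_, q3 = NA_real_,
    n = nrow(a), test = "paired_t", p_value = p, significant = p < 0.05)
}

.summarize_ordinal <- function(d) {
  systems <- sort(unique(d$system))
  if (length(systems) != 2L) {
    stop("pairing error: expected exactly 2 systems, got ",
         paste(systems, collapse = ", "), call. = FALSE)
  }
  a <- d[d$system == systems[1], ]
  b <- d[d$system == systems[2], ]
  ka <- paste(a$item, a$reader, a$session)
  kb <- paste(b$item, b$reader, b$session)
  if (nrow(a) != nrow(b) || !setequal(ka, kb) || anyDuplicated(ka)) {
    stop("pairing error: systems do not share identical (item, reader, session) tuples",
         call. = FALSE)
  }
  b <- b[match(ka, kb), ]
  p <- wilcoxon_signed_rank(a$score, b$score)$p_value
  q <- function(v) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
  qa <- q(a$score); qb <- q(b$score)
  tibble::tibble(
    metric = d$metric[1], fov = d$fov[1], system = systems,
    summary_type = "median_iqr",
    mean = NA_real_, sd = NA_real_,
    median = c(qa[2], qb[2]), q1 = c(qa[1], qb[1]), q3 = c(qa[3], qb[3]),
    n = nrow(a), test = "wilcoxon_signed_rank", p_value = p,
    significant = p < 0.05)
}
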