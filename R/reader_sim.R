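#' Simulate ordinal reader scores
#'
#' Generates 5-point Likert scores from a latent-quality cumulative model:
#' for item i, reader j, session s the score is
#' `1 + #{cut points below latent[i] + bias[j] + noise}`, with i.i.d.
#' Gaussian perceptual noise per (item, reader, session). This is the
#' fixture generator for the reader-statistics layer; no human scores are
#' collected.
#'
#' @param latent_quality_per_item Numeric vector of latent image quality,
#'   one value per item (same scale as `cut_points`).
#' @param reader_bias Numeric vector of per-reader additive bias.
#' @param cut_points Four strictly ascending thresholds mapping the latent
#'   scale to scores 1-5.
#' @param noise_sd Standard deviation of the perceptual noise (>= 0).
#' @param seed Optional integer seed (RNG state preserved).
#' @param n_sessions Number of scoring sessions per reader (2 enables
#'   intra-reader reliability).
#' @param metric_label Label of the scored quality
#'   (`"stent_appearance"`, `"blooming"` or `"inter_stent_visibility"`).
#' @return A `reader_scores` object: integer array items x readers x
#'   sessions with entries in 1..5.
#' @export
simulate_reader_scores <- function(latent_quality_per_item, reader_bias,
                                   cut_points, noise_sd, seed = NULL,
                                   n_sessions = 2L,
                                   metric_label = "stent_appearance") {
  if (length(cut_points) != 4L || any(diff(cut_points) <= 0)) {
    stop("`cut_points` must be 4 strictly ascending values", call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  ni <- length(latent_quality_per_item)
  nr <- length(reader_bias)
  ns <- as.integer(n_sessions)
  stopifnot(ni >= 1L, nr >= 1L, ns >= 1L)
  draw <- function() stats::rnorm(ni * nr * ns, 0, noise_sd)
  eps <- if (noise_sd == 0) {
    rep(0, ni * nr * ns)
  } else if (is.null(seed)) draw() else {
    withr::with_seed(as.integer(seed), draw())
  }
  latent <- array(latent_quality_per_item, c(ni, nr, ns)) +
    array(rep(reader_bias, each = ni), c(ni, nr, ns)) +
    array(eps, c(ni, nr, ns))
  scores <- array(1L + rowSums(outer(c(latent), cut_points, ">")),
                  c(ni, nr, ns))
  reader_scores(scores, metric_label)
}

#' Reader-score container
#'
#' @param scores Integer array items x readers x sessions with entries in
#'   1..5 (a matrix is treated as a single session).
#' @param metric_label Scored quality label.
#' @return An object of class `reader_scores`.
#' @export
reader_scores <- function(scores, metric_label = "stent_appearance") {
  if (is.matrix(scores)) dim(scores) <- c(dim(scores), 1L)
  if (!is.array(scores) || length(dim(scores)) != 3L) {
    stop("`scores` must be an items x readers x sessions array", call. = FALSE)
  }
  if (!all(scores %in% 1:5)) {
    stop("all scores must be integers in 1..5", call. = FALSE)
  }
  metric_label <- match.arg(metric_label,
                            c("stent_appearance", "blooming",
                              "inter_stent_visibility"))
  structure(list(scores = array(as.integer(scores), dim(scores)),
                 metric_label = metric_label),
            class = "reader_scores")
}

#' @export
print.reader_scores <- function(x, ...) {
  d <- dim(x$scores)
  cat(sprintf("<reader_scores> %s: %d items x %d readers x %d sessions\n",
              x$metric_label, d[1], d[2], d[3]))
  print(table(score = c(x$scores)))
  invisible(x)
}
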