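#' Bland-Altman agreement analysis on relative differences
#'
#' Method-agreement analysis for paired measurements of the same quantity by
#' two methods (here, lipid amounts after dual extraction vs. the classical
#' reference extraction). Each pair contributes a *relative* difference
#' \deqn{d_i = (x_i - y_i) / ((x_i + y_i)/2),}
#' the difference as a fraction of the pair average — appropriate when
#' measurement error scales with the measured amount. Agreement is
#' summarized by the bias (mean of \eqn{d}), the sample (n-1) standard
#' deviation of \eqn{d}, and the 95% limits of agreement
#' \eqn{bias \pm 1.96\, s.d.} (a fixed 1.96 multiplier, not a t-quantile).
#' Points outside the limits are flagged.
#'
#' @param x Measurements by the method under evaluation (dual extraction).
#' @param y Paired measurements by the reference method; same length as `x`,
#'   no pair may have `x + y == 0`.
#' @return Object of class `bland_altman`: list with `points` (data.frame:
#'   `x`, `y`, `mean_xy`, `d`, `outside`), `bias`, `sd`, `loa_low`,
#'   `loa_high`, `n`, `n_outside`.
#' @examples
#' ba <- bland_altman(c(10, 12), c(10, 8))
#' ba$bias   # 0.2
#' ba$sd     # 0.28284...
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 paired measurements")
  if (anyNA(x) || anyNA(y)) stop("paired measurements must not contain NA")
  avg <- (x + y) / 2
  if (any(avg == 0)) {
    stop("pair(s) with x + y = 0 (relative difference undefined): index ",
         paste(which(avg == 0), collapse = ", "))
  }
  d <- (x - y) / avg
  bias <- mean(d)
  s <- stats::sd(d)
  loa_low <- bias - 1.96 * s
  loa_high <- bias + 1.96 * s
  outside <- d < loa_low | d > loa_high
  structure(list(
    points = data.frame(x = x, y = y, mean_xy = avg, d = d, outside = outside),
    bias = bias, sd = s, loa_low = loa_low, loa_high = loa_high,
    n = length(x), n_outside = sum(outside)), class = "bland_altman")
}

#' @param percent Display the summary as percentages.
#' @rdname bland_altman
#' @export
print.bland_altman <- function(x, percent = FALSE, ...) {
  f <- if (percent) function(v) sprintf("%.2f%%", 100 * v) else
    function(v) sprintf("%.5f", v)
  cat(sprintf(
    "Bland-Altman (relative differences, n = %d)\n  bias %s, s.d. %s\n  95%% limits of agreement [%s, %s]\n  %d point(s) outside the limits\n",
    x$n, f(x$bias), f(x$sd), f(x$loa_low), f(x$loa_high), x$n_outside))
  invisible(x)
}

#' Estimate the organic-phase volume from a tracer aliquot
#'
#' After a phase separation spiked with a radioactive tracer, the organic
#' phase volume can be estimated without recovering the whole phase: count a
#' small aliquot of known volume, and scale by the fraction of the organic-
#' phase radioactivity the aliquot contains. The organic-phase total is the
#' input minus what stayed in the aqueous phase:
#' \deqn{V_{org} = V_{aliquot} \times \frac{cpm_{input} - cpm_{aqueous}}{cpm_{aliquot}}.}
#' The aqueous fraction \eqn{cpm_{aqueous}/cpm_{input}} is reported as a
#' tracer-partition check (it should be near zero for a lipid tracer).
#'
#' @param aliquot_volume Aliquot volume in microliters.
#' @param aliquot_counts Radioactivity of the aliquot (cpm), > 0.
#' @param input_counts Total radioactivity added (cpm).
#' @param aqueous_counts Radioactivity recovered in the aqueous phase (cpm),
#'   default 0.
#' @return List: `organic_volume` (microliters), `aqueous_fraction`,
#'   `organic_counts`.
#' @examples
#' # 25 uL holding 1/22.4 of the organic-phase counts -> 560 uL
#' estimate_phase_volume(25, 1000, 22400)$organic_volume
#' @export
estimate_phase_volume <- function(aliquot_volume, aliquot_counts,
                                  input_counts, aqueous_counts = 0) {
  if (aliquot_volume <= 0) stop("aliquot_volume must be positive")
  if (aliquot_counts <= 0) stop("aliquot_counts must be positive")
  if (aqueous_counts < 0 || input_counts < aqueous_counts) {
    stop("need input_counts >= aqueous_counts >= 0")
  }
  organic_counts <- input_counts - aqueous_counts
  if (aliquot_counts > organic_counts) {
    stop("aliquot_counts exceed the organic-phase total (impossible partition)")
  }
  list(organic_volume = aliquot_volume * organic_counts / aliquot_counts,
       aqueous_fraction = if (input_counts > 0) aqueous_counts / input_counts else 0,
       organic_counts = organic_counts)
}
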