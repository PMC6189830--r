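#' Inference on observed screen counts
#'
#' After sorting, recovered colonies are typed (e.g. by pigment) and the data
#' reduce to small binomial counts: x positive colonies out of n recovered,
#' against an input spike fraction f. All intervals are exact
#' (Clopper-Pearson) because the observed counts are small (9, 3, even 0);
#' arm comparisons use Fisher's exact test.
#'
#' @name estimation
NULL

#' Estimate hit enrichment from colony counts
#'
#' Point estimate `x / n` for the post-sort hit fraction, its exact
#' two-sided Clopper-Pearson interval, and both transformed to fold
#' enrichment by dividing by the input hit fraction `f`.
#'
#' @param x Positive colonies (0 <= x <= n).
#' @param n Total colonies recovered (> 0).
#' @param f Input hit fraction, e.g. 0.001 for a 1:1000 spike (0 < f <= 1).
#' @param level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` (exact, default) or `"wilson"` (score).
#' @return An object of class `enrichment_estimate`: `x_positive`, `n_total`,
#'   `input_fraction`, `point_fraction`, `point_enrichment`, `ci_low`,
#'   `ci_high` (on the fraction scale), `enrichment_ci_low`,
#'   `enrichment_ci_high`, `level`, `method`.
#' @examples
#' estimate_enrichment(9, 300, 0.001)   # single-cell spike-in arm
#' estimate_enrichment(3, 20, 0.001)    # aggregate arm
#' @export
estimate_enrichment <- function(x, n, f, level = 0.95,
                                method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  .check_xn(x, n)
  stopifnot(is.numeric(f), length(f) == 1L)
  if (f <= 0 || f > 1) stop("`f` must be in (0, 1]", call. = FALSE)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)", call. = FALSE)
  ci <- .binom_ci(x, n, level, method)
  structure(list(
    x_positive = as.integer(x), n_total = as.integer(n),
    input_fraction = f,
    point_fraction = x / n,
    point_enrichment = (x / n) / f,
    ci_low = ci[1], ci_high = ci[2],
    enrichment_ci_low = ci[1] / f, enrichment_ci_high = ci[2] / f,
    level = level, method = method
  ), class = "enrichment_estimate")
}

.check_xn <- function(x, n) {
  stopifnot(is.numeric(x), is.numeric(n), length(x) == 1L, length(n) == 1L)
  if (n < 1 || n != round(n)) stop("`n` must be a positive integer", call. = FALSE)
  if (x < 0 || x > n || x != round(x)) {
    stop("`x` must be an integer in 0..n", call. = FALSE)
  }
}

.binom_ci <- function(x, n, level, method) {
  if (method == "clopper-pearson") {
    as.numeric(stats::binom.test(x, n, conf.level = level)$conf.int)
  } else {
    as.numeric(stats::prop.test(x, n, conf.level = level,
                                correct = FALSE)$conf.int)
  }
}

#' @export
print.enrichment_estimate <- function(x, ...) {
  cat(sprintf("<enrichment_estimate> %d / %d positive (input fraction %g)\n",
              x$x_positive, x$n_total, x$input_fraction))
  cat(sprintf("  post-sort fraction: %.4g  [%.4g, %.4g] (%g%% %s)\n",
              x$point_fraction, x$ci_low, x$ci_high, 100 * x$level, x$method))
  cat(sprintf("  fold enrichment:    %.4g  [%.4g, %.4g]\n",
              x$point_enrichment, x$enrichment_ci_low, x$enrichment_ci_high))
  invisible(x)
}

#' Compare enrichment between two screen arms
#'
#' Ratio of point enrichments (second over first) together with the
#' two-sided p-value of Fisher's exact test on the 2x2 table of positive /
#' negative colonies. Both arms must share the same input hit fraction, so
#' the enrichment ratio equals the ratio of post-sort positive fractions.
#'
#' @param arm1,arm2 [estimate_enrichment()] objects with identical
#'   `input_fraction` (e.g. the single-cell and aggregate arms).
#' @return A list of class `arm_comparison`: `enrichment_ratio` (`arm2` over
#'   `arm1`; `NA` when both point estimates are zero), `p_value`, and the
#'   underlying 2x2 `table`.
#' @examples
#' single <- estimate_enrichment(9, 300, 0.001)
#' aggregate <- estimate_enrichment(3, 20, 0.001)
#' compare_arms(single, aggregate)
#' @export
compare_arms <- function(arm1, arm2) {
  if (!inherits(arm1, "enrichment_estimate") ||
      !inherits(arm2, "enrichment_estimate")) {
    stop("both arguments must be enrichment_estimate objects", call. = FALSE)
  }
  if (arm1$input_fraction != arm2$input_fraction) {
    stop("arms have different input fractions; comparison is not meaningful",
         call. = FALSE)
  }
  tab <- matrix(c(arm1$x_positive, arm1$n_total - arm1$x_positive,
                  arm2$x_positive, arm2$n_total - arm2$x_positive),
                nrow = 2, byrow = TRUE,
                dimnames = list(arm = c("arm1", "arm2"),
                                colony = c("positive", "negative")))
  ratio <- if (arm1$point_fraction == 0 && arm2$point_fraction == 0) {
    NA_real_
  } else if (arm1$point_fraction == 0) {
    Inf
  } else {
    arm2$point_enrichment / arm1$point_enrichment
  }
  p <- stats::fisher.test(tab)$p.value
  structure(list(enrichment_ratio = ratio, p_value = p, table = tab),
            class = "arm_comparison")
}

#' @export
print.arm_comparison <- function(x, ...) {
  cat(sprintf("<arm_comparison> enrichment ratio (arm2 / arm1): %s\n",
              format(x$enrichment_ratio, digits = 4)))
  cat(sprintf("  Fisher exact two-sided p = %.4g\n", x$p_value))
  invisible(x)
}

#' Estimate the per-cell background apoptosis rate
#'
#' Maximum-likelihood estimate `x / n` of the per-cell probability that a
#' null-dosed cell scores apoptotic, with an exact Clopper-Pearson interval.
#'
#' @param x_apoptotic Apoptotic cells observed (0 <= x <= n).
#' @param n_cells Cells assayed (> 0).
#' @param level Confidence level (default 0.95).
#' @return A list of class `rate_estimate`: `rate`, `ci_low`, `ci_high`,
#'   `x`, `n`, `level`.
#' @examples
#' estimate_background(964, 10000)  # ~9.6% background
#' @export
estimate_background <- function(x_apoptotic, n_cells, level = 0.95) {
  .check_xn(x_apoptotic, n_cells)
  ci <- .binom_ci(x_apoptotic, n_cells, level, "clopper-pearson")
  structure(list(rate = x_apoptotic / n_cells, ci_low = ci[1], ci_high = ci[2],
                 x = as.integer(x_apoptotic), n = as.integer(n_cells),
                 level = level),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> %d / %d = %.4g  [%.4g, %.4g] (%g%% exact)\n",
              x$x, x$n, x$rate, x$ci_low, x$ci_high, 100 * x$level))
  invisible(x)
}

#' Enrichment estimates from a simulated event table
#'
#' Convenience wrapper: pools colonies from the positive-sorted units of an
#' event table and estimates enrichment of hit-derived colonies against the
#' input fraction.
#'
#' @param events A droplet event table ([run_screen()] / [read_events()]).
#' @param f Input hit fraction used in the simulation.
#' @param level Confidence level.
#' @return An [estimate_enrichment()] result, or `NULL` (with a message) when
#'   no colonies were recovered from the positive gate.
#' @export
estimate_from_events <- function(events, f, level = 0.95) {
  validate_events(events)
  pos <- events[events$sorted_positive, , drop = FALSE]
  n <- sum(pos$n_colonies_recovered)
  if (n == 0) {
    message("no colonies recovered from the positive gate")
    return(NULL)
  }
  estimate_enrichment(sum(pos$n_positive_colonies), n, f, level)
}
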