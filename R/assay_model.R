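#' Apoptosis readout model for single cells and aggregates
#'
#' Each screening unit (a single mammalian cell, or an aggregate of N cells)
#' is dosed by one bacterial clone. Cells score apoptotic independently with
#' probability `p_background` under a null clone and `p_hit` under a hit
#' clone. An aggregate is called positive when its apoptotic-cell count
#' reaches the sorting threshold; with the mid-size rule that is "at least
#' half the cells apoptotic". Grouping cells into aggregates suppresses the
#' background: a null aggregate rarely reaches the threshold while a hit
#' aggregate almost always does, which is the signal-to-noise advantage
#' quantified by [fold_improvement_vs_single()].
#'
#' @name assay_model
NULL

#' Construct assay parameters
#'
#' @param hit_fraction Fraction `f` of library clones that are true positives
#'   (e.g. 0.001 for a 1:1000 spike-in).
#' @param p_background Per-cell probability a null-dosed cell scores
#'   apoptotic (assay background).
#' @param p_hit Per-cell probability a hit-dosed cell scores apoptotic;
#'   must be >= `p_background`.
#' @param aggregate_size Cells per screening unit `N` (1 = single cells).
#' @param count_model `"binomial"` (exact, cells are a finite set) or
#'   `"poisson"` (the classical approximation for small per-cell rates).
#' @param threshold `"midsize"` for `ceiling(N/2)`, or an explicit integer
#'   count in `1..N`.
#' @return An object of class `assay_params`.
#' @examples
#' assay_params(hit_fraction = 0.001, p_background = 0.10, p_hit = 0.9,
#'              aggregate_size = 12)
#' @export
assay_params <- function(hit_fraction, p_background, p_hit,
                         aggregate_size = 1L,
                         count_model = c("binomial", "poisson"),
                         threshold = "midsize") {
  count_model <- match.arg(count_model)
  stopifnot(is.numeric(hit_fraction), is.numeric(p_background),
            is.numeric(p_hit), is.numeric(aggregate_size))
  if (hit_fraction < 0 || hit_fraction > 1) {
    stop("`hit_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (p_background < 0 || p_hit > 1 || p_background > p_hit) {
    stop("need 0 <= p_background <= p_hit <= 1", call. = FALSE)
  }
  if (aggregate_size < 1 || aggregate_size != round(aggregate_size)) {
    stop("`aggregate_size` must be an integer >= 1", call. = FALSE)
  }
  N <- as.integer(aggregate_size)
  if (identical(threshold, "midsize")) {
    thr <- midsize_threshold(N)
    rule <- "midsize"
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    if (threshold < 1 || threshold > N || threshold != round(threshold)) {
      stop("explicit `threshold` must be an integer in 1..aggregate_size",
           call. = FALSE)
    }
    thr <- as.integer(threshold)
    rule <- "explicit"
  }
  structure(list(hit_fraction = hit_fraction,
                 p_background = p_background,
                 p_hit = p_hit,
                 aggregate_size = N,
                 count_model = count_model,
                 threshold = thr,
                 threshold_rule = rule),
            class = "assay_params")
}

#' @export
print.assay_params <- function(x, ...) {
  cat(sprintf(paste0("<assay_params> f = %g, p_bg = %g, p_hit = %g, N = %d, ",
                     "threshold K >= %d (%s), %s counts\n"),
              x$hit_fraction, x$p_background, x$p_hit, x$aggregate_size,
              x$threshold, x$threshold_rule, x$count_model))
  invisible(x)
}

#' Mid-size sorting threshold
#'
#' An aggregate is called positive when at least half of its cells score
#' apoptotic: the threshold count is `ceiling(N / 2)`. For `N = 1` this
#' reduces to "the cell is apoptotic".
#'
#' @param n_cells Aggregate size `N` (integer >= 1, vectorised).
#' @return Integer threshold(s).
#' @examples
#' midsize_threshold(c(1, 10, 12, 13))
#' @export
midsize_threshold <- function(n_cells) {
  stopifnot(is.numeric(n_cells))
  if (any(n_cells < 1) || any(n_cells != round(n_cells))) {
    stop("`n_cells` must be integer(s) >= 1", call. = FALSE)
  }
  as.integer(ceiling(n_cells / 2))
}

#' Distribution of apoptotic cells in an aggregate
#'
#' Probability mass function of the apoptotic-cell count `K` in an aggregate
#' of `N` cells, each apoptotic independently with probability `p`. The exact
#' model is Binomial(N, p); the Poisson model uses mean `N * p`, which is the
#' classical low-rate approximation (e.g. about 1 expected apoptotic cell in
#' a 10-cell aggregate at 10\% background). The Poisson pmf is reported
#' truncated to `0..N`; its mass above `N` is attached as attribute
#' `truncation_mass`.
#'
#' @param n_cells Aggregate size `N` (>= 1).
#' @param p Per-cell apoptosis probability in \[0, 1\].
#' @param count_model `"binomial"` or `"poisson"`.
#' @return Numeric vector `pmf` of length `N + 1` over `k = 0..N`, with
#'   attribute `truncation_mass` (0 for the binomial model).
#' @examples
#' pmf <- aggregate_count_pmf(10, 0.1)
#' sum((0:10) * pmf)  # mean apoptotic count = 1
#' @export
aggregate_count_pmf <- function(n_cells, p,
                                count_model = c("binomial", "poisson")) {
  count_model <- match.arg(count_model)
  .check_Np(n_cells, p)
  k <- 0:n_cells
  if (count_model == "binomial") {
    pmf <- stats::dbinom(k, n_cells, p)
    trunc <- 0
  } else {
    pmf <- stats::dpois(k, n_cells * p)
    trunc <- stats::ppois(n_cells, n_cells * p, lower.tail = FALSE)
  }
  structure(pmf, truncation_mass = trunc, names = as.character(k))
}

.check_Np <- function(n_cells, p) {
  stopifnot(is.numeric(n_cells), is.numeric(p))
  if (any(n_cells < 1) || any(n_cells != round(n_cells))) {
    stop("`n_cells` must be integer(s) >= 1", call. = FALSE)
  }
  if (any(p < 0) || any(p > 1)) stop("`p` must be in [0, 1]", call. = FALSE)
}

#' Probability an aggregate is called positive
#'
#' Upper tail `P(K >= threshold)` of the apoptotic-count distribution. With
#' `p = p_background` this is the per-unit false-positive (sorting) rate;
#' with `p = p_hit` it is the per-unit sensitivity.
#'
#' @inheritParams aggregate_count_pmf
#' @param threshold Count threshold in `1..n_cells`.
#' @return Probability in \[0, 1\]. Vectorised over `p`.
#' @examples
#' aggregate_positive_prob(10, 0.1, 5)  # null 10-cell aggregate, mid-size gate
#' @export
aggregate_positive_prob <- function(n_cells, p, threshold,
                                    count_model = c("binomial", "poisson")) {
  count_model <- match.arg(count_model)
  .check_Np(n_cells, p)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold < 1 || threshold > n_cells || threshold != round(threshold)) {
    stop("`threshold` must be an integer in 1..n_cells", call. = FALSE)
  }
  if (count_model == "binomial") {
    stats::pbinom(threshold - 1, n_cells, p, lower.tail = FALSE)
  } else {
    stats::ppois(threshold - 1, n_cells * p, lower.tail = FALSE)
  }
}

#' Expected apoptotic cells per aggregate under background alone
#'
#' @param n_cells Aggregate size `N`.
#' @param p_background Per-cell background apoptosis probability.
#' @return Expected count `N * p_background`.
#' @examples
#' expected_apoptotic_per_aggregate(10, 0.1)  # 1 cell on average
#' @export
expected_apoptotic_per_aggregate <- function(n_cells, p_background) {
  .check_Np(n_cells, p_background)
  n_cells * p_background
}

#' Hit fraction among sorted-positive units
#'
#' If a fraction `f` of units is hit-dosed, hits sort positive with
#' probability `S_hit` and nulls with probability `S_null`, then by Bayes'
#' rule the post-sort hit fraction is
#' \deqn{\frac{f S_{hit}}{f S_{hit} + (1 - f) S_{null}}.}
#' This is the quantity measured experimentally as the fraction of recovered
#' colonies that carry the active pathway.
#'
#' @param f Input hit fraction in \[0, 1\].
#' @param s_hit Per-unit probability a hit-dosed unit sorts positive.
#' @param s_null Per-unit probability a null-dosed unit sorts positive.
#' @return Post-sort hit fraction, or `NA` with a warning when no units sort
#'   positive at all (`f * s_hit + (1 - f) * s_null = 0`).
#' @examples
#' post_sort_positive_fraction(0.001, 1, 0.1)
#' @export
post_sort_positive_fraction <- function(f, s_hit, s_null) {
  stopifnot(is.numeric(f), is.numeric(s_hit), is.numeric(s_null))
  if (any(f < 0 | f > 1) || any(s_hit < 0 | s_hit > 1) ||
      any(s_null < 0 | s_null > 1)) {
    stop("`f`, `s_hit`, `s_null` must be probabilities in [0, 1]",
         call. = FALSE)
  }
  denom <- f * s_hit + (1 - f) * s_null
  out <- ifelse(denom > 0, f * s_hit / denom, NA_real_)
  if (anyNA(out)) {
    warning("no positives: f * s_hit + (1 - f) * s_null = 0; returning NA",
            call. = FALSE)
  }
  out
}

#' Fold enrichment of hits in one sorting cycle
#'
#' Post-sort hit fraction divided by the input hit fraction `f`. Equals 1
#' when the readout is uninformative (`s_hit == s_null`) and approaches
#' `1 / f` as the background sorting rate vanishes.
#'
#' @inheritParams post_sort_positive_fraction
#' @return Fold enrichment (>= 0), `NA` when nothing sorts positive.
#' @examples
#' fold_enrichment(0.001, 1, 0.1)
#' @export
fold_enrichment <- function(f, s_hit, s_null) {
  if (any(f <= 0)) stop("`f` must be > 0 for fold enrichment", call. = FALSE)
  post_sort_positive_fraction(f, s_hit, s_null) / f
}

#' Enrichment improvement of aggregates over single cells
#'
#' Fold enrichment achievable with aggregates of `n_cells` cells at the
#' mid-size threshold, relative to the fold enrichment with single cells
#' (N = 1, threshold 1) at the same per-cell probabilities. Equals 1 at
#' `n_cells = 1` by construction and grows with aggregate size whenever
#' `p_hit > p_background`: larger aggregates average away the background.
#'
#' @param n_cells Aggregate size `N` (vectorised).
#' @param p_background,p_hit Per-cell apoptosis probabilities
#'   (null and hit dosing).
#' @param f Input hit fraction (> 0).
#' @param count_model `"binomial"` or `"poisson"`.
#' @return Fold improvement(s) relative to single-cell sorting.
#' @examples
#' fold_improvement_vs_single(c(1, 6, 12), 0.1, 0.9, 0.001)
#' @export
fold_improvement_vs_single <- function(n_cells, p_background, p_hit, f,
                                       count_model = c("binomial", "poisson")) {
  count_model <- match.arg(count_model)
  .check_Np(n_cells, p_background)
  .check_Np(n_cells, p_hit)
  single <- fold_enrichment(f, p_hit, p_background)
  vapply(n_cells, function(N) {
    thr <- midsize_threshold(N)
    s_hit <- aggregate_positive_prob(N, p_hit, thr, count_model)
    s_null <- aggregate_positive_prob(N, p_background, thr, count_model)
    fold_enrichment(f, s_hit, s_null) / single
  }, numeric(1))
}

#' Aggregate-size enrichment curve
#'
#' Tabulates, for each aggregate size, the mid-size threshold, per-unit
#' sensitivity and background sorting rate, one-cycle fold enrichment and
#' the fold improvement over single-cell sorting.
#'
#' @inheritParams fold_improvement_vs_single
#' @return A data frame with columns `n_cells`, `threshold`, `s_hit`,
#'   `s_null`, `enrichment`, `fold_improvement`.
#' @examples
#' enrichment_curve(c(1, 2, 5, 10, 12), 0.1, 0.9, 0.001)
#' @export
enrichment_curve <- function(n_cells, p_background, p_hit, f,
                             count_model = c("binomial", "poisson")) {
  count_model <- match.arg(count_model)
  thr <- midsize_threshold(n_cells)
  s_hit <- mapply(aggregate_positive_prob, n_cells = n_cells, threshold = thr,
                  MoreArgs = list(p = p_hit, count_model = count_model))
  s_null <- mapply(aggregate_positive_prob, n_cells = n_cells, threshold = thr,
                   MoreArgs = list(p = p_background, count_model = count_model))
  data.frame(n_cells = as.integer(n_cells),
             threshold = thr,
             s_hit = s_hit,
             s_null = s_null,
             enrichment = fold_enrichment(f, s_hit, s_null),
             fold_improvement = fold_improvement_vs_single(
               n_cells, p_background, p_hit, f, count_model))
}
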