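#' Monte Carlo simulator of the droplet screening workflow
#'
#' `run_screen()` simulates one pass of the screen: monoclonal encapsulation
#' of a spiked library, merging with mammalian-cell droplets, the apoptosis
#' readout, threshold sorting, and colony recovery from sorted units. It is
#' the stochastic twin of the analytic quantities in the assay model, and the
#' two are required to agree in expectation (see the package tests).
#'
#' @name screen_sim
NULL

#' Construct a screen configuration
#'
#' @param assay An [assay_params()] object.
#' @param loading A [loading_model()] for the bacterial library (or a bare
#'   numeric \eqn{\lambda}).
#' @param n_droplets Number of bacterial-library droplets generated.
#' @param cell_count_model `"fixed"`: every merged droplet holds exactly
#'   `assay$aggregate_size` cells; `"poisson"`: Poisson with that mean
#'   (zero-cell droplets then carry no readout and are dropped).
#' @param merge_pairing_efficiency Probability an occupied bacterial droplet
#'   is successfully paired and fused with a cell droplet.
#' @param colony_recovery_rate Expected colonies recovered per sorted unit
#'   (Poisson). A calibration parameter, not an instrument constant.
#' @param sorter_rate Sorter throughput in events per second (`NA` if
#'   walltime accounting is not wanted).
#' @param seed Integer seed; the whole simulation is deterministic given the
#'   configuration and seed.
#' @return An object of class `screen_config`.
#' @examples
#' cfg <- screen_config(
#'   assay = assay_params(0.001, 0.10, 0.9, aggregate_size = 12),
#'   loading = loading_model(lambda_for_occupancy(0.10)),
#'   n_droplets = 5000, sorter_rate = 50, seed = 1)
#' @export
screen_config <- function(assay, loading, n_droplets,
                          cell_count_model = c("fixed", "poisson"),
                          merge_pairing_efficiency = 1,
                          colony_recovery_rate = 0.03,
                          sorter_rate = NA_real_,
                          seed = 1L) {
  cell_count_model <- match.arg(cell_count_model)
  if (!inherits(assay, "assay_params")) {
    stop("`assay` must be an assay_params object", call. = FALSE)
  }
  if (!inherits(loading, "loading_model")) loading <- loading_model(loading)
  stopifnot(is.numeric(n_droplets), length(n_droplets) == 1L)
  if (n_droplets < 0 || n_droplets != round(n_droplets)) {
    stop("`n_droplets` must be a non-negative integer", call. = FALSE)
  }
  if (merge_pairing_efficiency < 0 || merge_pairing_efficiency > 1) {
    stop("`merge_pairing_efficiency` must be in [0, 1]", call. = FALSE)
  }
  if (colony_recovery_rate < 0) {
    stop("`colony_recovery_rate` must be >= 0", call. = FALSE)
  }
  if (!is.na(sorter_rate) && sorter_rate <= 0) {
    stop("`sorter_rate` must be > 0 (or NA)", call. = FALSE)
  }
  structure(list(assay = assay, loading = loading,
                 n_droplets = as.integer(n_droplets),
                 cell_count_model = cell_count_model,
                 merge_pairing_efficiency = merge_pairing_efficiency,
                 colony_recovery_rate = colony_recovery_rate,
                 sorter_rate = sorter_rate,
                 seed = as.integer(seed)),
            class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat(sprintf("<screen_config> %d droplets, lambda = %.4g, seed = %d\n",
              x$n_droplets, x$loading$mean_per_droplet, x$seed))
  print(x$assay)
  invisible(x)
}

#' Run a Monte Carlo screen
#'
#' Stage order: (1) Poisson bacterial loading and clone identity (a droplet
#' with k bacteria is hit-dosed with probability \eqn{1 - (1-f)^k}: any hit
#' occupant suffices); (2) mammalian cell counts per merged droplet;
#' (3) merge pairing (unpaired occupied droplets are dropped); (4) apoptotic
#' counts given clone identity; (5) threshold sorting; (6) Poisson colony
#' recovery per sorted unit, recovered colonies positive iff the clone is a
#' hit. Empty bacterial droplets carry no readout and are tallied
#' separately. With the `"poisson"` count model, apoptotic draws are clamped
#' at the cell count so events remain internally consistent.
#'
#' @param config A [screen_config()].
#' @return A list of class `screen_run` with `events` (one row per
#'   non-empty bacterial droplet; columns `droplet_id`, `clone`, `n_cells`,
#'   `n_apoptotic`, `sorted_positive`, `n_colonies_recovered`,
#'   `n_positive_colonies`) and `summary` (a `screen_result`, see
#'   [screen_summary()]).
#' @examples
#' cfg <- screen_config(assay_params(0.001, 0.10, 0.9, aggregate_size = 12),
#'                      lambda_for_occupancy(0.10), 2000, seed = 7)
#' res <- run_screen(cfg)
#' res$summary
#' @export
run_screen <- function(config) {
  if (!inherits(config, "screen_config")) {
    stop("`config` must be a screen_config object", call. = FALSE)
  }
  a <- config$assay
  with_seed(config$seed, {
    k_bact <- stats::rpois(config$n_droplets, config$loading$mean_per_droplet)
    occupied <- which(k_bact > 0)
    n_empty <- config$n_droplets - length(occupied)

    # clone identity: any hit occupant makes the droplet hit-dosed
    p_hit_droplet <- 1 - (1 - a$hit_fraction)^k_bact[occupied]
    is_hit <- stats::runif(length(occupied)) < p_hit_droplet

    # merge pairing
    paired <- stats::runif(length(occupied)) < config$merge_pairing_efficiency
    n_dropped <- sum(!paired)
    idx <- occupied[paired]
    is_hit <- is_hit[paired]

    # mammalian cell counts
    n_units <- length(idx)
    if (config$cell_count_model == "fixed") {
      n_cells <- rep(a$aggregate_size, n_units)
    } else {
      n_cells <- stats::rpois(n_units, a$aggregate_size)
      nonzero <- n_cells > 0
      n_dropped <- n_dropped + sum(!nonzero)
      idx <- idx[nonzero]; is_hit <- is_hit[nonzero]
      n_cells <- n_cells[nonzero]
      n_units <- length(idx)
    }

    # apoptosis readout
    p_cell <- ifelse(is_hit, a$p_hit, a$p_background)
    if (a$count_model == "binomial") {
      n_apop <- stats::rbinom(n_units, n_cells, p_cell)
    } else {
      n_apop <- pmin(stats::rpois(n_units, n_cells * p_cell), n_cells)
    }

    # threshold sorting (threshold clamped to the actual unit size when
    # Poisson cell counts make a unit smaller than the nominal aggregate)
    thr <- pmin(a$threshold, n_cells)
    sorted_pos <- n_apop >= thr

    # colony recovery from every sorted unit (both gates are plated)
    n_col <- stats::rpois(n_units, config$colony_recovery_rate)
    n_pos_col <- ifelse(is_hit, n_col, 0L)

    events <- data.frame(
      droplet_id = idx,
      clone = ifelse(is_hit, "hit", "null"),
      n_cells = as.integer(n_cells),
      n_apoptotic = as.integer(n_apop),
      sorted_positive = sorted_pos,
      n_colonies_recovered = as.integer(n_col),
      n_positive_colonies = as.integer(n_pos_col),
      stringsAsFactors = FALSE
    )
  })
  summary <- screen_summary(events, n_empty = n_empty, n_dropped = n_dropped,
                            sorter_rate = config$sorter_rate)
  structure(list(events = events, summary = summary, config = config),
            class = "screen_run")
}

#' Summarise a screen event table
#'
#' @param events A droplet event table as produced by [run_screen()] (or
#'   read back with [read_events()]).
#' @param n_empty Number of empty bacterial droplets not in the table.
#' @param n_dropped Number of occupied droplets lost at merge pairing.
#' @param sorter_rate Events per second for walltime accounting (`NA` to skip).
#' @return A list of class `screen_result`: sorted counts, colony counts per
#'   arm, the observed post-sort hit fraction, false-negative count, and
#'   estimated sorter walltime in seconds.
#' @export
screen_summary <- function(events, n_empty = 0L, n_dropped = 0L,
                           sorter_rate = NA_real_) {
  validate_events(events)
  pos <- events$sorted_positive
  hit <- events$clone == "hit"
  n_pos <- sum(pos)
  res <- list(
    n_units = nrow(events),
    n_empty = as.integer(n_empty),
    n_dropped = as.integer(n_dropped),
    n_sorted_positive = n_pos,
    n_sorted_negative = nrow(events) - n_pos,
    n_colonies_positive_arm = sum(events$n_colonies_recovered[pos]),
    n_positive_colonies_positive_arm = sum(events$n_positive_colonies[pos]),
    n_colonies_negative_arm = sum(events$n_colonies_recovered[!pos]),
    n_positive_colonies_negative_arm = sum(events$n_positive_colonies[!pos]),
    observed_post_sort_fraction =
      if (n_pos > 0) sum(hit & pos) / n_pos else NA_real_,
    false_negative_count = count_false_negatives(events),
    estimated_sort_walltime =
      if (is.na(sorter_rate)) NA_real_ else sort_walltime(nrow(events), sorter_rate)
  )
  structure(res, class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d units sorted (+%d empty, %d dropped)\n",
              x$n_units, x$n_empty, x$n_dropped))
  cat(sprintf("  positive gate: %d units, %d colonies (%d hit-positive)\n",
              x$n_sorted_positive, x$n_colonies_positive_arm,
              x$n_positive_colonies_positive_arm))
  cat(sprintf("  negative gate: %d units, %d colonies (%d hit-positive)\n",
              x$n_sorted_negative, x$n_colonies_negative_arm,
              x$n_positive_colonies_negative_arm))
  cat(sprintf("  post-sort hit fraction: %s; false negatives: %d\n",
              format(x$observed_post_sort_fraction, digits = 4),
              x$false_negative_count))
  if (!is.na(x$estimated_sort_walltime)) {
    cat(sprintf("  sorter walltime: %.1f s\n", x$estimated_sort_walltime))
  }
  invisible(x)
}

#' Sorter walltime
#'
#' Time to pass `n_events` units through a sorter running at `sorter_rate`
#' events per second. Large-particle sorters are slow (tens of events per
#' second), so this is a real design constraint for aggregate screens.
#'
#' @param n_events Number of sorted events (>= 0).
#' @param sorter_rate Events per second (> 0).
#' @return Seconds.
#' @examples
#' sort_walltime(1000, 50)
#' @export
sort_walltime <- function(n_events, sorter_rate) {
  stopifnot(is.numeric(n_events), is.numeric(sorter_rate))
  if (any(n_events < 0)) stop("`n_events` must be >= 0", call. = FALSE)
  if (any(sorter_rate <= 0)) stop("`sorter_rate` must be > 0", call. = FALSE)
  n_events / sorter_rate
}

#' Count screen false negatives
#'
#' Hit-dosed units sorted into the negative gate. With near-saturating
#' `p_hit` and the mid-size threshold this is expected to be very rare,
#' matching the observation that recovering hundreds of negative aggregates
#' yields no hidden hits.
#'
#' @param events A droplet event table.
#' @return Integer count.
#' @export
count_false_negatives <- function(events) {
  validate_events(events)
  sum(events$clone == "hit" & !events$sorted_positive)
}
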