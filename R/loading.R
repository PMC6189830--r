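#' Poisson encapsulation statistics
#'
#' Random co-flow encapsulation of a dilute particle suspension puts a
#' Poisson-distributed number of particles in each droplet. To keep droplets
#' monoclonal, libraries are loaded so that only a small fraction of droplets
#' is occupied; the functions here translate between the loading intensity
#' \eqn{\lambda} (mean particles per droplet), droplet occupancy, and the
#' fraction of occupied droplets that are clonal (exactly one particle).
#'
#' @name loading
NULL

#' Construct a Poisson loading model
#'
#' @param mean_per_droplet Expected particles per droplet (\eqn{\lambda} >= 0).
#' @param particle_kind `"bacterium"` or `"mammalian_cell"`.
#' @return An object of class `loading_model`.
#' @examples
#' loading_model(lambda_for_occupancy(0.10))
#' @export
loading_model <- function(mean_per_droplet,
                          particle_kind = c("bacterium", "mammalian_cell")) {
  particle_kind <- match.arg(particle_kind)
  stopifnot(length(mean_per_droplet) == 1L, is.numeric(mean_per_droplet))
  if (!is.finite(mean_per_droplet) || mean_per_droplet < 0) {
    stop("`mean_per_droplet` must be finite and >= 0", call. = FALSE)
  }
  structure(list(mean_per_droplet = mean_per_droplet,
                 particle_kind = particle_kind),
            class = "loading_model")
}

# accept either a loading_model or a bare numeric lambda
.lambda_of <- function(model) {
  if (inherits(model, "loading_model")) return(model$mean_per_droplet)
  stopifnot(is.numeric(model), length(model) == 1L)
  model
}

#' Fraction of droplets containing at least one particle
#'
#' For Poisson loading at intensity \eqn{\lambda}, the occupancy is
#' \eqn{1 - e^{-\lambda}}.
#'
#' @param model A `loading_model` or a numeric \eqn{\lambda}.
#' @return Occupied fraction in \[0, 1\].
#' @examples
#' occupancy_fraction(0.1)  # just under the 10% monoclonality bound
#' @export
occupancy_fraction <- function(model) {
  lambda <- .lambda_of(model)
  if (!is.finite(lambda) || lambda < 0) {
    stop("lambda must be finite and >= 0", call. = FALSE)
  }
  -expm1(-lambda)
}

#' Fraction of occupied droplets containing exactly one particle
#'
#' \eqn{P(K = 1 \mid K \ge 1) = \lambda e^{-\lambda} / (1 - e^{-\lambda})};
#' tends to 1 as \eqn{\lambda \to 0}, which is why libraries are loaded
#' dilutely to keep droplets monoclonal.
#'
#' @inheritParams occupancy_fraction
#' @return Clonal fraction in (0, 1\].
#' @export
clonal_fraction <- function(model) {
  lambda <- .lambda_of(model)
  if (!is.finite(lambda) || lambda <= 0) {
    stop("lambda must be finite and > 0", call. = FALSE)
  }
  lambda * exp(-lambda) / (-expm1(-lambda))
}

#' Multiplet fraction among occupied droplets
#'
#' Complement of [clonal_fraction()]: \eqn{P(K \ge 2 \mid K \ge 1)}.
#'
#' @inheritParams occupancy_fraction
#' @return Multiplet fraction in \[0, 1).
#' @export
multiplet_fraction <- function(model) {
  1 - clonal_fraction(model)
}

#' Loading intensity achieving a target occupancy
#'
#' Inverse of [occupancy_fraction()]: \eqn{\lambda = -\ln(1 - occupancy)}.
#' Used to load a library at the chosen occupancy bound (for example 10\%
#' occupied droplets).
#'
#' @param target_occupancy Desired occupied fraction, in \[0, 1).
#' @return \eqn{\lambda} (mean particles per droplet).
#' @examples
#' lambda_for_occupancy(0.10)
#' @export
lambda_for_occupancy <- function(target_occupancy) {
  stopifnot(is.numeric(target_occupancy))
  if (any(!is.finite(target_occupancy)) ||
      any(target_occupancy < 0) || any(target_occupancy >= 1)) {
    stop("`target_occupancy` must be in [0, 1)", call. = FALSE)
  }
  -log1p(-target_occupancy)
}

#' Summary of a loading model
#'
#' @inheritParams occupancy_fraction
#' @return A data frame with columns `lambda`, `occupancy`, `clonal_fraction`,
#'   `multiplet_fraction` (the clonal/multiplet columns are `NA` at
#'   \eqn{\lambda = 0}).
#' @export
loading_stats <- function(model) {
  lambda <- .lambda_of(model)
  occ <- occupancy_fraction(lambda)
  if (lambda > 0) {
    cf <- clonal_fraction(lambda)
  } else {
    cf <- NA_real_
  }
  data.frame(lambda = lambda, occupancy = occ,
             clonal_fraction = cf, multiplet_fraction = 1 - cf)
}

#' Sample per-droplet particle counts
#'
#' Draws i.i.d. Poisson(\eqn{\lambda}) particle counts for `n_droplets`
#' droplets. Reproducible: the global RNG state is saved, seeded with `seed`,
#' and restored afterwards, so the same `(model, n_droplets, seed)` always
#' yields the same sequence and the caller's RNG stream is untouched.
#'
#' @inheritParams occupancy_fraction
#' @param n_droplets Number of droplets (>= 0).
#' @param seed Integer seed.
#' @return Integer vector of length `n_droplets`.
#' @examples
#' counts <- sample_counts(0.1, 1000, seed = 1)
#' mean(counts > 0)
#' @export
sample_counts <- function(model, n_droplets, seed) {
  lambda <- .lambda_of(model)
  stopifnot(length(n_droplets) == 1L, n_droplets >= 0)
  with_seed(seed, stats::rpois(n_droplets, lambda))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(length(seed) == 1L, is.numeric(seed), seed == round(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
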