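#' Integrate stage estimates into a susceptibility distribution
#'
#' Monte Carlo propagation of stage-wise uncertainty into an overall
#' colonization probability. Each stage's logit-scale estimate is treated as
#' Normal(logit_mean, logit_se); per draw, one value is sampled from each of
#' the three stage distributions, back-transformed to a probability, and the
#' three probabilities are multiplied:
#' \deqn{S = \prod_{j=1}^{3} \mathrm{logit}^{-1}(\mu_j + \sigma_j Z_j),
#'       \quad Z_j \sim N(0,1) \textrm{ independent.}}
#' Multiplication happens on the probability scale (multiplying logits has no
#' probabilistic meaning for a product of stage-passage probabilities).
#' Stages are assumed independent; no correlation structure is modeled.
#'
#' The standard-normal draws are generated before being scaled by the stage
#' parameters, so two calls with the same seed and `n_draws` share their
#' random numbers: raising one stage's logit mean under a common seed raises
#' every draw (common-random-number monotone coupling). In the zero-variance
#' limit every draw equals the product of the back-transformed means.
#'
#' @param stages list of exactly three [stage_estimate()]s (or
#'   `proportion_estimate`s) for one species, in any order — the draw
#'   distribution is order-invariant.
#' @param n_draws number of Monte Carlo draws (default 100,000).
#' @param seed integer seed; per-species reproducibility is obtained by
#'   passing [substream_seed()] of a master seed and the species label.
#' @param keep_draws keep the raw draw vector in the result.
#' @return object of class `susceptibility_mc` with `species`, `n_draws`,
#'   `seed`, `draws` (if kept), `median`, `lower_2_5`, `upper_97_5`,
#'   `mean`, and `point_product` (the zero-variance product of
#'   back-transformed logit means).
#' @examples
#' st <- lapply(c("bark", "phloem", "brood"), function(s)
#'   stage_estimate("ponderosa", s, qlogis(0.7), 0.2))
#' integrate_susceptibility(st, n_draws = 1000, seed = 1)
#' @export
integrate_susceptibility <- function(stages, n_draws = 100000L, seed = 1L,
                                     keep_draws = TRUE) {
  if (length(stages) != 3L) stop("exactly three stage estimates required")
  est <- lapply(stages, function(s) {
    if (inherits(s, "stage_estimate")) s$estimate
    else if (inherits(s, "proportion_estimate")) s
    else stop("stages must be stage_estimate or proportion_estimate objects")
  })
  mu <- vapply(est, function(e) e$logit_mean, numeric(1))
  sg <- vapply(est, function(e) e$logit_se, numeric(1))
  if (any(!is.finite(mu)) || any(!is.finite(sg)))
    stop("stage logit means and SEs must be finite")
  if (any(sg < 0)) stop("negative logit SE")
  species <- if (inherits(stages[[1]], "stage_estimate"))
    stages[[1]]$species else NA_character_
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) stop("n_draws must be >= 1")

  draws <- with_seed(seed, {
    z <- matrix(stats::rnorm(3L * n_draws), nrow = n_draws)
    # scale/shift after drawing: common random numbers across parameter sets
    stats::plogis(sweep(sweep(z, 2, sg, "*"), 2, mu, "+"))
  })
  s <- draws[, 1] * draws[, 2] * draws[, 3]
  qs <- stats::quantile(s, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(list(
    species = species, n_draws = n_draws, seed = seed,
    draws = if (keep_draws) s else NULL,
    median = qs[2], lower_2_5 = qs[1], upper_97_5 = qs[3],
    mean = mean(s),
    point_product = prod(stats::plogis(mu))), class = "susceptibility_mc")
}

#' Truncate a draw vector to its middle band
#'
#' Computes the lower and upper empirical percentiles (linear interpolation
#' between order statistics, i.e. `quantile type = 7`; the convention is
#' configurable via `type`) and returns the draws strictly inside them —
#' the "middle 95%" display band of a susceptibility distribution.
#'
#' @param draws non-empty numeric vector.
#' @param lower_pct,upper_pct percentile bounds in [0, 100].
#' @param type quantile convention passed to [stats::quantile()].
#' @return list with `lower`, `upper`, `retained` (draws strictly inside the
#'   bounds; with a degenerate distribution, all draws).
#' @examples
#' truncate_middle(1:100)  # bounds 3.475, 97.525
#' @export
truncate_middle <- function(draws, lower_pct = 2.5, upper_pct = 97.5,
                            type = 7) {
  if (length(draws) == 0L) stop("empty draws")
  if (!(lower_pct >= 0 && lower_pct < upper_pct && upper_pct <= 100))
    stop("need 0 <= lower_pct < upper_pct <= 100")
  q <- stats::quantile(draws, c(lower_pct, upper_pct) / 100, names = FALSE,
                       type = type)
  retained <- if (q[1] == q[2]) draws[draws == q[1]]
              else draws[draws > q[1] & draws < q[2]]
  list(lower = q[1], upper = q[2], retained = retained)
}

#' Summarize a susceptibility distribution as one table row
#'
#' @param dist a `susceptibility_mc` object.
#' @return one-row `data.frame`: `species`, `median`, `lo95`, `hi95`,
#'   `point_product`, `n_draws`, `seed`.
#' @export
summarize_susceptibility <- function(dist) {
  stopifnot(inherits(dist, "susceptibility_mc"))
  data.frame(species = dist$species, median = dist$median,
             lo95 = dist$lower_2_5, hi95 = dist$upper_97_5,
             point_product = dist$point_product,
             n_draws = dist$n_draws, seed = dist$seed,
             stringsAsFactors = FALSE)
}

#' @export
print.susceptibility_mc <- function(x, ...) {
  cat(sprintf(
    "susceptibility [%s]: median %.4f, middle 95%% (%.4f, %.4f)\n",
    if (is.na(x$species)) "?" else x$species,
    x$median, x$lower_2_5, x$upper_97_5))
  cat(sprintf("  point product %.4f, %d draws, seed %d\n",
              x$point_product, x$n_draws, x$seed))
  invisible(x)
}

#' @export
summary.susceptibility_mc <- function(object, ...) {
  summarize_susceptibility(object)
}
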