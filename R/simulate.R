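#' Simulate colonization-trial records for one stage
#'
#' Draws one row per assay unit. For every species, tree and unit, the
#' success probability is the inverse logit of the species' stage intercept
#' plus the phloem-thickness effect plus Gaussian tree and unit random
#' effects. Success counts are drawn by thresholding per-beetle uniforms
#' against the unit probability, so that under a common seed a higher
#' intercept can never yield a lower success count (monotone coupling).
#'
#' The random-number consumption order is fixed by the design alone
#' (tree effects, then per-tree thickness, then unit effects, then per-beetle
#' uniforms), so two parameter sets with the same design and seed share
#' their random numbers.
#'
#' @param params a [colonization_params()] object.
#' @param stage `"bark"`, `"phloem"` or `"brood"`.
#' @param seed integer seed; equal (params, stage, seed) gives identical
#'   output.
#' @return a `data.frame` of trial records with columns `stage`, `year`,
#'   `species`, `host_class`, `tree_id`, `unit_id`, `n_exposed`, `n_success`,
#'   `phloem_mm`, `paired_male`.
#' @examples
#' p <- colonization_params(sd_tree = 0, sd_unit = 0)
#' head(simulate_colonization(p, "bark", seed = 1))
#' @export
simulate_colonization <- function(params, stage, seed) {
  stopifnot(inherits(params, "colonization_params"))
  check_stage(stage)
  beta0 <- params$stage_intercepts[, stage]
  if (any(!is.finite(beta0))) stop("non-finite stage intercepts")

  with_seed(substream_seed(seed, paste0("col-", stage)), {
    rows <- list()
    for (d in params$design) {
      for (si in seq_along(params$species)) {
        sp <- params$species[si]
        for (tr in seq_len(d$trees_per_species)) {
          u_tree <- stats::rnorm(1, 0, params$sd_tree)
          mm_tree <- stats::rnorm(1, params$phloem_mean[si],
                                  params$phloem_sd[si])
          mm_tree <- max(mm_tree, 0.1)  # thickness is physically positive
          u_units <- stats::rnorm(d$units_per_tree, 0, params$sd_unit)
          eta <- beta0[si] + params$phloem_slope * mm_tree + u_tree + u_units
          p <- stats::plogis(eta)
          n_b <- d$beetles_per_unit
          u_mat <- matrix(stats::runif(n_b * d$units_per_tree),
                          nrow = d$units_per_tree)
          n_succ <- as.integer(rowSums(u_mat < p))
          rows[[length(rows) + 1L]] <- data.frame(
            stage = stage, year = d$year, species = sp,
            host_class = params$host_class[si],
            tree_id = sprintf("%s_%d_t%02d", sp, d$year, tr),
            unit_id = sprintf("%s_%d_t%02d_u%02d", sp, d$year, tr,
                              seq_len(d$units_per_tree)),
            n_exposed = n_b, n_success = n_succ,
            phloem_mm = mm_tree,
            paired_male = stage == "brood",
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate trap-catch records
#'
#' One count per site x week x treatment, from the gamma-Poisson model in
#' [trap_params()]. A design with zero sites or weeks returns an empty frame.
#'
#' @param params a [trap_params()] object.
#' @param seed integer seed.
#' @param year year label stamped on the records.
#' @return `data.frame` with columns `site`, `week`, `year`, `treatment`,
#'   `count`.
#' @examples
#' head(simulate_traps(trap_params(), seed = 1))
#' @export
simulate_traps <- function(params, seed, year = 2013L) {
  stopifnot(inherits(params, "trap_params"))
  if (params$n_sites == 0L || params$n_weeks == 0L) {
    return(data.frame(site = character(), week = character(),
                      year = integer(), treatment = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  trts <- names(params$log_means)
  with_seed(substream_seed(seed, "traps"), {
    b_site <- stats::rnorm(params$n_sites, 0, params$sd_site)
    b_week <- stats::rnorm(params$n_weeks, 0, params$sd_week)
    grid <- expand.grid(site = seq_len(params$n_sites),
                        week = seq_len(params$n_weeks),
                        treatment = trts, stringsAsFactors = FALSE)
    lambda <- exp(params$log_means[grid$treatment] +
                  b_site[grid$site] + b_week[grid$week])
    g <- stats::rgamma(nrow(grid), shape = 1 / params$dispersion,
                       scale = params$dispersion)
    data.frame(site = sprintf("s%02d", grid$site),
               week = sprintf("w%d", grid$week),
               year = as.integer(year), treatment = grid$treatment,
               count = stats::rpois(nrow(grid), lambda * g),
               stringsAsFactors = FALSE)
  })
}

#' Simulate phloem-chemistry records
#'
#' One lognormal concentration per species x tree x compound.
#'
#' @param params a [chem_params()] object.
#' @param seed integer seed.
#' @return `data.frame` with columns `species`, `tree_id`, `compound`,
#'   `mg_per_g`.
#' @examples
#' chem <- simulate_chemistry(chem_params(), seed = 1)
#' head(total_monoterpenes(chem))
#' @export
simulate_chemistry <- function(params, seed) {
  stopifnot(inherits(params, "chem_params"))
  with_seed(substream_seed(seed, "chem"), {
    grid <- expand.grid(tree = seq_len(params$trees_per_species),
                        compound = params$compounds,
                        species = params$species,
                        stringsAsFactors = FALSE)
    mu <- params$log_means[cbind(grid$species, grid$compound)]
    sg <- params$log_sds[cbind(grid$species, grid$compound)]
    data.frame(species = grid$species,
               tree_id = sprintf("%s_t%02d", grid$species, grid$tree),
               compound = grid$compound,
               mg_per_g = exp(stats::rnorm(nrow(grid), mu, sg)),
               stringsAsFactors = FALSE)
  })
}

#' Total monoterpene concentration per tree
#'
#' Sums the seven monoterpenes per species x tree; 4-allylanisole (a
#' phenylpropanoid) is excluded by definition.
#'
#' @param chem chemistry records as from [simulate_chemistry()].
#' @return `data.frame` with `species`, `tree_id`, `total_mono_mg_per_g`.
#' @export
total_monoterpenes <- function(chem) {
  keep <- chem[chem$compound %in% MONOTERPENES, ]
  agg <- stats::aggregate(mg_per_g ~ species + tree_id, data = keep, FUN = sum)
  names(agg)[names(agg) == "mg_per_g"] <- "total_mono_mg_per_g"
  agg[order(agg$species, agg$tree_id), , drop = FALSE]
}
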