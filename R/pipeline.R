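#' Pipeline run configuration
#'
#' Collects everything a full run needs: a master seed (from which the
#' simulation, Monte Carlo and permutation substreams are derived via
#' [substream_seed()]), Monte Carlo and permutation sizes, the significance
#' level, simulation parameter objects (or CSV input paths), and the
#' transform registry. All sizes and the seed are stamped into every output
#' artifact.
#'
#' @param seed master integer seed.
#' @param n_draws Monte Carlo draws per species (default 100,000).
#' @param n_reps permutation replicates (default 999).
#' @param alpha significance level in (0,1).
#' @param colonization,traps,chem parameter objects
#'   ([colonization_params()], [trap_params()], [chem_params()]) used when
#'   simulating; ignored for any component with a CSV path supplied.
#' @param trials_csv,traps_csv,chem_csv optional input CSV paths (schemas as
#'   written by the simulators).
#' @param transforms named transform overrides merged over
#'   [transform_registry()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, n_draws = 100000L, n_reps = 999L,
                       alpha = 0.05,
                       colonization = colonization_params(),
                       traps = trap_params(), chem = chem_params(),
                       trials_csv = NULL, traps_csv = NULL, chem_csv = NULL,
                       transforms = character()) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0,1)")
  reg <- transform_registry()
  reg[names(transforms)] <- transforms
  structure(list(seed = as.integer(seed), n_draws = as.integer(n_draws),
                 n_reps = as.integer(n_reps), alpha = alpha,
                 colonization = colonization, traps = traps, chem = chem,
                 trials_csv = trials_csv, traps_csv = traps_csv,
                 chem_csv = chem_csv, transforms = reg),
            class = "run_config")
}

#' Validate an input CSV against a pipeline schema
#'
#' Row-level checks for the three input schemas: `trials` (counts within
#' exposure, known stage labels, positive thickness), `traps` (non-negative
#' integer counts), `chem` (non-negative concentrations; unknown compound
#' labels are warnings, not errors).
#'
#' @param path CSV file path.
#' @param schema `"trials"`, `"traps"` or `"chem"`.
#' @return `data.frame` with columns `row`, `severity` (`"error"` or
#'   `"warning"`), `message`; zero rows when the file is clean.
#' @export
validate_input <- function(path, schema = c("trials", "traps", "chem")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("unreadable file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  problems <- list()
  note <- function(row, sev, msg)
    problems[[length(problems) + 1L]] <<- data.frame(
      row = row, severity = sev, message = msg, stringsAsFactors = FALSE)
  req <- switch(schema,
    trials = c("stage", "year", "species", "tree_id", "unit_id",
               "n_exposed", "n_success"),
    traps = c("site", "week", "year", "treatment", "count"),
    chem = c("species", "tree_id", "compound", "mg_per_g"))
  missing_cols <- setdiff(req, names(d))
  if (length(missing_cols)) {
    note(0L, "error", paste("missing columns:",
                            paste(missing_cols, collapse = ", ")))
    return(do.call(rbind, problems))
  }
  for (i in seq_len(nrow(d))) {
    if (schema == "trials") {
      if (!(d$stage[i] %in% STAGES))
        note(i, "error", paste("unknown stage:", d$stage[i]))
      if (is.na(d$n_success[i]) || is.na(d$n_exposed[i]) ||
          d$n_success[i] < 0 || d$n_success[i] > d$n_exposed[i])
        note(i, "error", "need 0 <= n_success <= n_exposed")
      if ("phloem_mm" %in% names(d) && !is.na(d$phloem_mm[i]) &&
          d$phloem_mm[i] <= 0)
        note(i, "error", "phloem_mm must be positive")
    } else if (schema == "traps") {
      if (is.na(d$count[i]) || d$count[i] < 0 ||
          d$count[i] != round(d$count[i]))
        note(i, "error", "count must be a non-negative integer")
    } else {
      if (is.na(d$mg_per_g[i]) || d$mg_per_g[i] < 0)
        note(i, "error", "mg_per_g must be non-negative")
      if (!(d$compound[i] %in% COMPOUNDS))
        note(i, "warning", paste("unknown compound:", d$compound[i]))
    }
  }
  if (length(problems)) do.call(rbind, problems)
  else data.frame(row = integer(), severity = character(),
                  message = character(), stringsAsFactors = FALSE)
}

read_or_simulate <- function(config) {
  trials <- if (!is.null(config$trials_csv)) {
    v <- validate_input(config$trials_csv, "trials")
    if (any(v$severity == "error"))
      stop("trials input invalid at rows: ",
           paste(v$row[v$severity == "error"], collapse = ", "))
    utils::read.csv(config$trials_csv, stringsAsFactors = FALSE)
  } else {
    sim_seed <- substream_seed(config$seed, "simulate")
    do.call(rbind, lapply(STAGES, function(s)
      simulate_colonization(config$colonization, s, seed = sim_seed)))
  }
  traps <- if (!is.null(config$traps_csv)) {
    v <- validate_input(config$traps_csv, "traps")
    if (any(v$severity == "error")) stop("traps input invalid")
    utils::read.csv(config$traps_csv, stringsAsFactors = FALSE)
  } else {
    rbind(
      simulate_traps(config$traps, seed = substream_seed(config$seed,
                                                         "traps-2013"),
                     year = 2013L),
      simulate_traps(config$traps, seed = substream_seed(config$seed,
                                                         "traps-2014"),
                     year = 2014L))
  }
  chem <- if (!is.null(config$chem_csv)) {
    utils::read.csv(config$chem_csv, stringsAsFactors = FALSE)
  } else {
    simulate_chemistry(config$chem, seed = substream_seed(config$seed,
                                                          "chem"))
  }
  list(trials = trials, traps = traps, chem = chem)
}

# Default "suspiciously high" rule: transformed count more than 3 pooled SDs
# above its treatment-year mean.
default_trap_candidates <- function(traps, transform = "sqrt") {
  y <- apply_transform(traps$count, transform)
  key <- interaction(traps$treatment, traps$year, drop = TRUE)
  mu <- stats::ave(y, key, FUN = mean)
  sdp <- stats::sd(y - mu)
  which(y - mu > 3 * sdp)
}

#' Run the full colonization-analysis pipeline
#'
#' Orchestrates simulate/load -> validate -> stage estimation -> Monte Carlo
#' susceptibility integration -> between-year rank-concordance test ->
#' blocked ANOVA with protected LSD -> Bonferroni outlier scan, and writes
#' `stage_estimates.csv`, `susceptibility.csv`, `ranktest.json`,
#' `anova.json`, `outliers.json` and a human-readable `report.txt` to
#' `out_dir`. Every artifact records the master seed and a hash of the
#' configuration; the run is byte-reproducible for a fixed config.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if absent).
#' @return (invisibly) a list with all in-memory results: `stage_estimates`,
#'   `susceptibility`, `rank_test`, `anova`, `letters`, `outliers`,
#'   `pooled`, `config_hash`.
#' @export
run_full_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  tf <- tempfile(); writeLines(cfg_json, tf)
  config_hash <- unname(tools::md5sum(tf)); unlink(tf)

  data <- read_or_simulate(config)
  species <- sort(unique(data$trials$species))

  # stage-wise estimates
  est_rows <- list()
  est_by_species <- list()
  for (sp in species) {
    sts <- lapply(STAGES, function(st)
      species_logit_estimate(data$trials, sp, st))
    est_by_species[[sp]] <- sts
    for (s in sts) {
      e <- s$estimate
      est_rows[[length(est_rows) + 1L]] <- data.frame(
        species = s$species, stage = s$stage, k = e$k, n = e$n,
        p_hat = e$p_hat, logit_mean = e$logit_mean, logit_se = e$logit_se,
        ci_low = e$ci_low, ci_high = e$ci_high,
        correction_applied = e$correction_applied,
        stringsAsFactors = FALSE)
    }
  }
  stage_estimates <- do.call(rbind, est_rows)
  stage_estimates$seed <- config$seed
  stage_estimates$config_hash <- config_hash
  utils::write.csv(stage_estimates,
                   file.path(out_dir, "stage_estimates.csv"),
                   row.names = FALSE)

  # Monte Carlo integration, one substream per species
  susc <- do.call(rbind, lapply(species, function(sp) {
    d <- integrate_susceptibility(
      est_by_species[[sp]], n_draws = config$n_draws,
      seed = substream_seed(config$seed, paste0("mc-", sp)),
      keep_draws = FALSE)
    summarize_susceptibility(d)
  }))
  susc$config_hash <- config_hash
  utils::write.csv(susc, file.path(out_dir, "susceptibility.csv"),
                   row.names = FALSE)

  # rank concordance between years
  years <- sort(unique(data$traps$year))
  rank_res <- NULL
  if (length(years) >= 2L && nrow(data$traps) > 0L) {
    mean_by <- function(yr) {
      d <- data$traps[data$traps$year == yr, ]
      tapply(d$count, d$treatment, mean)
    }
    r1 <- rank_treatments(mean_by(years[1]), source_year = years[1])
    r2 <- rank_treatments(mean_by(years[2]), source_year = years[2])
    rank_res <- permutation_pvalue(r1, r2, n_reps = config$n_reps,
                                   seed = substream_seed(config$seed,
                                                         "ranktest"))
    jsonlite::write_json(
      list(d_obs = rank_res$d_obs, k_items = rank_res$k_items,
           n_reps = rank_res$n_reps, p_value = rank_res$p_value,
           method = rank_res$method, seed = config$seed,
           config_hash = config_hash),
      file.path(out_dir, "ranktest.json"), auto_unbox = TRUE, digits = NA)
  }

  # blocked ANOVA on transformed trap counts + protected LSD
  trap_tf <- unname(config$transforms["trap_count"])
  av <- blocked_anova(data$traps, "count", "treatment",
                      blocks = c("site", "week"), transform = trap_tf)
  lsd <- protected_lsd(av, alpha = config$alpha)
  jsonlite::write_json(
    list(F = av$F, df_num = av$df_num, df_den = av$df_den,
         p_value = av$p_value, ms_between = av$ms_between,
         ms_within = av$ms_within, transform = av$transform_applied,
         method = av$method, block_effects = "additive fixed approximation",
         seed = config$seed, config_hash = config_hash),
    file.path(out_dir, "anova.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(
    data.frame(treatment = names(lsd$letters),
               mean = unname(lsd$means[names(lsd$letters)]),
               letters = unname(lsd$letters),
               seed = config$seed, config_hash = config_hash,
               stringsAsFactors = FALSE),
    file.path(out_dir, "letters.csv"), row.names = FALSE)

  # outlier scan on the transformed trap counts
  data$traps$.y <- apply_transform(data$traps$count, trap_tf)
  cand <- default_trap_candidates(data$traps, trap_tf)
  outliers <- bonferroni_outlier_scan(
    data$traps, .y ~ site + week + treatment, candidates = cand,
    alpha = config$alpha)
  jsonlite::write_json(
    list(candidates = cand, flagged = outliers$flagged,
         p_values = as.list(outliers$p_values),
         thresholds = as.list(outliers$thresholds),
         alpha = config$alpha, seed = config$seed,
         config_hash = config_hash),
    file.path(out_dir, "outliers.json"), auto_unbox = TRUE, digits = NA)

  # pooled fixture-anchored summaries
  fx <- fixture_tables()
  pooled_pct <- 100 * fx$pooled$exp1_pooled$successes /
    fx$pooled$exp1_pooled$total
  pooled_product <- prod(vapply(fx$pooled, function(e) e$percent / 100,
                                numeric(1)))

  report <- c(
    "Colonization-analysis pipeline report",
    sprintf("seed: %d  config: %s", config$seed, config_hash),
    sprintf("n_draws: %d  n_reps: %d  alpha: %g", config$n_draws,
            config$n_reps, config$alpha),
    "",
    sprintf("Pooled bark entry (packaged counts): %d/%d = %.1f%%",
            fx$pooled$exp1_pooled$successes, fx$pooled$exp1_pooled$total,
            pooled_pct),
    sprintf("Integrated stage product (packaged pooled rates): %.4f (%s 50%%)",
            pooled_product, if (pooled_product < 0.5) "<" else ">="),
    "",
    "Per-species susceptibility (median, middle 95%):",
    sprintf("  %-14s %.4f (%.4f, %.4f)", susc$species, susc$median,
            susc$lo95, susc$hi95),
    "",
    if (!is.null(rank_res))
      sprintf("Rank concordance: D = %g, p = %.4g (%d reps)",
              rank_res$d_obs, rank_res$p_value, rank_res$n_reps)
    else "Rank concordance: skipped (need two years of trap data)",
    sprintf("Trap ANOVA (%s): F_%d,%d = %.3f, P = %.4g", trap_tf,
            av$df_num, av$df_den, av$F, av$p_value),
    sprintf("Outliers flagged: %s",
            if (length(outliers$flagged)) paste(outliers$flagged,
                                                collapse = ", ")
            else "none"))
  writeLines(report, file.path(out_dir, "report.txt"))

  invisible(list(stage_estimates = stage_estimates, susceptibility = susc,
                 rank_test = rank_res, anova = av, letters = lsd,
                 outliers = outliers,
                 pooled = list(bark_pct = pooled_pct,
                               product = pooled_product),
                 config_hash = config_hash))
}
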