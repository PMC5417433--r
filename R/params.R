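#' Parameters for the hierarchical colonization-trial simulator
#'
#' Describes the data-generating process of a staged colonization assay:
#' beetles are exposed in assay units (caged cells or drilled holes), units
#' are nested in logs/trees, and trees in species. Success at a stage is
#' binomial with probability
#' \deqn{p = \mathrm{logit}^{-1}(\beta_{species,stage} +
#'       \beta_{phloem} \cdot x_{mm} + u_{tree} + u_{unit})}
#' where \eqn{u_{tree} \sim N(0, \sigma_{tree}^2)} and
#' \eqn{u_{unit} \sim N(0, \sigma_{unit}^2)} are independent logit-scale
#' random effects.
#'
#' The default stage intercepts are calibrated so that, with zero random
#' effects and zero thickness slope, the pooled success probabilities at the
#' bark-entry, phloem-entry and brood-establishment stages are 0.633, 0.847
#' and 0.702 — the pooled rates observed across species in the staged assays
#' this simulator emulates.
#'
#' @param species character vector of species labels.
#' @param host_class character vector, one of `"historical"`/`"novel"` per
#'   species (historical = hosts with a co-evolutionary history with the
#'   beetle).
#' @param stage_intercepts numeric matrix, species x stage (`bark`, `phloem`,
#'   `brood`), logit-scale intercepts. A single row is recycled to all
#'   species.
#' @param sd_tree,sd_unit non-negative logit-scale SDs of the tree and
#'   unit-within-tree random effects.
#' @param phloem_slope logit units per mm of phloem thickness.
#' @param phloem_mean,phloem_sd per-species mean and SD (mm) of phloem
#'   thickness; scalars are recycled.
#' @param design list of per-year design blocks; each element a list with
#'   `year`, `trees_per_species`, `units_per_tree`, `beetles_per_unit`.
#'   The default mirrors the staged assays' layout: 2 trees x 10 cells x 5
#'   beetles in year 1 and 3 trees x 2 cells x 15 beetles in year 2.
#' @return an object of class `colonization_params`.
#' @seealso [simulate_colonization()]
#' @export
colonization_params <- function(
    species = c("ponderosa", "lodgepole", "jack", "red",
                "eastern_white", "scots"),
    host_class = c("historical", "historical", "novel", "novel",
                   "novel", "novel"),
    stage_intercepts = matrix(
      rep(stats::qlogis(c(0.633, 0.847, 0.702)), each = length(species)),
      nrow = length(species), dimnames = list(species, STAGES)),
    sd_tree = 0.5,
    sd_unit = 0.25,
    phloem_slope = 0,
    phloem_mean = 2.0,
    phloem_sd = 0.3,
    design = list(
      list(year = 2013L, trees_per_species = 2L, units_per_tree = 10L,
           beetles_per_unit = 5L),
      list(year = 2014L, trees_per_species = 3L, units_per_tree = 2L,
           beetles_per_unit = 15L))) {
  species <- as.character(species)
  k <- length(species)
  if (k < 1L) stop("need at least one species")
  host_class <- rep_len(as.character(host_class), k)
  if (!all(host_class %in% c("historical", "novel")))
    stop("host_class must be 'historical' or 'novel'")
  if (is.vector(stage_intercepts))
    stage_intercepts <- matrix(stage_intercepts, nrow = k, ncol = 3,
                               byrow = TRUE, dimnames = list(species, STAGES))
  if (nrow(stage_intercepts) == 1L && k > 1L)
    stage_intercepts <- stage_intercepts[rep(1L, k), , drop = FALSE]
  if (is.null(colnames(stage_intercepts)))
    colnames(stage_intercepts) <- STAGES
  if (!all(STAGES %in% colnames(stage_intercepts)))
    stop("stage_intercepts must have columns bark, phloem, brood")
  if (any(!is.finite(stage_intercepts)))
    stop("stage intercepts must be finite")
  rownames(stage_intercepts) <- species
  if (sd_tree < 0 || sd_unit < 0) stop("random-effect SDs must be >= 0")
  if (any(phloem_sd < 0)) stop("phloem_sd must be >= 0")
  for (d in design) {
    stopifnot(d$trees_per_species >= 1L, d$units_per_tree >= 1L,
              d$beetles_per_unit >= 1L)
  }
  structure(list(
    species = species, host_class = host_class,
    stage_intercepts = stage_intercepts[, STAGES, drop = FALSE],
    sd_tree = sd_tree, sd_unit = sd_unit,
    phloem_slope = phloem_slope,
    phloem_mean = rep_len(phloem_mean, k),
    phloem_sd = rep_len(phloem_sd, k),
    design = design), class = "colonization_params")
}

#' Parameters for the overdispersed trap-catch simulator
#'
#' Trap counts follow a gamma-Poisson (negative-binomial-type) construction:
#' \eqn{Y \sim Poisson(\lambda G)} with
#' \eqn{\lambda = \exp(\mu_{trt} + b_{site} + b_{week})} and
#' \eqn{G \sim Gamma(1/\phi, \phi)} (mean 1), giving
#' \eqn{Var(Y) = \lambda + \phi \lambda^2}. Site and week enter as
#' multiplicative lognormal blocks, matching a field layout of funnel traps
#' replicated over sites and collection weeks.
#'
#' Default treatment log-means are ordered ponderosa >= scots > lodgepole ~
#' jack ~ red > eastern white ~ unbaited control, the qualitative attraction
#' ordering the simulator emulates.
#'
#' @param log_means named numeric vector: per-treatment log mean catch.
#' @param sd_site,sd_week non-negative log-scale block SDs.
#' @param dispersion positive gamma-Poisson dispersion \eqn{\phi}.
#' @param n_sites,n_weeks design size (12 sites, 7-treatment rings by
#'   default).
#' @return object of class `trap_params`.
#' @seealso [simulate_traps()]
#' @export
trap_params <- function(
    log_means = c(ponderosa = log(6), scots = log(5), lodgepole = log(3.5),
                  jack = log(3.5), red = log(3.2), eastern_white = log(1.6),
                  control = log(1.5)),
    sd_site = 0.4, sd_week = 0.3, dispersion = 0.6,
    n_sites = 12L, n_weeks = 2L) {
  if (length(log_means) < 2L) stop("need at least two treatments")
  if (is.null(names(log_means)) || anyDuplicated(names(log_means)))
    stop("log_means must have unique treatment names")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (sd_site < 0 || sd_week < 0) stop("block SDs must be >= 0")
  if (n_sites < 0L || n_weeks < 0L) stop("design sizes must be >= 0")
  structure(list(log_means = log_means, sd_site = sd_site, sd_week = sd_week,
                 dispersion = dispersion, n_sites = as.integer(n_sites),
                 n_weeks = as.integer(n_weeks)), class = "trap_params")
}

#' Parameters for the phloem-chemistry simulator
#'
#' Concentrations (mg per g dry phloem) are lognormal per species x compound:
#' \eqn{\log C \sim N(\mu_{sp,cmp}, \sigma_{sp,cmp}^2)}. The compound list
#' covers the seven phloem monoterpenes plus the phenylpropanoid
#' 4-allylanisole.
#'
#' @param species character vector of species labels.
#' @param compounds character vector of compound labels.
#' @param log_means,log_sds numeric matrices (species x compound) of log-scale
#'   means and SDs; scalars recycled.
#' @param trees_per_species number of trees sampled per species.
#' @return object of class `chem_params`.
#' @seealso [simulate_chemistry()]
#' @export
chem_params <- function(
    species = c("ponderosa", "lodgepole", "jack", "red",
                "eastern_white", "scots"),
    compounds = COMPOUNDS,
    log_means = 0, log_sds = 0.5, trees_per_species = 4L) {
  ns <- length(species); nc <- length(compounds)
  mk <- function(x, what) {
    if (length(x) == 1L) x <- matrix(x, ns, nc)
    if (!is.matrix(x) || nrow(x) != ns || ncol(x) != nc)
      stop(what, " must be a species x compound matrix or a scalar")
    dimnames(x) <- list(species, compounds)
    x
  }
  log_means <- mk(log_means, "log_means")
  log_sds <- mk(log_sds, "log_sds")
  if (any(log_sds < 0)) stop("log_sds must be >= 0")
  if (trees_per_species < 1L) stop("trees_per_species must be >= 1")
  structure(list(species = species, compounds = compounds,
                 log_means = log_means, log_sds = log_sds,
                 trees_per_species = as.integer(trees_per_species)),
            class = "chem_params")
}
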