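# Build minimal trial-record frames from counts, for estimator tests.
make_trials <- function(k, n, stage = "bark", species = "sp1",
                        host_class = "historical", year = 2013L) {
  data.frame(stage = stage, year = year, species = species,
             host_class = host_class,
             tree_id = paste0(species, "_t1"),
             unit_id = paste0(species, "_t1_u", seq_along(k)),
             n_exposed = n, n_success = k, phloem_mm = 2,
             stringsAsFactors = FALSE)
}

# Direct grouped binomial log-likelihood at fitted proportions (oracle).
binom_ll <- function(k, n, p) {
  sum(ifelse(k > 0, k * log(p), 0) + ifelse(n - k > 0, (n - k) * log(1 - p), 0))
}

# Single-species design: one year, one tree, `units` units of `per` beetles.
flat_design <- function(units, per, year = 2013L) {
  list(list(year = year, trees_per_species = 1L, units_per_tree = units,
            beetles_per_unit = per))
}
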