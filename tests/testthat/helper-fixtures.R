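# Small simulation designs reused across tests.

tiny_design <- function(seed = 1L, n_timepoints = 120L, ...) {
  simulation_design(n_subjects_per_group = 4L,
                    nodes_per_module = c(3L, 4L, 3L),
                    n_timepoints = n_timepoints,
                    seed = seed, ...)
}

# 24 subjects, 9 small modules: same group structure as the full study at a
# fraction of the node count.
small_study_design <- function(seed = 1L, ...) {
  simulation_design(n_subjects_per_group = 12L,
                    nodes_per_module = rep(4L, 9L),
                    n_timepoints = 300L,
                    seed = seed, ...)
}

cohort_connectomes <- function(cohort) {
  build_connectomes(cohort$series)
}

# The planted-effect trio used for classifier checks: strengthens the
# positive coupling among the three visual modules for group 1.
visual_trio_effects <- function(delta = 0.3) {
  list(list(module_a = "Med Vis", module_b = "OP Vis", delta = delta, group = 1),
       list(module_a = "Med Vis", module_b = "Lat Vis", delta = delta, group = 1),
       list(module_a = "OP Vis", module_b = "Lat Vis", delta = delta, group = 1))
}
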