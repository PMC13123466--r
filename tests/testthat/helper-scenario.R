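# Shared fixtures, built lazily and cached for the whole test run.

.cache <- new.env(parent = emptyenv())

# the solved device field at the working 0.1 mm grid
default_field <- function() {
  if (is.null(.cache$field))
    .cache$field <- solve_unit_cell_flow(sorter_geometry(),
                                         grid_spacing = 1e-4)
  .cache$field
}

blend_fluid <- function() fluid_medium(1090, 4.78e-3, "ludox_blend")

std_body <- function() worm_body(5.96e-12, 1080, stokes_radius = 0.37e-3)

competent_phenotype <- function(quiescence = NULL)
  worm_phenotype("competent", std_body(),
                 behavior_params(0.81e-9, "directed_down"),
                 quiescence = quiescence)

deficient_phenotype <- function(scheme = "fixed_interval")
  worm_phenotype("deficient", std_body(),
                 behavior_params(0.81e-9, "random_reorient",
                                 reorientation_time = 4.65,
                                 reorientation_scheme = scheme))

# a device run with the standard populations, cached per (seed, n, dt)
device_run <- function(seed, n = c(600L, 600L), dt = 0.01,
                       max_time = 1800) {
  key <- paste0("run_", seed, "_", paste(n, collapse = "x"), "_", dt)
  if (is.null(.cache[[key]])) {
    cfg <- sim_config(geometry = sorter_geometry(), fluid = blend_fluid(),
                      phenotypes = list(competent_phenotype(),
                                        deficient_phenotype()),
                      n_per_phenotype = n, field = default_field(),
                      dt = dt, max_time = max_time, seed = seed)
    .cache[[key]] <- simulate_population(cfg)$outcome
  }
  .cache[[key]]
}
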