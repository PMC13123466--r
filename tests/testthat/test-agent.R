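# Overdamped particle stepping, reorientation, and sorter-run bookkeeping.

test_that("single-particle steps follow the overdamped velocity exactly", {
  f <- default_field()
  cf <- drag_coefficient(blend_fluid(), 0.37e-3)
  w <- buoyant_net_force(std_body(), blend_fluid())
  # passive buoyant particle in (near-)still fluid rises W/C_f per unit time
  mid <- c(2.05e-3, 1.5e-3, 10e-3)   # mid-column, where the fluid is still
  st <- particle_state(mid, c(0, 0, -1), force_budget(w, cf))
  st2 <- step(st, f, dt = 0.5)
  expect_equal(st2$position[3] - mid[3], w / cf * 0.5, tolerance = 1e-6)
  # drift in x only through the ~1e-9 m/s residual mid-column flow
  expect_equal(st2$position[1:2], mid[1:2], tolerance = 1e-5)
  # thrust exactly cancelling the reduced weight: no self-motion
  stc <- particle_state(mid, c(0, 0, -1),
                        force_budget(w, cf, thrust = c(0, 0, -w)))
  expect_equal(step(stc, f, dt = 0.5)$position, mid, tolerance = 1e-5)
  # tracer limit: no thrust, no weight -> moves with the local fluid
  node <- c(f$x[10], 1.5e-3, f$z[6])   # a feed-conduit grid node
  stt <- particle_state(node, c(1, 0, 0), force_budget(0, cf))
  stt$budget$reduced_weight <- 0
  adv <- step(stt, f, dt = 0.1)
  expect_equal((adv$position[1] - node[1]) / 0.1, f$u_x[6, 10],
               tolerance = 1e-9)
  expect_equal((adv$position[3] - node[3]) / 0.1, f$u_z[6, 10],
               tolerance = 1e-9)
})

test_that("reorientation resamples uniformly and on the configured clock", {
  cf <- drag_coefficient(blend_fluid(), 0.37e-3)
  # directed-down phenotypes never change heading
  bdown <- behavior_params(0.81e-9, "directed_down")
  st <- particle_state(c(0, 0, 0), c(0, 0, -1), force_budget(0, cf))
  expect_identical(reorient(st, bdown)$heading, c(0, 0, -1))
  # fixed-interval clock ticks at exact multiples of tau_r
  bfix <- behavior_params(0.81e-9, "random_reorient", 4.65, "fixed_interval")
  st$next_reorientation <- 4.65
  set.seed(1)
  for (k in 2:5) {
    st <- reorient(st, bfix)
    expect_equal(st$next_reorientation, k * 4.65)
    expect_equal(sqrt(sum(st$heading^2)), 1, tolerance = 1e-9)
  }
  # uniform-sphere sampling: the mean of many headings vanishes within
  # Monte-Carlo error (component sd is 1/sqrt(3))
  set.seed(42)
  h <- gravisort:::.sample_headings(1e4)
  se <- sqrt(1 / 3 / 1e4)
  expect_true(all(abs(colMeans(h)) < 3 * se))
  expect_equal(sqrt(rowSums(h^2)), rep(1, 1e4), tolerance = 1e-12)
})

test_that("sim refuses a time step that under-resolves the dynamics", {
  expect_error(
    sim_config(geometry = sorter_geometry(), fluid = blend_fluid(),
               phenotypes = list(deficient_phenotype()),
               n_per_phenotype = 10, field = default_field(), dt = 0.5),
    "dt")
})

test_that("runs are seed-reproducible and conserve particles", {
  cfg <- function()
    sim_config(geometry = sorter_geometry(), fluid = blend_fluid(),
               phenotypes = list(competent_phenotype(),
                                 deficient_phenotype()),
               n_per_phenotype = c(15L, 15L), field = default_field(),
               dt = 0.01, max_time = 200, seed = 99)
  o1 <- simulate_population(cfg())$outcome
  o2 <- simulate_population(cfg())$outcome
  expect_identical(o1$counts, o2$counts)
  expect_identical(o1$particles$status, o2$particles$status)
  with(o1$counts, expect_equal(exited_top + exited_bottom + timed_out, n_in))
  # the short horizon leaves the slow risers in transit, reported not dropped
  expect_gt(sum(o1$counts$timed_out), 0)
})

test_that("zero particles give an empty outcome", {
  cfg <- sim_config(geometry = sorter_geometry(), fluid = blend_fluid(),
                    phenotypes = list(competent_phenotype()),
                    n_per_phenotype = 0L, field = default_field(),
                    dt = 0.01, max_time = 10, seed = 1)
  out <- simulate_population(cfg)$outcome
  expect_equal(out$counts$n_in, 0L)
  expect_equal(nrow(out$particles), 0L)
})

test_that("bottom-injected competent particles never exit the top", {
  # net force is downward at all times (thrust 0.81 nN > buoyancy 0.58 nN),
  # so no competent particle can climb a column, for any seed
  for (s in c(2, 13, 77)) {
    cfg <- sim_config(geometry = sorter_geometry(), fluid = blend_fluid(),
                      phenotypes = list(competent_phenotype()),
                      n_per_phenotype = 30L, field = default_field(),
                      dt = 0.01, max_time = 700, seed = s)
    cts <- simulate_population(cfg)$outcome$counts
    expect_equal(cts$exited_top, 0L)
    expect_equal(cts$exited_bottom, 30L)   # and all are flushed out below
  }
})

test_that("free-space ensemble matches drift plus run-and-tumble diffusion", {
  # deficient particles with exponential reorientation in still fluid:
  # MSD(T) = (W/C_f)^2 T^2 + 2 U^2 tau (T - tau (1 - exp(-T/tau)))
  ph <- deficient_phenotype(scheme = "exponential")
  cfg <- sim_config(geometry = sorter_geometry(), fluid = blend_fluid(),
                    phenotypes = list(ph), n_per_phenotype = 300L,
                    field = "none", boundary = "none", dt = 0.2,
                    max_time = 60, seed = 5, record_interval = 60)
  tr <- simulate_population(cfg)$trajectories
  fin <- tr[tr$t == max(tr$t), ]
  msd <- fin$x^2 + fin$y^2 + fin$z^2
  cf <- drag_coefficient(blend_fluid(), 0.37e-3)
  w <- buoyant_net_force(std_body(), blend_fluid())
  u <- 0.81e-9 / cf; tau <- 4.65; T <- max(tr$t)
  theory <- (w / cf)^2 * T^2 + 2 * u^2 * tau * (T - tau * (1 - exp(-T / tau)))
  se <- stats::sd(msd) / sqrt(length(msd))
  expect_lt(abs(mean(msd) - theory), 3 * se)
})

test_that("exit fractions are insensitive to halving the time step", {
  o1 <- device_run(3, n = c(60L, 60L), dt = 0.01)
  o2 <- device_run(3, n = c(60L, 60L), dt = 0.005)
  f1 <- o1$counts$exited_top[o1$counts$phenotype == "deficient"] / 60
  f2 <- o2$counts$exited_top[o2$counts$phenotype == "deficient"] / 60
  se <- sqrt(max(f1 * (1 - f1), 0.5 / 60) / 60)
  expect_lt(abs(f1 - f2), se)
  b1 <- o1$counts$exited_bottom[o1$counts$phenotype == "competent"] / 60
  b2 <- o2$counts$exited_bottom[o2$counts$phenotype == "competent"] / 60
  expect_lt(abs(b1 - b2), sqrt(max(b1 * (1 - b1), 0.5 / 60) / 60))
})

test_that("quiescence switching reduces to the base cases", {
  # zero hazard leaves the trajectory identical to the base phenotype
  base <- competent_phenotype()
  zeroq <- competent_phenotype(quiescence_model(0, mean_bout = 30))
  run <- function(ph) {
    cfg <- sim_config(geometry = sorter_geometry(), fluid = blend_fluid(),
                      phenotypes = list(ph), n_per_phenotype = 10L,
                      field = default_field(), dt = 0.01, max_time = 120,
                      seed = 7, record_interval = 60)
    simulate_population(cfg)
  }
  r1 <- run(base); r2 <- run(zeroq)
  expect_identical(r1$trajectories$z, r2$trajectories$z)
  expect_identical(r1$outcome$counts, r2$outcome$counts)
  # permanent quiescence turns a competent swimmer into a passive riser
  perm <- competent_phenotype(quiescence_model(1e9, mean_bout = Inf))
  cfg <- sim_config(geometry = sorter_geometry(), fluid = blend_fluid(),
                    phenotypes = list(perm), n_per_phenotype = 20L,
                    field = "none", boundary = "none", dt = 0.1,
                    max_time = 60, seed = 3, record_interval = 60)
  tr <- simulate_population(cfg)$trajectories
  fin <- tr[tr$t == max(tr$t), ]
  cf <- drag_coefficient(blend_fluid(), 0.37e-3)
  w <- buoyant_net_force(std_body(), blend_fluid())
  # pure upward drift at W/C_f (first step still thrusts; tolerance covers it)
  expect_equal(mean(fin$z), w / cf * max(tr$t), tolerance = 0.05)
  expect_lt(stats::sd(fin$z), 0.05 * mean(fin$z))
})
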