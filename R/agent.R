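## Particle simulation of sorter runs. Particles are passive point tracers
## carrying a thrust vector: in the overdamped (massless) limit the particle
## velocity is the algebraic sum
##
##   v = u_fluid + (F_p n_hat + W z_hat) / C_f
##
## integrated with explicit Euler. Positions are 3-D; the flow field is x-z
## planar and invariant along the 3 mm depth, so y-motion arises only from
## the thrust heading and is reflected at the depth walls. Walls reflect
## specularly at a small standoff (default half a grid cell) that keeps the
## velocity interpolation stencil inside the fluid.

#' Quiescence model
#'
#' Two-state (active/quiescent) Markov switching. Quiescent animals stop
#' thrusting but keep their weight and drag, so a quiescent
#' gravitaxis-competent worm drifts upward like a passive tracer; this is
#' the mechanism behind the decline of sorting efficiency with time.
#'
#' @param onset_hazard rate of entering quiescence, per minute; either a
#'   non-negative scalar or a function of time (s) returning a rate per
#'   minute (for ramps).
#' @param mean_bout mean quiescent bout duration, s.
#' @return object of class `quiescence_model`.
#' @export
quiescence_model <- function(onset_hazard, mean_bout) {
  if (!is.function(onset_hazard)) {
    # stored per minute; quantity strings ("0.05 /s") are converted
    if (is.character(onset_hazard))
      onset_hazard <- parse_quantity(onset_hazard) * 60
    .check_nonneg(onset_hazard, "onset_hazard")
  }
  mean_bout <- parse_quantity(mean_bout)
  if (!is.numeric(mean_bout) || length(mean_bout) != 1L ||
      is.na(mean_bout) || mean_bout <= 0)
    stop("mean_bout must be positive (Inf = permanent quiescence)",
         call. = FALSE)
  structure(list(onset_hazard = onset_hazard, mean_bout = mean_bout),
            class = "quiescence_model")
}

# hazard in 1/min at time t (s)
.hazard_at <- function(q, t) {
  if (is.function(q$onset_hazard)) q$onset_hazard(t) else q$onset_hazard
}

#' Worm phenotype
#'
#' Bundles a body ([worm_body()]), a behavior ([behavior_params()]), and an
#' optional [quiescence_model()] under an identifier.
#'
#' @param id short label (e.g. `"competent"`, `"deficient"`).
#' @param body a [worm_body()] with `stokes_radius` set.
#' @param behavior a [behavior_params()].
#' @param quiescence optional [quiescence_model()].
#' @return object of class `worm_phenotype`.
#' @export
worm_phenotype <- function(id, body, behavior, quiescence = NULL) {
  stopifnot(inherits(body, "worm_body"), inherits(behavior, "behavior_params"))
  if (is.null(body$stokes_radius))
    stop("phenotype body needs a stokes_radius", call. = FALSE)
  if (!is.null(quiescence) && !inherits(quiescence, "quiescence_model"))
    stop("quiescence must be a quiescence_model", call. = FALSE)
  structure(list(id = as.character(id), body = body, behavior = behavior,
                 quiescence = quiescence),
            class = "worm_phenotype")
}

#' Simulation configuration
#'
#' Validates and freezes everything a sorter run needs. The time step must
#' satisfy `dt <= 0.1 * min(tau_r, grid cell / max speed)` so that
#' reorientation clocks and grid cells are well resolved; violations are
#' refused with an explanation rather than silently adjusted.
#'
#' @param geometry a [sorter_geometry()].
#' @param fluid a [fluid_medium()] (sets drag and buoyancy).
#' @param phenotypes list of [worm_phenotype()].
#' @param n_per_phenotype integer counts, one per phenotype.
#' @param field a `flow_field_2d` ([solve_unit_cell_flow()] or
#'   [analytic_fallback_field()]), or `"none"` for still fluid.
#' @param dt time step, s.
#' @param max_time simulation horizon, s (default 1800 s, the 30 min
#'   operating window; particles still inside are reported as timed out).
#' @param injection `"pulse_at_inlet"` (released over the feed inlet
#'   cross-section at t = 0) or `"distributed_feedline"` (spread along the
#'   whole feed conduit).
#' @param boundary `"reflect"` (device walls) or `"none"` (free space, used
#'   for diffusion oracles; nothing exits).
#' @param wall_offset reflection standoff from walls, m. Defaults to half a
#'   field grid cell: particles are point tracers and the standoff keeps
#'   their interpolated velocity inside the fluid.
#' @param seed integer seed; runs are bit-reproducible given the seed.
#' @param record_interval optional trajectory sampling interval, s
#'   (`NULL` = do not store trajectories).
#' @param g gravitational acceleration, m/s2.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(geometry, fluid, phenotypes, n_per_phenotype,
                       field = "none", dt = 0.01, max_time = 1800,
                       injection = c("pulse_at_inlet", "distributed_feedline"),
                       boundary = c("reflect", "none"),
                       wall_offset = NULL, seed = 1,
                       record_interval = NULL, g = 9.81) {
  stopifnot(inherits(geometry, "sorter_geometry"),
            inherits(fluid, "fluid_medium"))
  injection <- match.arg(injection)
  boundary <- match.arg(boundary)
  if (inherits(phenotypes, "worm_phenotype")) phenotypes <- list(phenotypes)
  if (!length(phenotypes) ||
      !all(vapply(phenotypes, inherits, logical(1), "worm_phenotype")))
    stop("phenotypes must be a list of worm_phenotype objects", call. = FALSE)
  n_per_phenotype <- as.integer(n_per_phenotype)
  if (length(n_per_phenotype) != length(phenotypes) ||
      any(is.na(n_per_phenotype)) || any(n_per_phenotype < 0))
    stop("n_per_phenotype must give one non-negative count per phenotype",
         call. = FALSE)
  .check_positive(dt, "dt")
  .check_positive(max_time, "max_time")
  has_field <- inherits(field, "flow_field_2d")
  if (!has_field && !identical(field, "none"))
    stop("field must be a flow_field_2d or \"none\"", call. = FALSE)
  if (is.null(wall_offset))
    wall_offset <- if (has_field) field$hx / 2 else 5e-5
  .check_nonneg(wall_offset, "wall_offset")

  # dt bound: resolve the fastest of (reorientation clock, cell crossing)
  umax <- if (has_field)
    max(sqrt(field$u_x^2 + field$u_z^2), na.rm = TRUE) else 0
  taus <- Inf
  for (p in phenotypes) {
    cf <- drag_coefficient(fluid, p$body$stokes_radius)
    w <- buoyant_net_force(p$body, fluid, g)
    umax <- max(umax, (p$behavior$thrust_magnitude + abs(w)) / cf)
    if (p$behavior$mode == "random_reorient")
      taus <- min(taus, p$behavior$reorientation_time)
  }
  cell <- if (has_field) min(field$hx, field$hz) else Inf
  bound <- 0.1 * min(taus, cell / max(umax, 1e-30))
  if (dt > bound + 1e-12)
    stop(sprintf(paste0(
      "dt = %g s is too coarse: the configuration requires dt <= %.4g s ",
      "(0.1 * min(reorientation time %.3g s, grid cell %.3g m / max speed ",
      "%.3g m/s))"), dt, bound, taus, cell, umax), call. = FALSE)

  structure(list(geometry = geometry, fluid = fluid,
                 phenotypes = phenotypes, n_per_phenotype = n_per_phenotype,
                 field = field, dt = dt, max_time = max_time,
                 injection = injection, boundary = boundary,
                 wall_offset = wall_offset, seed = as.integer(seed),
                 record_interval = record_interval, g = g),
            class = "sim_config")
}

# --- internal vectorized machinery -----------------------------------------

# bilinear velocity interpolation; x is taken modulo the column pitch
.field_velocity <- function(field, x, z) {
  if (!inherits(field, "flow_field_2d"))
    return(list(ux = numeric(length(x)), uz = numeric(length(x))))
  UX <- field$.ux0; UZ <- field$.uz0
  nzg <- nrow(UX)
  pitch <- field$geometry$column_pitch
  xm <- x %% pitch
  jx <- pmin(pmax(xm / field$hx, 0), ncol(UX) - 1 - 1e-9)
  izf <- pmin(pmax(z / field$hz, 0), nzg - 1 - 1e-9)
  j0 <- floor(jx); i0 <- floor(izf)
  fx <- jx - j0; fz <- izf - i0
  k00 <- j0 * nzg + i0 + 1
  ux <- (1 - fx) * (1 - fz) * UX[k00] + (1 - fx) * fz * UX[k00 + 1] +
    fx * (1 - fz) * UX[k00 + nzg] + fx * fz * UX[k00 + nzg + 1]
  uz <- (1 - fx) * (1 - fz) * UZ[k00] + (1 - fx) * fz * UZ[k00 + 1] +
    fx * (1 - fz) * UZ[k00 + nzg] + fx * fz * UZ[k00 + nzg + 1]
  list(ux = ux, uz = uz)
}

# NA-free velocity copies cached on the field for fast lookup
.prep_field <- function(field) {
  if (!inherits(field, "flow_field_2d")) return(field)
  ux <- field$u_x; uz <- field$u_z
  ux[is.na(ux)] <- 0; uz[is.na(uz)] <- 0
  field$.ux0 <- ux; field$.uz0 <- uz
  field
}

# uniform headings on the unit sphere
.sample_headings <- function(n) {
  m <- matrix(stats::rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

#' Resample a particle heading
#'
#' Draws a new thrust direction uniformly on the unit sphere and schedules
#' the next reorientation: a fixed `tau_r` later (`fixed_interval`, the
#' observed 4.65 s clock) or an exponential waiting time with mean `tau_r`
#' (`exponential`). Uses R's global RNG. Particles in `directed_down` or
#' `passive` mode are returned unchanged.
#'
#' @param state a `particle_state`.
#' @param behavior a [behavior_params()].
#' @return the updated `particle_state`.
#' @export
reorient <- function(state, behavior) {
  stopifnot(inherits(state, "particle_state"),
            inherits(behavior, "behavior_params"))
  if (behavior$mode != "random_reorient") return(state)
  state$heading <- as.vector(.sample_headings(1))
  tau <- behavior$reorientation_time
  wait <- if (behavior$reorientation_scheme == "exponential")
    stats::rexp(1, 1 / tau) else tau
  state$next_reorientation <- state$next_reorientation + wait
  state
}

#' Particle state
#'
#' Position, unit heading, force budget, activity and transit status of one
#' simulated particle.
#'
#' @param position 3-vector (x, y, z), m.
#' @param heading unit 3-vector (thrust direction).
#' @param budget a [force_budget()].
#' @param activity `"active"` or `"quiescent"`.
#' @param next_reorientation time of the next heading resample, s.
#' @param status `"in_transit"`, `"exited_top"`, `"exited_bottom"`, or
#'   `"timed_out"`.
#' @return object of class `particle_state`.
#' @export
particle_state <- function(position, heading = c(0, 0, -1), budget,
                           activity = "active", next_reorientation = Inf,
                           status = "in_transit") {
  stopifnot(length(position) == 3, length(heading) == 3,
            inherits(budget, "force_budget"))
  nh <- sqrt(sum(heading^2))
  if (abs(nh - 1) > 1e-9) stop("heading must be a unit vector", call. = FALSE)
  structure(list(position = as.numeric(position),
                 heading = as.numeric(heading) / nh, budget = budget,
                 activity = match.arg(activity, c("active", "quiescent")),
                 next_reorientation = next_reorientation,
                 status = match.arg(status, c("in_transit", "exited_top",
                                              "exited_bottom", "timed_out"))),
            class = "particle_state")
}

#' Advance one particle by one overdamped Euler step
#'
#' The particle velocity is the local fluid velocity plus
#' `(thrust + W z_hat) / C_f`; quiescent particles contribute no thrust.
#' Walls (when a `field` is supplied) reflect specularly at `wall_offset`
#' with the heading preserved.
#'
#' @param state a [particle_state()].
#' @param field a `flow_field_2d` or `"none"` for still fluid.
#' @param dt time step, s.
#' @param wall_offset reflection standoff, m (default half a grid cell).
#' @return the advanced `particle_state`.
#' @export
step <- function(state, field, dt, wall_offset = NULL) {
  stopifnot(inherits(state, "particle_state"))
  .check_positive(dt, "dt")
  if (state$status != "in_transit")
    stop("cannot step a particle that is not in transit", call. = FALSE)
  has_field <- inherits(field, "flow_field_2d")
  if (has_field && is.null(field$.ux0)) field <- .prep_field(field)
  if (is.null(wall_offset))
    wall_offset <- if (has_field) field$hx / 2 else 0
  b <- state$budget
  thrust <- if (state$activity == "active") b$thrust else c(0, 0, 0)
  u <- if (has_field)
    .field_velocity(field, state$position[1], state$position[3])
  else list(ux = 0, uz = 0)
  v <- c(u$ux, 0, u$uz) + (thrust + c(0, 0, b$reduced_weight)) /
    b$drag_coefficient
  pos <- state$position + v * dt
  if (has_field) {
    r <- .reflect_positions(matrix(pos, 1), matrix(state$position, 1),
                            field, wall_offset)
    pos <- as.vector(r)
  }
  state$position <- pos
  state
}

# specular reflection of tentative positions `new` given previous `old`;
# both n x 3 matrices. Returns corrected n x 3 matrix.
.reflect_positions <- function(new, old, field, delta) {
  g <- field$geometry
  H <- field$total_height; a <- field$conduit_height
  depth <- g$conduit_depth
  pitch <- g$column_pitch
  xc0 <- field$xc0; xc1 <- field$xc1
  x <- new[, 1]; y <- new[, 2]; z <- new[, 3]
  for (pass in 1:3) {
    i <- y < delta; y[i] <- 2 * delta - y[i]
    i <- y > depth - delta; y[i] <- 2 * (depth - delta) - y[i]
    i <- z < delta; z[i] <- 2 * delta - z[i]
    i <- z > H - delta; z[i] <- 2 * (H - delta) - z[i]
    i <- x < delta; x[i] <- 2 * delta - x[i]
    xm <- x %% pitch
    inband <- z > a - delta & z < H - a + delta
    inopen <- xm >= xc0 + delta & xm <= xc1 - delta
    bad <- which(inband & !inopen)
    if (!length(bad)) break
    oz <- old[bad, 3]
    frombot <- oz <= a - delta + 1e-12
    fromtop <- oz >= H - a + delta - 1e-12
    fromcol <- !frombot & !fromtop
    z[bad[frombot]] <- 2 * (a - delta) - z[bad[frombot]]
    z[bad[fromtop]] <- 2 * (H - a + delta) - z[bad[fromtop]]
    if (any(fromcol)) {
      k <- bad[fromcol]
      xmc <- x[k] %% pitch
      lo <- xmc < xc0 + delta
      xr <- ifelse(lo, 2 * (xc0 + delta) - xmc, 2 * (xc1 - delta) - xmc)
      x[k] <- x[k] + (xr - xmc)
    }
  }
  cbind(x, y, z)
}

#' Stochastic quiescence transition
#'
#' One Markov-switching update for a vector of activity states: active
#' particles enter quiescence with probability `hazard(t)/60 * dt` and
#' quiescent particles resume with probability `dt / mean_bout`. Uses R's
#' global RNG.
#'
#' @param activity logical vector, `TRUE` = quiescent.
#' @param model a [quiescence_model()] (or `NULL`, returned unchanged).
#' @param t current time, s.
#' @param dt time step, s.
#' @return updated logical vector.
#' @export
apply_quiescence <- function(activity, model, t, dt) {
  if (is.null(model)) return(activity)
  stopifnot(inherits(model, "quiescence_model"))
  n <- length(activity)
  if (!n) return(activity)
  p_on <- min(.hazard_at(model, t) / 60 * dt, 1)
  p_off <- min(dt / model$mean_bout, 1)
  # zero hazard with nobody quiescent: no transition possible; leave the
  # RNG stream untouched so the run is identical to the base phenotype
  if (p_on == 0 && !any(activity)) return(activity)
  u <- stats::runif(n)
  (activity & u >= p_off) | (!activity & u < p_on)
}

#' Simulate a sorter run
#'
#' Releases the configured populations into the device, advances every
#' particle with overdamped Euler steps through the (tiled) unit-cell flow
#' field, resamples random-reorienting headings on their clocks, applies
#' quiescence switching where modeled, and classifies each particle as
#' exiting the top collection conduit, the bottom feed conduit, or timing
#' out. Runs are deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `outcome` (class `sort_outcome`: per-phenotype counts
#'   and a per-particle table) and `trajectories` (a `trajectory_set`
#'   data frame, or `NULL` unless `record_interval` was set).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$geometry
  field <- .prep_field(config$field)
  has_field <- inherits(field, "flow_field_2d")
  reflect <- config$boundary == "reflect" && has_field
  dt <- config$dt
  delta <- config$wall_offset
  a <- g$conduit_height
  depth <- g$conduit_depth
  L <- g$device_length
  H <- g$column_height + 2 * a

  n_tot <- sum(config$n_per_phenotype)
  phen_idx <- rep(seq_along(config$phenotypes), config$n_per_phenotype)
  ids <- vapply(config$phenotypes, `[[`, character(1), "id")

  # per-phenotype physics
  cf <- vapply(config$phenotypes, function(p)
    drag_coefficient(config$fluid, p$body$stokes_radius), numeric(1))
  W <- vapply(config$phenotypes, function(p)
    buoyant_net_force(p$body, config$fluid, config$g), numeric(1))
  Fp <- vapply(config$phenotypes, function(p)
    p$behavior$thrust_magnitude, numeric(1))
  mode <- vapply(config$phenotypes, function(p) p$behavior$mode, character(1))
  tau <- vapply(config$phenotypes, function(p)
    p$behavior$reorientation_time %||% Inf, numeric(1))
  expsch <- vapply(config$phenotypes, function(p)
    identical(p$behavior$reorientation_scheme, "exponential"), logical(1))

  if (n_tot == 0) {
    counts <- data.frame(phenotype = ids, n_in = 0L, exited_top = 0L,
                         exited_bottom = 0L, timed_out = 0L)
    out <- structure(list(counts = counts,
                          particles = data.frame(particle_id = integer(0),
                                                 phenotype = character(0),
                                                 status = character(0),
                                                 exit_time = numeric(0)),
                          seed = config$seed, dt = dt,
                          max_time = config$max_time),
                     class = "sort_outcome")
    return(list(outcome = out, trajectories = NULL))
  }

  # injection over the feed conduit cross-section
  if (config$boundary == "none") {
    px <- rep(0, n_tot); py <- rep(0, n_tot); pz <- rep(0, n_tot)
  } else if (config$injection == "pulse_at_inlet") {
    px <- stats::runif(n_tot, delta, max(2e-3, 4 * delta))
    py <- stats::runif(n_tot, delta, depth - delta)
    pz <- stats::runif(n_tot, delta, a - delta)
  } else {
    px <- stats::runif(n_tot, delta, L - delta)
    py <- stats::runif(n_tot, delta, depth - delta)
    pz <- stats::runif(n_tot, delta, a - delta)
  }

  hd <- .sample_headings(n_tot)
  fixed_down <- mode[phen_idx] == "directed_down"
  hd[fixed_down, 1] <- 0; hd[fixed_down, 2] <- 0; hd[fixed_down, 3] <- -1
  thrust_mag <- Fp[phen_idx]
  thrust_mag[mode[phen_idx] == "passive"] <- 0
  cf_i <- cf[phen_idx]; w_i <- W[phen_idx]
  tau_i <- tau[phen_idx]; exp_i <- expsch[phen_idx]
  reor <- mode[phen_idx] == "random_reorient"
  nextre <- rep(Inf, n_tot)
  nextre[reor & !exp_i] <- tau_i[reor & !exp_i]
  k <- reor & exp_i
  if (any(k)) nextre[k] <- stats::rexp(sum(k), 1 / tau_i[k])

  quiescent <- rep(FALSE, n_tot)
  qmodels <- lapply(config$phenotypes, `[[`, "quiescence")
  has_q <- vapply(qmodels, Negate(is.null), logical(1))

  status <- rep(0L, n_tot)    # 0 transit, 1 top, 2 bottom, 3 timed out
  exit_time <- rep(NA_real_, n_tot)
  act <- seq_len(n_tot)

  rec_every <- if (is.null(config$record_interval)) NULL
    else max(1L, round(config$record_interval / dt))
  rec <- list()
  if (!is.null(rec_every))
    rec[[1]] <- data.frame(particle_id = seq_len(n_tot),
                           phenotype = ids[phen_idx], t = 0,
                           x = px, y = py, z = pz)

  n_steps <- ceiling(config$max_time / dt)
  t <- 0
  for (s in seq_len(n_steps)) {
    t <- s * dt
    if (!length(act)) break
    u <- if (has_field) .field_velocity(field, px[act], pz[act])
    else list(ux = 0, uz = 0)
    th <- thrust_mag[act] * (!quiescent[act])
    vx <- u$ux + th * hd[act, 1] / cf_i[act]
    vy <- th * hd[act, 2] / cf_i[act]
    vz <- u$uz + (th * hd[act, 3] + w_i[act]) / cf_i[act]
    nx_ <- px[act] + vx * dt
    ny_ <- py[act] + vy * dt
    nz_ <- pz[act] + vz * dt
    if (reflect) {
      r <- .reflect_positions(cbind(nx_, ny_, nz_),
                              cbind(px[act], py[act], pz[act]), field, delta)
      nx_ <- r[, 1]; ny_ <- r[, 2]; nz_ <- r[, 3]
    }
    px[act] <- nx_; py[act] <- ny_; pz[act] <- nz_

    due <- which(reor[act] & t + 1e-9 >= nextre[act])
    if (length(due)) {
      ii <- act[due]
      hd[ii, ] <- .sample_headings(length(ii))
      iex <- exp_i[ii]
      nextre[ii[!iex]] <- nextre[ii[!iex]] + tau_i[ii[!iex]]
      if (any(iex))
        nextre[ii[iex]] <- t + stats::rexp(sum(iex), 1 / tau_i[ii[iex]])
    }

    if (any(has_q)) {
      for (pi in which(has_q)) {
        sel <- act[phen_idx[act] == pi]
        if (length(sel))
          quiescent[sel] <- apply_quiescence(quiescent[sel], qmodels[[pi]],
                                             t, dt)
      }
    }

    if (reflect) {
      out <- which(px[act] >= L)
      if (length(out)) {
        ii <- act[out]
        status[ii] <- ifelse(pz[ii] >= H - a, 1L, 2L)
        exit_time[ii] <- t
        act <- act[-out]
      }
    }

    if (!is.null(rec_every) && s %% rec_every == 0L)
      rec[[length(rec) + 1L]] <-
        data.frame(particle_id = seq_len(n_tot), phenotype = ids[phen_idx],
                   t = t, x = px, y = py, z = pz)
  }
  status[act] <- 3L

  counts <- do.call(rbind, lapply(seq_along(ids), function(pi) {
    sel <- phen_idx == pi
    data.frame(phenotype = ids[pi], n_in = sum(sel),
               exited_top = sum(status[sel] == 1L),
               exited_bottom = sum(status[sel] == 2L),
               timed_out = sum(status[sel] == 3L))
  }))
  particles <- data.frame(
    particle_id = seq_len(n_tot), phenotype = ids[phen_idx],
    status = c("exited_top", "exited_bottom",
               "timed_out")[pmax(status, 1L)],
    exit_time = exit_time)
  particles$status[status == 0L] <- "timed_out"
  out <- structure(list(counts = counts, particles = particles,
                        seed = config$seed, dt = dt,
                        max_time = config$max_time),
                   class = "sort_outcome")
  traj <- if (length(rec)) {
    tr <- do.call(rbind, rec)
    attr(tr, "sampling_interval") <- if (is.null(rec_every)) NA_real_
      else rec_every * dt
    class(tr) <- c("trajectory_set", class(tr))
    tr
  } else NULL
  list(outcome = out, trajectories = traj)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sort_outcome <- function(x, ...) {
  cat(sprintf("<sort_outcome> seed %d, dt %.3g s, horizon %.0f s\n",
              x$seed, x$dt, x$max_time))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
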