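## Quasi-static force balance for a swimming/settling worm approximated as a
## sphere of Stokes radius r_s:
##
##   (rho_w - rho_f) V_w g + 6 pi mu r_s U + F_p = 0
##
## Every scalar estimator in this file is algebra on that balance. Sign
## convention: +z is up; the "reduced weight" W = (rho_f - rho_w) V_w g is the
## signed net of gravity and buoyancy (positive = the body floats).

#' Fluid medium
#'
#' Density and dynamic viscosity of the liquid bathing the animals. Two media
#' matter in practice: M9 buffer (about 1000 kg/m3, 1 mPa s) and an
#' M9/colloidal-silica blend tuned to 1090 kg/m3 with viscosity 4.78 mPa s.
#'
#' @param density fluid density, kg/m3 (or a quantity string, see
#'   [parse_quantity()]).
#' @param dynamic_viscosity dynamic viscosity, Pa s.
#' @param label optional name.
#' @return object of class `fluid_medium`.
#' @examples
#' fluid_medium("1.09 g/mL", "4.78 mPa.s", "ludox_blend")
#' @export
fluid_medium <- function(density, dynamic_viscosity, label = "") {
  density <- parse_quantity(density)
  dynamic_viscosity <- parse_quantity(dynamic_viscosity)
  .check_positive(density, "density")
  .check_positive(dynamic_viscosity, "dynamic_viscosity")
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity,
                 label = as.character(label)),
            class = "fluid_medium")
}

#' @export
print.fluid_medium <- function(x, ...) {
  cat(sprintf("<fluid_medium%s> density %.4g kg/m3, viscosity %.4g Pa s\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$density, x$dynamic_viscosity))
  invisible(x)
}

#' Worm body
#'
#' Effective body volume, density, and Stokes radius of an adult worm. The
#' Stokes radius is the radius of the sphere with the same viscous drag as the
#' worm at equal speed; it is usually estimated from settling tracks with
#' [estimate_stokes_radius()] and may be left `NULL` until then.
#'
#' @param volume body volume, m3. Adults are about 5.96e-12 m3.
#' @param density body density, kg/m3 (about 1080).
#' @param stokes_radius Stokes radius, m, or `NULL`.
#' @return object of class `worm_body`.
#' @export
worm_body <- function(volume, density, stokes_radius = NULL) {
  volume <- parse_quantity(volume)
  density <- parse_quantity(density)
  .check_positive(volume, "volume")
  .check_positive(density, "density")
  if (!is.null(stokes_radius)) {
    stokes_radius <- parse_quantity(stokes_radius)
    .check_positive(stokes_radius, "stokes_radius")
    if (stokes_radius >= 1e-2)
      stop("stokes_radius must be below 1 cm", call. = FALSE)
  }
  structure(list(volume = volume, density = density,
                 stokes_radius = stokes_radius),
            class = "worm_body")
}

#' @export
print.worm_body <- function(x, ...) {
  cat(sprintf("<worm_body> V = %.4g m3, rho = %.4g kg/m3, r_s = %s\n",
              x$volume, x$density,
              if (is.null(x$stokes_radius)) "unset" else
                sprintf("%.4g m", x$stokes_radius)))
  invisible(x)
}

#' Behavioral parameters
#'
#' Thrust magnitude and heading dynamics of a phenotype. `directed_down`
#' models taxis-competent animals (constant downward thrust);
#' `random_reorient` models taxis-deficient animals whose thrust direction is
#' resampled uniformly on the sphere, either on a fixed clock
#' (`fixed_interval`) or with exponential waiting times (`exponential`), both
#' with mean `reorientation_time`; `passive` has no thrust.
#'
#' @param thrust_magnitude propulsive thrust, N.
#' @param mode one of `"directed_down"`, `"random_reorient"`, `"passive"`.
#' @param reorientation_time mean directional persistence time tau_r, s
#'   (required for `random_reorient`; measured at 4.65 s for the deficient
#'   mutant).
#' @param reorientation_scheme `"fixed_interval"` or `"exponential"`.
#' @param gait_frequency optional body-undulation frequency, Hz, used by
#'   [thrust_from_frequency()] scaling.
#' @return object of class `behavior_params`.
#' @export
behavior_params <- function(thrust_magnitude,
                            mode = c("directed_down", "random_reorient",
                                     "passive"),
                            reorientation_time = NULL,
                            reorientation_scheme = c("fixed_interval",
                                                     "exponential"),
                            gait_frequency = NULL) {
  mode <- match.arg(mode)
  reorientation_scheme <- match.arg(reorientation_scheme)
  thrust_magnitude <- parse_quantity(thrust_magnitude)
  .check_nonneg(thrust_magnitude, "thrust_magnitude")
  if (mode == "random_reorient") {
    if (is.null(reorientation_time))
      stop("random_reorient mode needs a reorientation_time", call. = FALSE)
    reorientation_time <- parse_quantity(reorientation_time)
    .check_positive(reorientation_time, "reorientation_time")
  }
  if (!is.null(gait_frequency)) {
    gait_frequency <- parse_quantity(gait_frequency)
    .check_positive(gait_frequency, "gait_frequency")
  }
  structure(list(thrust_magnitude = thrust_magnitude, mode = mode,
                 reorientation_time = reorientation_time,
                 reorientation_scheme = reorientation_scheme,
                 gait_frequency = gait_frequency),
            class = "behavior_params")
}

#' Force budget of a particle
#'
#' The three signed ingredients of the overdamped balance: reduced weight
#' (gravity + buoyancy, signed, +z up), Stokes drag coefficient
#' `C_f = 6 pi mu r_s`, and a thrust vector.
#'
#' @param reduced_weight signed net of gravity and buoyancy, N (+ = floats).
#' @param drag_coefficient `6 pi mu r_s`, N s/m.
#' @param thrust thrust force 3-vector (x, y, z), N.
#' @return object of class `force_budget`.
#' @seealso [buoyant_net_force()], [drag_coefficient()], [terminal_velocity()]
#' @export
force_budget <- function(reduced_weight, drag_coefficient,
                         thrust = c(0, 0, 0)) {
  if (!is.numeric(reduced_weight) || length(reduced_weight) != 1L)
    stop("reduced_weight must be a single signed number", call. = FALSE)
  .check_positive(drag_coefficient, "drag_coefficient")
  if (length(thrust) != 3L || !is.numeric(thrust))
    stop("thrust must be a numeric 3-vector", call. = FALSE)
  structure(list(reduced_weight = reduced_weight,
                 drag_coefficient = drag_coefficient,
                 thrust = as.numeric(thrust)),
            class = "force_budget")
}

#' Net of gravity and buoyancy on a worm
#'
#' Returns the reduced weight `(rho_f - rho_w) V_w g`, signed with +z up:
#' positive means the worm floats. With the blend at 1090 kg/m3 and a worm at
#' 1080 kg/m3 the result is +0.58 nN.
#'
#' @param worm a [worm_body()].
#' @param fluid a [fluid_medium()].
#' @param g gravitational acceleration, m/s2.
#' @return signed force, N.
#' @export
buoyant_net_force <- function(worm, fluid, g = 9.81) {
  stopifnot(inherits(worm, "worm_body"), inherits(fluid, "fluid_medium"))
  .check_positive(g, "g")
  (fluid$density - worm$density) * worm$volume * g
}

#' Stokes drag coefficient
#'
#' `C_f = 6 pi mu r_s` for a sphere of Stokes radius `r_s`.
#'
#' @param fluid a [fluid_medium()].
#' @param r_s Stokes radius, m.
#' @return drag coefficient, N s/m.
#' @export
drag_coefficient <- function(fluid, r_s) {
  stopifnot(inherits(fluid, "fluid_medium"))
  r_s <- parse_quantity(r_s)
  .check_nonneg(r_s, "r_s")
  6 * pi * fluid$dynamic_viscosity * r_s
}

#' Estimate the Stokes radius from a passive settling speed
#'
#' For a randomly reorienting swimmer the thrust averages to zero over times
#' much longer than tau_r, so its mean settling speed is that of a passive
#' sphere and the balance with `F_p = 0` gives
#' `r_s = (rho_w - rho_f) V_w g / (6 pi mu U)`.
#'
#' @param settling_speed mean downward settling speed U, m/s (positive).
#' @param worm a [worm_body()] (its `stokes_radius` is ignored).
#' @param fluid a [fluid_medium()]; the worm must be denser than the fluid.
#' @param g gravitational acceleration, m/s2.
#' @return Stokes radius, m.
#' @export
estimate_stokes_radius <- function(settling_speed, worm, fluid, g = 9.81) {
  stopifnot(inherits(worm, "worm_body"), inherits(fluid, "fluid_medium"))
  settling_speed <- parse_quantity(settling_speed)
  .check_positive(settling_speed, "settling_speed")
  if (worm$density <= fluid$density)
    stop("worm must be denser than the fluid to settle", call. = FALSE)
  (worm$density - fluid$density) * worm$volume * g /
    (6 * pi * fluid$dynamic_viscosity * settling_speed)
}

#' Estimate propulsive thrust from two settling speeds
#'
#' Subtracting the force balance of a passive settler from that of a directed
#' downward swimmer with the same body (same reduced weight, same drag) leaves
#' `F_p = 6 pi mu r_s (U_directed - U_passive)`. The estimate is therefore
#' independent of the (poorly pinned) density difference.
#'
#' @param U_directed mean downward speed of the directed swimmer, m/s.
#' @param U_passive mean settling speed of the passive/random strain, m/s.
#' @param r_s shared Stokes radius, m.
#' @param fluid a [fluid_medium()].
#' @return thrust, N. Negative values (directed slower than passive) are
#'   returned with a warning and attribute `opposes_gravity = TRUE`.
#' @export
estimate_thrust <- function(U_directed, U_passive, r_s, fluid) {
  stopifnot(inherits(fluid, "fluid_medium"))
  U_directed <- parse_quantity(U_directed)
  U_passive <- parse_quantity(U_passive)
  r_s <- parse_quantity(r_s)
  .check_positive(U_directed, "U_directed")
  .check_positive(U_passive, "U_passive")
  .check_positive(r_s, "r_s")
  fp <- 6 * pi * fluid$dynamic_viscosity * r_s * (U_directed - U_passive)
  if (fp < 0) {
    warning("directed speed below passive settling speed: ",
            "estimated thrust opposes gravity", call. = FALSE)
    attr(fp, "opposes_gravity") <- TRUE
  }
  fp
}

#' Single-strain thrust estimate (density-sensitive form)
#'
#' Direct use of the balance for one directed swimmer:
#' `F_p = 6 pi mu r_s U - (rho_w - rho_f) V_w g` (downward-positive). This
#' form needs the density difference and body volume explicitly, which are
#' the least certain inputs; prefer [estimate_thrust()] when a passive
#' reference strain is available.
#'
#' @param U_directed mean downward swimming speed, m/s.
#' @param worm a [worm_body()] with `stokes_radius` set.
#' @param fluid a [fluid_medium()].
#' @param g gravitational acceleration, m/s2.
#' @return thrust, N (downward-positive).
#' @export
estimate_thrust_single_strain <- function(U_directed, worm, fluid, g = 9.81) {
  stopifnot(inherits(worm, "worm_body"), inherits(fluid, "fluid_medium"))
  if (is.null(worm$stokes_radius))
    stop("worm_body needs a stokes_radius for the single-strain form",
         call. = FALSE)
  U_directed <- parse_quantity(U_directed)
  .check_positive(U_directed, "U_directed")
  6 * pi * fluid$dynamic_viscosity * worm$stokes_radius * U_directed -
    (worm$density - fluid$density) * worm$volume * g
}

#' Terminal velocity from a force budget
#'
#' In the overdamped limit velocity is an algebraic function of the forces:
#' `U = (thrust + W zhat) / C_f`, with W the signed reduced weight.
#'
#' @param budget a [force_budget()].
#' @return velocity 3-vector (x, y, z), m/s; +z is up.
#' @export
terminal_velocity <- function(budget) {
  stopifnot(inherits(budget, "force_budget"))
  (budget$thrust + c(0, 0, budget$reduced_weight)) / budget$drag_coefficient
}

#' Apparent diffusion coefficient of a run-and-tumble swimmer
#'
#' A self-propelled particle moving at speed `U` whose heading decorrelates
#' with persistence time `tau_r` diffuses at long times with
#' `D_app = U^2 tau_r / 3`.
#'
#' @param U swimming speed, m/s.
#' @param tau_r directional persistence time, s.
#' @return diffusion coefficient, m2/s.
#' @export
apparent_diffusion <- function(U, tau_r) {
  U <- parse_quantity(U); tau_r <- parse_quantity(tau_r)
  .check_nonneg(U, "U"); .check_nonneg(tau_r, "tau_r")
  U^2 * tau_r / 3
}

#' Reynolds number of the moving particle
#'
#' `Re = rho_f U r_s / mu`. Values well below 1 justify the quasi-static
#' force balance used throughout.
#'
#' @param fluid a [fluid_medium()].
#' @param U speed, m/s.
#' @param r_s length scale (Stokes radius), m.
#' @return dimensionless Reynolds number.
#' @export
reynolds_number <- function(fluid, U, r_s) {
  stopifnot(inherits(fluid, "fluid_medium"))
  U <- parse_quantity(U); r_s <- parse_quantity(r_s)
  .check_nonneg(U, "U"); .check_nonneg(r_s, "r_s")
  fluid$density * U * r_s / fluid$dynamic_viscosity
}

#' Ideal-mixing density of a blend
#'
#' Volume-additive estimate `sum(v_i rho_i) / sum(v_i)` for a mixture such as
#' M9/colloidal-silica. Real blends can mix non-ideally (the working blend is
#' measured at 1.09 g/mL where ideal mixing predicts about 1.07), so treat
#' this as an estimate and measure the final density.
#'
#' @param volumes positive volume parts (any common unit).
#' @param densities component densities, kg/m3, same length as `volumes`.
#' @return mixture density, kg/m3.
#' @export
mixture_density <- function(volumes, densities) {
  if (length(volumes) == 0L) stop("empty mixture", call. = FALSE)
  if (length(volumes) != length(densities))
    stop("volumes and densities must have the same length", call. = FALSE)
  densities <- vapply(densities, parse_quantity, numeric(1))
  if (any(!is.finite(volumes)) || any(volumes < 0) || sum(volumes) <= 0)
    stop("volumes must be non-negative with a positive total", call. = FALSE)
  sum(volumes * densities) / sum(volumes)
}

#' Rescale thrust with gait frequency
#'
#' Propulsive thrust of an undulatory swimmer is proportional to the body
#' undulation frequency, so `F(new) = F(base) * new_freq / base_freq`.
#'
#' @param base_thrust reference thrust, N.
#' @param base_freq reference gait frequency, Hz (> 0).
#' @param new_freq new gait frequency, Hz.
#' @return rescaled thrust, N.
#' @export
thrust_from_frequency <- function(base_thrust, base_freq, new_freq) {
  base_thrust <- parse_quantity(base_thrust)
  base_freq <- parse_quantity(base_freq)
  new_freq <- parse_quantity(new_freq)
  .check_positive(base_freq, "base_freq")
  .check_nonneg(new_freq, "new_freq")
  base_thrust * new_freq / base_freq
}
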