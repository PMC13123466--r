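## Steady creeping flow in one column unit cell of the sorter, solved on a
## regular x-z grid with the stream-function / vorticity formulation:
##
##   lap(psi) = -omega,   lap(omega) = 0   (Stokes limit),
##
## with fully developed plane-Poiseuille profiles on the four conduit ports,
## no-slip walls (Thom wall vorticity), and zero net flux through the column
## imposed by the wall stream-function constants. The device Reynolds number
## is about 0.3, so dropping the inertial terms is a faithful simplification.
## Inner Poisson solves use a pre-factorized sparse Cholesky; the outer
## iteration relaxes the wall vorticity until the relative change in psi
## drops below `tolerance`.

# Unit-cell discretization. Returns grid, fluid mask, Dirichlet psi/omega.
.build_cell_grid <- function(geometry, h) {
  pitch <- geometry$column_pitch
  a <- geometry$conduit_height
  Hc <- geometry$column_height
  # a zero column height degenerates the cell to one straight conduit
  H <- if (Hc > 0) Hc + 2 * a else a
  Um <- geometry$mean_conduit_velocity

  nx <- max(round(pitch / h), 4L) + 1L
  nz <- max(round(H / h), 4L) + 1L
  hx <- pitch / (nx - 1L)
  hz <- H / (nz - 1L)
  x <- seq(0, pitch, length.out = nx)
  z <- seq(0, H, length.out = nz)

  # snap column walls to nodes, preserving the opening width
  jc0 <- round((pitch - geometry$column_width) / 2 / hx)
  jc1 <- jc0 + round(geometry$column_width / hx)
  xc0 <- jc0 * hx
  xc1 <- min(jc1 * hx, pitch)
  ia <- round(a / hz)            # node row of the feed-conduit ceiling
  it <- nz - 1L - ia             # 0-based row of collection-conduit floor

  iz <- matrix(seq_len(nz) - 1L, nz, nx)
  jx <- matrix(rep(seq_len(nx) - 1L, each = nz), nz, nx)
  if (Hc > 0) {
    in_bot <- iz <= ia
    in_top <- iz >= it
    in_col <- (jx >= jc0 & jx <= jc1) & !in_bot & !in_top
  } else {
    in_bot <- iz >= 0L                     # the whole cell is one conduit
    in_top <- matrix(FALSE, nz, nx)
    in_col <- matrix(FALSE, nz, nx)
  }
  fluid <- in_bot | in_top | in_col

  Qb <- Um * a
  Qt <- Um * a
  psi_bc <- matrix(NA_real_, nz, nx)
  omg_bc <- matrix(NA_real_, nz, nx)
  s_bot <- function(zz) pmin(pmax(zz / a, 0), 1)
  s_top <- function(zz) pmin(pmax((zz - (H - a)) / a, 0), 1)
  for (j in c(1L, nx)) {
    ib <- which(in_bot[, j]); s <- s_bot(z[ib])
    psi_bc[ib, j] <- Qb * (3 * s^2 - 2 * s^3)
    omg_bc[ib, j] <- -6 * Um * (1 - 2 * s) / a
    itp <- which(in_top[, j]); s <- s_top(z[itp])
    psi_bc[itp, j] <- Qb + Qt * (3 * s^2 - 2 * s^3)
    omg_bc[itp, j] <- -6 * Um * (1 - 2 * s) / a
  }
  psi_bc[1, ] <- 0
  psi_bc[nz, ] <- if (Hc > 0) Qb + Qt else Qb

  solid <- !fluid
  nb_solid <- matrix(FALSE, nz, nx)
  nb_solid[-1, ] <- nb_solid[-1, ] | solid[-nz, ]
  nb_solid[-nz, ] <- nb_solid[-nz, ] | solid[-1, ]
  nb_solid[, -1] <- nb_solid[, -1] | solid[, -nx]
  nb_solid[, -nx] <- nb_solid[, -nx] | solid[, -1]
  wall <- fluid & nb_solid & is.na(psi_bc)
  psi_bc[wall] <- Qb                       # interior walls separate the loops
  dirich <- fluid & !is.na(psi_bc)

  list(x = x, z = z, hx = hx, hz = hz, nx = nx, nz = nz,
       fluid = fluid, dirich = dirich, psi_bc = psi_bc, omg_bc = omg_bc,
       in_bot = in_bot, in_top = in_top, in_col = in_col,
       xc0 = xc0, xc1 = xc1, a = a, H = H, Q_conduit = Qb,
       s_bot = s_bot, s_top = s_top, Um = Um)
}

# velocities from psi by central differences; walls stay 0, ports analytic
.velocity_from_psi <- function(gr, psi) {
  nz <- gr$nz; nx <- gr$nx
  p <- psi; p[is.na(p)] <- 0
  ux <- matrix(0, nz, nx); uz <- matrix(0, nz, nx)
  ux[2:(nz - 1), ] <- (p[3:nz, ] - p[1:(nz - 2), ]) / (2 * gr$hz)
  uz[, 2:(nx - 1)] <- -(p[, 3:nx] - p[, 1:(nx - 2)]) / (2 * gr$hx)
  keep <- gr$fluid & !gr$dirich
  ux[!keep] <- 0; uz[!keep] <- 0
  for (j in c(1L, nx)) {
    ib <- which(gr$in_bot[, j]); s <- gr$s_bot(gr$z[ib])
    ux[ib, j] <- 6 * gr$Um * s * (1 - s)
    itp <- which(gr$in_top[, j]); s <- gr$s_top(gr$z[itp])
    ux[itp, j] <- 6 * gr$Um * s * (1 - s)
  }
  list(u_x = ux, u_z = uz)
}

.flow_field <- function(gr, psi, geometry, grid_spacing, method,
                        residual = 0, iterations = 0L,
                        residual_history = numeric(0)) {
  v <- .velocity_from_psi(gr, psi)
  structure(list(
    x = gr$x, z = gr$z, hx = gr$hx, hz = gr$hz,
    stream_function = psi, u_x = v$u_x, u_z = v$u_z,
    mask = gr$fluid, dirichlet = gr$dirich,
    geometry = geometry, grid_spacing = grid_spacing, method = method,
    residual = residual, iterations = iterations,
    residual_history = residual_history,
    xc0 = gr$xc0, xc1 = gr$xc1, conduit_height = gr$a,
    total_height = gr$H, Q_conduit = gr$Q_conduit),
    class = "flow_field_2d")
}

#' Solve the Stokes flow in one column unit cell
#'
#' Computes the steady creeping flow on the x-z cross-section of one vertical
#' column plus half a pitch of feed and collection conduit on either side.
#' Plane-Poiseuille profiles with the geometry's mean velocity are imposed on
#' the four conduit ports, walls are no-slip, and the wall stream-function
#' constants impose zero net flux through the column (both syringes pump at
#' the same rate, and dye tracing shows no crossflow between the conduits).
#'
#' @param geometry a [sorter_geometry()].
#' @param grid_spacing target grid spacing, m (snapped so the cell divides
#'   evenly; must be at most `column_width / 10`).
#' @param tolerance relative tolerance on the stream-function update.
#' @param max_iter cap on outer (wall-vorticity) iterations.
#' @param relax under-relaxation of the Thom wall-vorticity update. The
#'   stable range shrinks roughly linearly with the grid spacing; the default
#'   `0.4 * grid_spacing / 1e-3` (capped at 0.1) sits safely inside it and is
#'   halved automatically if divergence is detected.
#' @return object of class `flow_field_2d`: grid coordinates, stream
#'   function, velocity components, fluid mask, solver diagnostics.
#' @seealso [vortex_diagnostics()], [check_flux_balance()],
#'   [analytic_fallback_field()]
#' @export
solve_unit_cell_flow <- function(geometry, grid_spacing = 1e-4,
                                 tolerance = 1e-8, max_iter = 5000,
                                 relax = NULL) {
  stopifnot(inherits(geometry, "sorter_geometry"))
  .check_positive(grid_spacing, "grid_spacing")
  if (grid_spacing > geometry$column_width / 10)
    stop("grid_spacing must be at most column_width / 10", call. = FALSE)
  if (is.null(relax)) relax <- min(0.1, 0.4 * grid_spacing / 1e-3)
  gr <- .build_cell_grid(geometry, grid_spacing)

  if (geometry$mean_conduit_velocity == 0) {
    psi <- matrix(0, gr$nz, gr$nx); psi[!gr$fluid] <- NA
    return(.flow_field(gr, psi, geometry, grid_spacing, "stokes"))
  }

  nz <- gr$nz; nx <- gr$nx
  unk <- gr$fluid & !gr$dirich
  n <- sum(unk)
  unkid <- matrix(0L, nz, nx); unkid[unk] <- seq_len(n)
  dirid <- matrix(0L, nz, nx); dirid[gr$dirich] <- seq_len(sum(gr$dirich))
  cz <- 1 / gr$hz^2; cx <- 1 / gr$hx^2

  ks <- which(unk)
  ii <- unkid[ks]; jj <- ii; vv <- rep(2 * (cx + cz), n)
  bi <- integer(0); bj <- integer(0); bv <- numeric(0)
  for (off in list(c(-1L, cz), c(1L, cz), c(-nz, cx), c(nz, cx))) {
    kn <- ks + off[[1]]
    cc <- off[[2]]
    wu <- unk[kn]
    ii <- c(ii, unkid[ks[wu]]); jj <- c(jj, unkid[kn[wu]])
    vv <- c(vv, rep(-cc, sum(wu)))
    wd <- gr$dirich[kn]
    bi <- c(bi, unkid[ks[wd]]); bj <- c(bj, dirid[kn[wd]])
    bv <- c(bv, rep(cc, sum(wd)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  B <- Matrix::sparseMatrix(i = bi, j = bj, x = bv,
                            dims = c(n, sum(gr$dirich)))
  Fct <- Matrix::Cholesky(Matrix::forceSymmetric(A))

  # wall nodes and their interior normals for the Thom update
  wall_k <- which(gr$dirich & is.na(gr$omg_bc))
  thom_nb <- lapply(list(c(-1L, gr$hz), c(1L, gr$hz),
                         c(-nz, gr$hx), c(nz, gr$hx)), function(o) {
    kn <- wall_k + o[[1]]
    ok <- kn >= 1 & kn <= nz * nx
    ok[ok] <- unk[kn[ok]]
    list(kn = kn, ok = ok, h2 = o[[2]]^2)
  })

  psi <- matrix(0, nz, nx)
  psi[gr$dirich] <- gr$psi_bc[gr$dirich]
  omg_d <- ifelse(is.na(gr$omg_bc[gr$dirich]), 0, gr$omg_bc[gr$dirich])
  psi_d <- gr$psi_bc[gr$dirich]
  wall_d <- match(wall_k, which(gr$dirich))

  hist <- numeric(0)
  best <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # Thom wall vorticity, averaged over available interior normals
    num <- numeric(length(wall_k)); den <- numeric(length(wall_k))
    for (nb in thom_nb) {
      w <- nb$ok
      num[w] <- num[w] + 2 * (psi[wall_k[w]] - psi[nb$kn[w]]) / nb$h2
      den[w] <- den[w] + 1
    }
    new_w <- ifelse(den > 0, num / pmax(den, 1), 0)
    omg_d[wall_d] <- (1 - relax) * omg_d[wall_d] + relax * new_w
    omg_u <- as.vector(Matrix::solve(Fct, as.vector(B %*% omg_d)))
    psi_new <- as.vector(Matrix::solve(Fct,
                                       omg_u + as.vector(B %*% psi_d)))
    d <- max(abs(psi_new - psi[unk])) / max(max(abs(psi_new)), 1e-30)
    psi[unk] <- psi_new
    hist <- c(hist, d)
    if (!is.finite(d) || (it > 20 && d > 100 * best)) {
      relax <- relax / 2              # divergence guard: damp and continue
      psi[unk] <- 0
      omg_d[wall_d] <- 0
      best <- Inf
      next
    }
    best <- min(best, d)
    if (d < tolerance) break
  }
  if (it >= max_iter && (length(hist) == 0 || utils::tail(hist, 1) >= tolerance)) {
    cond <- simpleError(sprintf(
      "flow solver did not converge in %d iterations (last residual %.3g)",
      max_iter, utils::tail(hist, 1)))
    class(cond) <- c("flow_solver_failure", class(cond))
    cond$residual_history <- hist
    stop(cond)
  }
  psi[!gr$fluid] <- NA
  .flow_field(gr, psi, geometry, grid_spacing, "stokes",
              residual = utils::tail(hist, 1), iterations = it,
              residual_history = hist)
}

#' Analytic stand-in flow field
#'
#' Cheap divergence-consistent field for fast agent simulations: fully
#' developed plane Poiseuille in both conduits (including across the column
#' mouths) and quiescent fluid in the columns. It omits the junction
#' vortices that the Stokes solve resolves.
#'
#' @param geometry a [sorter_geometry()].
#' @param grid_spacing grid spacing, m.
#' @return object of class `flow_field_2d`.
#' @export
analytic_fallback_field <- function(geometry, grid_spacing = 1e-4) {
  stopifnot(inherits(geometry, "sorter_geometry"))
  gr <- .build_cell_grid(geometry, grid_spacing)
  psi <- matrix(NA_real_, gr$nz, gr$nx)
  Qb <- gr$Q_conduit
  for (j in seq_len(gr$nx)) {
    ib <- which(gr$in_bot[, j]); s <- gr$s_bot(gr$z[ib])
    psi[ib, j] <- Qb * (3 * s^2 - 2 * s^3)
    itp <- which(gr$in_top[, j]); s <- gr$s_top(gr$z[itp])
    psi[itp, j] <- Qb + Qb * (3 * s^2 - 2 * s^3)
    ic <- which(gr$in_col[, j]); psi[ic, j] <- Qb
  }
  fld <- .flow_field(gr, psi, geometry, grid_spacing, "analytic")
  # conduit profiles everywhere, zero in the columns, exact no-slip
  ux <- matrix(0, gr$nz, gr$nx)
  for (j in seq_len(gr$nx)) {
    ib <- which(gr$in_bot[, j]); s <- gr$s_bot(gr$z[ib])
    ux[ib, j] <- 6 * gr$Um * s * (1 - s)
    itp <- which(gr$in_top[, j]); s <- gr$s_top(gr$z[itp])
    ux[itp, j] <- 6 * gr$Um * s * (1 - s)
  }
  fld$u_x <- ux
  fld$u_z <- matrix(0, gr$nz, gr$nx)
  fld
}

#' @export
print.flow_field_2d <- function(x, ...) {
  cat(sprintf(
    "<flow_field_2d> %s, %d x %d grid (h = %.3g mm), residual %.3g (%d iterations)\n",
    x$method, length(x$z), length(x$x), 1e3 * x$grid_spacing, x$residual,
    x$iterations))
  invisible(x)
}

#' Vortex diagnostics of a unit-cell field
#'
#' The conduit flow shears across the column mouths and drives slow
#' recirculating vortices a short way into the columns. This reports the
#' maximum speed over column-interior nodes (more than one grid cell from
#' the side walls) and the vertical penetration depth of the vortices:
#' the distance from the feed-side column mouth at which the
#' horizontal-slice maximum speed first falls below `threshold` times its
#' value at the mouth.
#'
#' @param field a `flow_field_2d` from [solve_unit_cell_flow()].
#' @param threshold decay threshold as a fraction of the mouth value
#'   (default 1 percent).
#' @return list with `max_column_speed` (m/s), `penetration_depth` (m),
#'   `threshold`, and the slice profile (`depth`, `slice_max_speed`).
#' @export
vortex_diagnostics <- function(field, threshold = 0.01) {
  stopifnot(inherits(field, "flow_field_2d"))
  spd <- sqrt(field$u_x^2 + field$u_z^2)
  colj <- which(field$x > field$xc0 + 1.5 * field$hx &
                field$x < field$xc1 - 1.5 * field$hx)
  a <- field$conduit_height; H <- field$total_height
  coli <- which(field$z > a + field$hz / 2 & field$z < H - a - field$hz / 2)
  if (!length(colj) || !length(coli))
    return(list(max_column_speed = 0, penetration_depth = 0,
                threshold = threshold,
                profile = data.frame(depth = numeric(0),
                                     slice_max_speed = numeric(0))))
  vmax <- max(spd[coli, colj])
  mouth_i <- which.min(abs(field$z - a))
  mouth_val <- max(spd[mouth_i, colj])
  slice_max <- apply(spd[coli, colj, drop = FALSE], 1, max)
  depth <- field$z[coli] - a
  prof <- data.frame(depth = depth, slice_max_speed = slice_max)
  if (mouth_val <= 0)
    return(list(max_column_speed = 0, penetration_depth = 0,
                threshold = threshold, profile = prof))
  upper <- depth <= (H - 2 * a) / 2       # scan the feed-side half only
  k <- which(slice_max < threshold * mouth_val & upper)[1]
  pen <- if (is.na(k)) NA_real_ else depth[k]
  list(max_column_speed = vmax, penetration_depth = pen,
       threshold = threshold, mouth_speed = mouth_val, profile = prof)
}

# trapezoid rule on a uniform grid
.trapz <- function(y, h) if (length(y) < 2) 0 else
  h * (sum(y) - (y[1] + y[length(y)]) / 2)

#' Flux-balance diagnostics
#'
#' Checks discrete mass conservation of a unit-cell field: the flux entering
#' each conduit against the flux leaving it (measured one node inside the
#' ports, where the vertical cut spans only the conduit), and the net
#' vertical flux across a mid-column horizontal cut, all relative to the
#' nominal conduit flux. The experimental bound on collected-volume
#' imbalance is 3 percent; the discrete field conserves flux far more
#' tightly.
#'
#' @param field a `flow_field_2d`.
#' @return list with `bottom_mismatch`, `top_mismatch`, `column_net_flux`
#'   (all relative to the conduit flux) and their maximum `max_mismatch`.
#' @export
check_flux_balance <- function(field) {
  stopifnot(inherits(field, "flow_field_2d"))
  Q <- field$Q_conduit
  if (Q <= 0)
    return(list(bottom_mismatch = 0, top_mismatch = 0,
                column_net_flux = 0, max_mismatch = 0))
  a <- field$conduit_height; H <- field$total_height
  nx <- length(field$x)
  ib <- which(field$z <= a + field$hz / 2)
  itp <- which(field$z >= H - a - field$hz / 2)
  jin <- 2L; jout <- nx - 1L
  bm <- abs(.trapz(field$u_x[ib, jin], field$hz) -
            .trapz(field$u_x[ib, jout], field$hz)) / Q
  tm <- abs(.trapz(field$u_x[itp, jin], field$hz) -
            .trapz(field$u_x[itp, jout], field$hz)) / Q
  colj <- which(field$x >= field$xc0 & field$x <= field$xc1)
  mid_i <- which.min(abs(field$z - H / 2))
  cn <- if (length(colj) > 1 && field$z[mid_i] > a && field$z[mid_i] < H - a)
    abs(.trapz(field$u_z[mid_i, colj], field$hx)) / Q else 0
  list(bottom_mismatch = bm, top_mismatch = tm, column_net_flux = cn,
       max_mismatch = max(bm, tm, cn))
}
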