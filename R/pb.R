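# Finite-difference linearized Poisson-Boltzmann electrostatics.
#
# Potential is carried in kT/e, lengths in Angstrom, charges in e. With
# C = e^2/(4 pi eps0 kT) expressed in kT.Angstrom/e^2, the Coulomb potential
# of a charge q in a uniform dielectric eps is C q / (eps r) kT/e, and the
# linearized PB equation reads
#     div(eps grad phi) - eps_s kappa^2(r) phi = -4 pi C rho,
# discretized on a uniform cubic grid with harmonic-mean face dielectrics
# and solved by successive over-relaxation (compiled kernel).

# Coulomb constant in kT.Angstrom/e^2 at temperature T (Kelvin):
# e^2/(4 pi eps0) = 332.0637 kcal.Angstrom/mol, kT = 0.0019872 T kcal/mol.
.coulomb_kt <- function(temperature) 332.0637 / (0.0019872 * temperature)

#' Debye screening parameter
#'
#' Inverse screening length (1/Angstrom) of a 1:1 electrolyte at the given
#' molar ionic strength, solvent dielectric and temperature, computed as
#' `kappa^2 = 8 pi lambda_B n` with `lambda_B` the Bjerrum length and `n`
#' the per-species number density.
#'
#' @param ionic_strength mol/L.
#' @param solvent_dielectric relative permittivity of the solvent.
#' @param temperature Kelvin.
#' @return kappa in 1/Angstrom (0 at zero ionic strength).
#' @export
debye_kappa <- function(ionic_strength, solvent_dielectric = 80,
                        temperature = 298.15) {
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  lambda_b <- .coulomb_kt(temperature) / solvent_dielectric
  n_per_a3 <- ionic_strength * 6.02214076e-4  # mol/L -> molecules/Angstrom^3
  sqrt(8 * pi * lambda_b * n_per_a3)
}

#' Solver parameters for the linearized PB solver
#'
#' Defaults follow the standard continuum-electrostatics protocol for
#' protein work: interior dielectric 2, solvent dielectric 80, 0.145 M
#' ionic strength, 1.4-Angstrom solvent probe, 2-Angstrom Stern (ion
#' exclusion) layer, 251 grid points per axis, and two-stage focusing with
#' 50%/90% solute fill. Desk-scale grids (65 points) are recommended for
#' interactive use; the full 251-point grid is supported but slow.
#'
#' @param interior_dielectric,solvent_dielectric relative permittivities.
#' @param ionic_strength mol/L (1:1 electrolyte assumed).
#' @param temperature Kelvin.
#' @param probe_radius solvent probe radius, Angstrom.
#' @param stern_radius ion-exclusion (Stern) layer thickness, Angstrom.
#' @param grid_n grid points per axis (odd, >= 5).
#' @param coarse_fill,fine_fill solute fill fractions of the two focusing
#'   stages, in (0, 1].
#' @param tol convergence tolerance on the largest node update, kT/e.
#' @param max_iter relaxation sweep cap.
#' @return a validated `pb_params` list.
#' @export
pb_params <- function(interior_dielectric = 2, solvent_dielectric = 80,
                      ionic_strength = 0.145, temperature = 298.15,
                      probe_radius = 1.4, stern_radius = 2.0,
                      grid_n = 251L, coarse_fill = 0.5, fine_fill = 0.9,
                      tol = 1e-6, max_iter = 10000L) {
  if (interior_dielectric <= 0 || solvent_dielectric <= 0) {
    stop("dielectric constants must be positive")
  }
  grid_n <- as.integer(grid_n)
  if (grid_n < 5L || grid_n %% 2L == 0L) {
    stop("grid_n must be odd and at least 5")
  }
  if (coarse_fill <= 0 || coarse_fill > 1 || fine_fill <= 0 || fine_fill > 1) {
    stop("fill fractions must lie in (0, 1]")
  }
  if (ionic_strength < 0) stop("ionic strength must be >= 0")
  if (probe_radius < 0 || stern_radius < 0) stop("radii must be >= 0")
  structure(list(interior_dielectric = interior_dielectric,
                 solvent_dielectric = solvent_dielectric,
                 ionic_strength = ionic_strength,
                 temperature = temperature,
                 probe_radius = probe_radius, stern_radius = stern_radius,
                 grid_n = grid_n, coarse_fill = coarse_fill,
                 fine_fill = fine_fill, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "pb_params")
}

#' Cubic grid geometry
#'
#' @param center grid center (length-3, Angstrom).
#' @param length edge length of the cube, Angstrom.
#' @param n grid points per axis (odd so the center is a node).
#' @return a `pb_grid`: `origin`, `spacing`, `n`.
#' @export
pb_grid <- function(center = c(0, 0, 0), length, n) {
  n <- as.integer(n)
  if (n < 5L || n %% 2L == 0L) stop("n must be odd and at least 5")
  if (length <= 0) stop("grid length must be positive")
  spacing <- length / (n - 1L)
  structure(list(origin = center - length / 2, spacing = spacing, n = n),
            class = "pb_grid")
}

.grid_axes <- function(geom) {
  lapply(1:3, function(k) geom$origin[k] + geom$spacing * (0:(geom$n - 1L)))
}

#' Dielectric and ion-accessibility maps
#'
#' Grid nodes within `atom radius + probe` of any atom are solute interior
#' (interior dielectric, no mobile ions); nodes beyond that but within
#' `atom radius + stern` form the Stern shell (solvent dielectric, still no
#' ions); all remaining nodes are bulk solvent with the Debye screening of
#' the assigned ionic strength. The interior is the union of
#' probe-inflated atomic spheres, which coincides with the rolling-probe
#' molecular surface for isolated spheres.
#'
#' @param system a `charge_system`.
#' @param params a `pb_params`.
#' @param geom a `pb_grid`.
#' @return list with `eps` (n^3 array, relative permittivity per node) and
#'   `kappa2` (n^3 array, screening term `eps_s kappa^2` per node, 1/A^2).
#' @export
build_maps <- function(system, params, geom) {
  stopifnot(inherits(system, "charge_system"), inherits(params, "pb_params"),
            inherits(geom, "pb_grid"))
  n <- geom$n
  ax <- .grid_axes(geom)
  kap2_bulk <- params$solvent_dielectric *
    debye_kappa(params$ionic_strength, params$solvent_dielectric,
                params$temperature)^2
  eps <- array(params$solvent_dielectric, dim = c(n, n, n))
  kap2 <- array(kap2_bulk, dim = c(n, n, n))
  a <- system$atoms
  if (nrow(a)) {
    # the van-der-Waals solute must fit the grid (fill fraction <= 1);
    # probe/Stern shells may be clipped at the edge, as in focused solves
    # where the fine-grid boundary values come from the coarse map anyway
    hi <- geom$origin + geom$spacing * (n - 1L)
    if (any(a$x - a$radius < geom$origin[1] | a$x + a$radius > hi[1] |
            a$y - a$radius < geom$origin[2] | a$y + a$radius > hi[2] |
            a$z - a$radius < geom$origin[3] | a$z + a$radius > hi[3])) {
      stop("solute extends beyond the grid; use a larger grid length")
    }
    for (i in seq_len(nrow(a))) {
      r_in <- a$radius[i] + params$probe_radius
      r_st <- a$radius[i] + params$stern_radius
      r_max <- max(r_in, r_st)
      ix <- which(abs(ax[[1]] - a$x[i]) <= r_max)
      iy <- which(abs(ax[[2]] - a$y[i]) <= r_max)
      iz <- which(abs(ax[[3]] - a$z[i]) <= r_max)
      if (!length(ix) || !length(iy) || !length(iz)) next
      dx2 <- (ax[[1]][ix] - a$x[i])^2
      dy2 <- (ax[[2]][iy] - a$y[i])^2
      dz2 <- (ax[[3]][iz] - a$z[i])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      sub_in <- d2 <= r_in^2
      sub_st <- d2 <= r_st^2
      eps[ix, iy, iz][sub_in] <- params$interior_dielectric
      kap2[ix, iy, iz][sub_st] <- 0
    }
  }
  list(eps = eps, kappa2 = kap2)
}

#' Debye-Hueckel boundary potentials
#'
#' Every node on the six grid faces receives the screened-Coulomb
#' superposition `sum_i C q_i exp(-kappa r_i) / (eps_s r_i)` in kT/e.
#'
#' @inheritParams build_maps
#' @return n^3 array, zero in the interior, boundary faces filled.
#' @export
boundary_potentials <- function(system, params, geom) {
  stopifnot(inherits(system, "charge_system"), inherits(geom, "pb_grid"))
  n <- geom$n
  phi <- array(0, dim = c(n, n, n))
  a <- system$atoms
  if (nrow(a) == 0L) return(phi)
  ax <- .grid_axes(geom)
  kap <- debye_kappa(params$ionic_strength, params$solvent_dielectric,
                     params$temperature)
  ck <- .coulomb_kt(params$temperature) / params$solvent_dielectric
  bfaces <- which(slice.index(phi, 1) %in% c(1L, n) |
                  slice.index(phi, 2) %in% c(1L, n) |
                  slice.index(phi, 3) %in% c(1L, n))
  idx <- arrayInd(bfaces, dim(phi))
  px <- ax[[1]][idx[, 1]]
  py <- ax[[2]][idx[, 2]]
  pz <- ax[[3]][idx[, 3]]
  val <- numeric(length(bfaces))
  for (i in seq_len(nrow(a))) {
    r <- sqrt((px - a$x[i])^2 + (py - a$y[i])^2 + (pz - a$z[i])^2)
    if (any(r < 1e-9)) {
      stop("boundary node coincides with a charge; grid misconfigured")
    }
    val <- val + ck * a$charge[i] * exp(-kap * r) / r
  }
  phi[bfaces] <- val
  phi
}

# trilinear spreading of point charges to the eight surrounding nodes
.spread_charges <- function(system, geom) {
  n <- geom$n
  q <- array(0, dim = c(n, n, n))
  a <- system$atoms
  if (nrow(a) == 0L) return(q)
  for (i in seq_len(nrow(a))) {
    fr <- (c(a$x[i], a$y[i], a$z[i]) - geom$origin) / geom$spacing
    i0 <- pmin(pmax(floor(fr), 0), n - 2L)
    t <- fr - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) t[1] else 1 - t[1]) *
           (if (dy) t[2] else 1 - t[2]) *
           (if (dz) t[3] else 1 - t[3])
      ii <- i0 + c(dx, dy, dz) + 1L
      q[ii[1], ii[2], ii[3]] <- q[ii[1], ii[2], ii[3]] + w * a$charge[i]
    }
  }
  q
}

#' Solve the linearized Poisson-Boltzmann equation on a grid
#'
#' Assembles dielectric/ion maps (unless supplied), spreads the point
#' charges trilinearly, applies Debye-Hueckel boundary values (unless
#' supplied) and relaxes the finite-difference equations by successive
#' over-relaxation with harmonic-mean face dielectrics until the largest
#' node update falls below `params$tol`.
#'
#' @inheritParams build_maps
#' @param maps optional precomputed [build_maps()] result.
#' @param boundary optional precomputed boundary array (also used as the
#'   initial guess).
#' @param omega over-relaxation factor; default `2 / (1 + sin(pi / n))`.
#' @return a `potential_map`: `phi` (n^3 array, kT/e), `geom`, `params`,
#'   `iterations`, `converged`, `max_update`, `max_residual`, `history`.
#'   Non-convergence within `params$max_iter` is an error carrying the
#'   update history.
#' @export
solve_lpb <- function(system, params, geom, maps = NULL, boundary = NULL,
                      omega = NULL) {
  stopifnot(inherits(params, "pb_params"), inherits(geom, "pb_grid"))
  if (is.null(maps)) maps <- build_maps(system, params, geom)
  if (is.null(boundary)) boundary <- boundary_potentials(system, params, geom)
  n <- geom$n
  h <- geom$spacing
  src <- .spread_charges(system, geom) *
    (4 * pi * .coulomb_kt(params$temperature) / h)
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / n))
  res <- sor_lpb(as.double(maps$eps), as.double(maps$kappa2 * h^2),
                 as.double(src), as.double(boundary),
                 dim(maps$eps), omega, params$tol, params$max_iter)
  if (!res$converged) {
    cond <- simpleError(paste0("LPB solver did not converge in ",
                               params$max_iter, " sweeps (last update ",
                               format(res$max_update), " kT/e)"))
    cond$history <- res$history
    stop(cond)
  }
  phi <- array(res$phi, dim = c(n, n, n))
  structure(list(phi = phi, geom = geom, params = params,
                 iterations = res$iterations, converged = res$converged,
                 max_update = res$max_update,
                 max_residual = res$max_residual,
                 history = res$history),
            class = "potential_map")
}

#' Trilinear interpolation of a potential map
#'
#' @param map a `potential_map`.
#' @param points numeric matrix (m x 3) or length-3 vector, Angstrom.
#' @return numeric vector of interpolated potentials, kT/e.
#' @export
interpolate_potential <- function(map, points) {
  stopifnot(inherits(map, "potential_map"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  geom <- map$geom
  n <- geom$n
  fr <- sweep(points, 2L, geom$origin) / geom$spacing
  if (any(fr < -1e-9) || any(fr > n - 1 + 1e-9)) {
    stop("point(s) outside the potential map bounds")
  }
  fr <- pmin(pmax(fr, 0), n - 1)
  i0 <- pmin(floor(fr), n - 2)
  t <- fr - i0
  out <- numeric(nrow(points))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx) t[, 1] else 1 - t[, 1]) *
         (if (dy) t[, 2] else 1 - t[, 2]) *
         (if (dz) t[, 3] else 1 - t[, 3])
    out <- out + w * map$phi[cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1,
                                   i0[, 3] + dz + 1)]
  }
  out
}

#' Two-stage focused solve
#'
#' First solves on a coarse grid sized so the solute fills `coarse_fill`
#' of the edge length (Debye-Hueckel boundaries), then on a fine grid
#' (`fine_fill`) whose boundary values are trilinearly interpolated from
#' the coarse solution. Both stages use `params$grid_n` points per axis.
#'
#' @inheritParams build_maps
#' @return the fine-stage `potential_map`, with the coarse map attached as
#'   attribute `coarse`.
#' @export
focused_solve <- function(system, params) {
  stopifnot(inherits(system, "charge_system"))
  a <- system$atoms
  if (nrow(a) == 0L) stop("cannot size a focusing grid for an empty system")
  lo <- c(min(a$x - a$radius), min(a$y - a$radius), min(a$z - a$radius))
  hi <- c(max(a$x + a$radius), max(a$y + a$radius), max(a$z + a$radius))
  extent <- max(c(hi - lo, 1e-3))
  center <- (hi + lo) / 2
  coarse_geom <- pb_grid(center, extent / params$coarse_fill, params$grid_n)
  coarse <- solve_lpb(system, params, coarse_geom)
  fine_geom <- pb_grid(center, extent / params$fine_fill, params$grid_n)
  ax <- .grid_axes(fine_geom)
  nf <- fine_geom$n
  bidx <- which(slice.index(array(0, c(nf, nf, nf)), 1) %in% c(1L, nf) |
                slice.index(array(0, c(nf, nf, nf)), 2) %in% c(1L, nf) |
                slice.index(array(0, c(nf, nf, nf)), 3) %in% c(1L, nf))
  ind <- arrayInd(bidx, c(nf, nf, nf))
  pts <- cbind(ax[[1]][ind[, 1]], ax[[2]][ind[, 2]], ax[[3]][ind[, 3]])
  boundary <- array(0, dim = c(nf, nf, nf))
  boundary[bidx] <- interpolate_potential(coarse, pts)
  fine <- solve_lpb(system, params, fine_geom, boundary = boundary)
  attr(fine, "coarse") <- coarse
  fine
}

#' Classify the electrostatic sign of a pocket patch
#'
#' Averages the trilinearly interpolated potential over the patch points
#' and labels the pocket `positive` / `negative` when the mean exceeds the
#' threshold in magnitude (default 5 kT/e, the conventional surface-coloring
#' cutoff), `neutral` otherwise.
#'
#' @param map a `potential_map`.
#' @param patch numeric matrix (m x 3) of evaluation points, Angstrom.
#' @param threshold classification cutoff, kT/e.
#' @return list with `mean_potential` (kT/e) and `label`.
#' @export
classify_pocket <- function(map, patch, threshold = 5) {
  if (is.null(dim(patch))) patch <- matrix(patch, ncol = 3L)
  if (nrow(patch) == 0L) stop("empty patch")
  m <- mean(interpolate_potential(map, patch))
  label <- if (m < -threshold) "negative" else
    if (m > threshold) "positive" else "neutral"
  list(mean_potential = m, label = label)
}

#' @export
print.potential_map <- function(x, ...) {
  cat("Potential map:", x$geom$n, "^3 grid, spacing",
      format(x$geom$spacing, digits = 4), "A |",
      x$iterations, "sweeps, max update",
      format(x$max_update, digits = 3), "kT/e\n")
  invisible(x)
}
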