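test_that("dielectric and ion maps reproduce a brute-force distance check", {
  sys <- charge_system(0.3, -0.2, 0.1, 1, 2)
  p <- pb_params(grid_n = 17, tol = 1e-6)
  g <- pb_grid(c(0, 0, 0), length = 12, n = 17)
  maps <- build_maps(sys, p, g)
  ax <- lapply(1:3, function(k) g$origin[k] + g$spacing * 0:16)
  n_in <- 0
  for (i in 1:17) for (j in 1:17) for (k in 1:17) {
    d <- sqrt((ax[[1]][i] - 0.3)^2 + (ax[[2]][j] + 0.2)^2 + (ax[[3]][k] - 0.1)^2)
    eps_exp <- if (d <= 2 + 1.4) 2 else 80
    kap_zero <- d <= 2 + 2
    expect_identical(maps$eps[i, j, k], eps_exp)
    expect_identical(maps$kappa2[i, j, k] == 0, kap_zero)
    if (eps_exp == 2) n_in <- n_in + 1
  }
  expect_equal(sum(maps$eps == 2), n_in)
  # no atoms: uniform solvent and uniform screening
  m0 <- build_maps(charge_system(numeric(0), numeric(0), numeric(0),
                                 numeric(0), numeric(0)), p, g)
  expect_true(all(m0$eps == 80))
  expect_equal(length(unique(as.vector(m0$kappa2))), 1L)
})

test_that("Debye-Hueckel boundary values match the screened-Coulomb closed form", {
  p <- pb_params(grid_n = 9, tol = 1e-6)
  g <- pb_grid(c(0, 0, 0), length = 16, n = 9)
  # zero charge: zero boundary
  z <- boundary_potentials(charge_system(0, 0, 0, 0, 1), p, g)
  expect_true(all(z == 0))
  # centred unit charge: symmetric faces, kappa = 0 limit is plain Coulomb
  sys <- charge_system(0, 0, 0, 1, 1)
  b <- boundary_potentials(sys, p, g)
  expect_equal(b[1, 5, 5], b[9, 5, 5], tolerance = 1e-12)
  expect_equal(b[5, 1, 5], b[5, 5, 9], tolerance = 1e-12)
  p0 <- pb_params(ionic_strength = 0, grid_n = 9, tol = 1e-6)
  b0 <- boundary_potentials(sys, p0, g)
  C <- coulomb_kt_si(298.15)
  expect_equal(b0[1, 5, 5], C / (80 * 8), tolerance = 1e-3)
  corner <- sqrt(3 * 8^2)
  expect_equal(b0[1, 1, 1], C / (80 * corner), tolerance = 1e-3)
  # screened values: verify against independently computed kappa
  kap <- kappa_si(0.145)
  expect_equal(b[1, 5, 5], C * exp(-kap * 8) / (80 * 8), tolerance = 1e-3)
})

test_that("the solver is linear and antisymmetric under charge negation", {
  # identical two-atom geometry throughout; only the charges vary
  p <- pb_params(grid_n = 33, tol = 1e-9)
  g <- pb_grid(c(0, 0, 0), length = 16, n = 33)
  xs <- c(-1.5, 1.5)
  ys <- c(0, 0.5)
  zs <- c(0, 0)
  rads <- c(1.5, 1.2)
  m1 <- solve_lpb(charge_system(xs, ys, zs, c(1, 0), rads), p, g)
  m2 <- solve_lpb(charge_system(xs, ys, zs, c(0, -0.7), rads), p, g)
  m12 <- solve_lpb(charge_system(xs, ys, zs, c(1, -0.7), rads), p, g)
  expect_lt(max(abs(m12$phi - m1$phi - m2$phi)), 10 * 1e-6)
  # charge negation flips the map exactly
  mneg <- solve_lpb(charge_system(xs, ys, zs, c(-1, 0), rads), p, g)
  expect_equal(mneg$phi, -m1$phi, tolerance = 1e-12)
  # zero charge, zero boundary: identically zero map
  mz <- solve_lpb(charge_system(xs, ys, zs, c(0, 0), rads), p, g)
  expect_true(all(mz$phi == 0))
})

# exact Dirichlet data from the closed form, to isolate discretization error
born_boundary <- function(geom) {
  n <- geom$n
  phi <- array(0, dim = c(n, n, n))
  ax <- lapply(1:3, function(k) geom$origin[k] + geom$spacing * (0:(n - 1)))
  bidx <- which(slice.index(phi, 1) %in% c(1L, n) |
                slice.index(phi, 2) %in% c(1L, n) |
                slice.index(phi, 3) %in% c(1L, n))
  ind <- arrayInd(bidx, dim(phi))
  r <- sqrt(ax[[1]][ind[, 1]]^2 + ax[[2]][ind[, 2]]^2 + ax[[3]][ind[, 3]]^2)
  phi[bidx] <- born_analytic(r)
  phi
}

test_that("refining the grid shrinks the Born-ion error monotonically", {
  sys <- charge_system(0, 0, 0, 1, 2)
  r <- seq(6, 10, by = 1)
  errs <- vapply(c(33, 65, 129), function(n) {
    p <- pb_params(grid_n = n, tol = 1e-7)
    g <- pb_grid(c(0, 0, 0), length = 24, n = n)
    m <- solve_lpb(sys, p, g, boundary = born_boundary(g))
    max(abs(interpolate_potential(m, cbind(r, 0, 0)) / born_analytic(r) - 1))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("the far field decays with the analytic Debye length", {
  # uniform solvent, kappa from 0.145 M: fit the decay of log(phi * r)
  p <- pb_params(interior_dielectric = 80, solvent_dielectric = 80,
                 ionic_strength = 0.145, probe_radius = 0, stern_radius = 0,
                 grid_n = 65, tol = 1e-8)
  g <- pb_grid(c(0, 0, 0), length = 40, n = 65)
  m <- solve_lpb(charge_system(0, 0, 0, 1, 0), p, g)
  r <- seq(8, 16, by = 0.625)
  phi <- interpolate_potential(m, cbind(r, 0, 0))
  slope <- -coef(lm(log(phi * r) ~ r))[[2]]
  kap <- kappa_si(0.145)
  expect_lt(abs(1 / slope - 1 / kap) / (1 / kap), 0.15)
})

test_that("non-convergence is an error carrying the update history", {
  p <- pb_params(grid_n = 17, tol = 1e-12, max_iter = 3)
  g <- pb_grid(c(0, 0, 0), length = 12, n = 17)
  err <- tryCatch(solve_lpb(charge_system(0, 0, 0, 1, 1), p, g),
                  error = identity)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "did not converge")
  expect_equal(length(err$history), 3)
})

test_that("pocket classification labels the sign of a buried charge", {
  g <- pb_grid(c(0, 0, 0), length = 16, n = 33)
  p <- pb_params(grid_n = 33, tol = 1e-7)
  set.seed(603)
  patch <- cbind(runif(20, -0.5, 0.5), runif(20, -0.5, 0.5),
                 runif(20, 2.5, 3.2))
  # zero map: neutral
  mz <- solve_lpb(charge_system(0, 0, 0, 0, 2), p, g)
  cz <- classify_pocket(mz, patch)
  expect_equal(cz$mean_potential, 0)
  expect_equal(cz$label, "neutral")
  # +1 charge about 3 A beneath the patch: positive pocket
  mp <- solve_lpb(charge_system(0, 0, 0, 1, 2), p, g)
  cp <- classify_pocket(mp, patch)
  expect_equal(cp$label, "positive")
  # negation flips the label (linearity corollary)
  mn <- solve_lpb(charge_system(0, 0, 0, -1, 2), p, g)
  cn <- classify_pocket(mn, patch)
  expect_equal(cn$label, "negative")
  expect_equal(cn$mean_potential, -cp$mean_potential, tolerance = 1e-9)
  expect_error(classify_pocket(mp, patch[0, , drop = FALSE]), "empty patch")
})

test_that("fine-stage focusing boundaries interpolate the coarse map", {
  sys <- charge_system(0, 0, 0, 1, 2)
  p <- pb_params(grid_n = 33, tol = 1e-7)
  fine <- focused_solve(sys, p)
  coarse <- attr(fine, "coarse")
  expect_equal(coarse$geom$spacing * 32 * p$coarse_fill, 4, tolerance = 1e-9)
  expect_equal(fine$geom$spacing * 32 * p$fine_fill, 4, tolerance = 1e-9)
  nf <- fine$geom$n
  ax <- lapply(1:3, function(k) fine$geom$origin[k] + fine$geom$spacing * 0:(nf - 1))
  # spot-check face nodes against an independent interpolation of the coarse map
  for (node in list(c(1, 10, 20), c(nf, 5, 17), c(8, 1, 30), c(12, nf, 3),
                    c(21, 7, 1), c(4, 25, nf))) {
    pt <- c(ax[[1]][node[1]], ax[[2]][node[2]], ax[[3]][node[3]])
    expect_equal(fine$phi[node[1], node[2], node[3]],
                 interpolate_potential(coarse, pt), tolerance = 1e-6)
  }
})
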