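# Pairwise forces, Irving-Kirkwood profile, moments, unit conversion, work.

test_that("pair forces follow the analytic LJ and Coulomb gradients", {
  ff <- pair_force_field(lj = data.frame(species_a = "*", species_b = "*",
                                         epsilon = 0.5, sigma = 0.3))
  mk2 <- function(r, charge = 0, coul = FALSE) {
    cfg <- make_config(x = c(1, 1 + r), y = c(1, 1), z = c(1, 1),
                       charge = charge, box = c(4, 4, 4))
    cfg
  }
  # LJ force vanishes at the potential minimum r = 2^(1/6) sigma
  rmin <- 2^(1/6) * 0.3
  pf <- pair_forces(mk2(rmin), ff)
  if (nrow(pf)) expect_lt(abs(pf$fx), 1e-10) else succeed()

  # numeric gradient oracle at several separations
  for (r in c(0.28, 0.32, 0.5, 0.8)) {
    pf <- pair_forces(mk2(r), ff)
    h <- 1e-6
    fnum <- -(pair_energy(r + h, 0.5, 0.3) - pair_energy(r - h, 0.5, 0.3)) / (2 * h)
    # force on i at larger x acts along +x for repulsion
    expect_equal(pf$fx[1] * sign(pf$dx[1]), fnum, tolerance = 1e-5)
  }

  # two +1e charges at 1 nm: Coulomb repulsion = f_coul / r^2 along separation
  ffc <- pair_force_field(coulomb = TRUE, coulomb_cutoff = 1.9)
  pfc <- pair_forces(mk2(1, charge = 1), ffc)
  expect_equal(abs(pfc$fx), 138.935458, tolerance = 1e-9)
  expect_gt(pfc$fx * pfc$dx, 0)  # repulsive

  # beyond cutoff: no record
  pfo <- pair_forces(mk2(1.5), ff)
  expect_equal(nrow(pfo), 0)

  # overlap errors
  expect_error(pair_forces(mk2(1e-8), ff), "overlap")
  # cutoff wider than half the box errors
  expect_error(pair_forces(mk2(0.5), pair_force_field(lj = ff$lj, lj_cutoff = 3)),
               "half the smallest box edge")
})

test_that("ideal gas pressure is kinetic-only and equals rho kBT slice-wise", {
  set.seed(42)
  n <- 400
  box <- c(4, 4, 6)
  cfg <- make_config(x = runif(n, 0, 4), y = runif(n, 0, 4),
                     z = runif(n, -3, 3), box = box)
  pp <- lateral_pressure_profile(cfg, pair_force_field(), T = 310)
  rhoN <- density_profile(cfg, grid = pp$grid, weight = "number")
  occ <- rhoN$value > 0
  expect_lt(max(abs(pp$P_L[occ] - rhoN$value[occ]) / rhoN$value[occ]), 1e-10)
  expect_equal(pp$conf_xx, numeric(pp$grid$n))
  expect_equal(pp$P_L, pp$P_N, tolerance = 1e-12)
})

test_that("the contour distributes a pair virial by exact segment fractions", {
  box <- c(2, 2, 1)
  g <- grid_from_box(box)          # 10 slices of 0.1 nm
  ff <- pair_force_field(lj = data.frame(species_a = "*", species_b = "*",
                                         epsilon = 0.4, sigma = 0.25),
                         lj_cutoff = 0.45)
  cfg <- make_config(x = c(1, 1), y = c(1, 1), z = c(0.25, -0.05), box = box)
  pf <- pair_forces(cfg, ff)
  expect_equal(nrow(pf), 1)
  pp <- lateral_pressure_profile(cfg, ff, grid = g, T = 310)
  RT <- 8.314462618e-3 * 310
  vir_zz <- pf$dz * pf$fz / (box[1] * box[2] * g$thickness) / RT
  conf <- pp$conf_zz
  # segment [-0.05, 0.25]: fractions 1/6, 1/3, 1/3, 1/6 over four slices
  idx <- findInterval(c(-0.05, 0.05, 0.15, 0.25), g$edges, rightmost.closed = TRUE)
  expect_equal(conf[idx], vir_zz * c(1/6, 1/3, 1/3, 1/6), tolerance = 1e-12)
  expect_equal(sum(conf != 0), 4)
  # thin-slice degeneracy guard
  tiny <- structure(list(thickness = 5e-4, n = 2000,
                         edges = seq(-0.5, 0.5, length.out = 2001),
                         centers = seq(-0.5, 0.5, length.out = 2001)[-1] - 2.5e-4),
                    class = "profile_grid")
  expect_error(lateral_pressure_profile(cfg, ff, grid = tiny), "1e-3 nm")
})

test_that("slice-integrated stress equals the double-loop global virial", {
  set.seed(7)
  for (trial in 1:2) {
    n <- if (trial == 1) 120 else 300
    box <- c(3.2, 3.2, 5)
    cfg <- make_config(x = runif(n, 0, box[1]), y = runif(n, 0, box[2]),
                       z = rnorm(n, 0, 1.0), box = box)
    cfg$particles$z <- pmax(pmin(cfg$particles$z, 2.4), -2.4)
    ff <- pair_force_field(lj = data.frame(species_a = "*", species_b = "*",
                                           epsilon = 0.25, sigma = 0.3),
                           lj_cutoff = 1.2)
    pp <- lateral_pressure_profile(cfg, ff, T = 310)
    RT <- 8.314462618e-3 * 310
    glob <- oracle_virial_tensor(cfg, ff) / RT     # kBT/nm^3
    h <- pp$grid$thickness
    vs <- box[1] * box[2] * h
    slice_sum <- c(sum(pp$conf_xx), sum(pp$conf_yy), sum(pp$conf_zz)) * vs / prod(box)
    expect_lt(max(abs(slice_sum - glob) / pmax(abs(glob), 1e-12)), 1e-8)
  }
})

test_that("periodic wrap of contour segments conserves the pair virial", {
  # pair straddling the z boundary: minimum-image segment wraps
  box <- c(2, 2, 2)
  g <- grid_from_box(box)
  ff <- pair_force_field(lj = data.frame(species_a = "*", species_b = "*",
                                         epsilon = 0.4, sigma = 0.25))
  cfg <- make_config(x = c(1, 1), y = c(1, 1), z = c(0.95, -0.9), box = box)
  pp <- lateral_pressure_profile(cfg, ff, grid = g, T = 310)
  pf <- pair_forces(cfg, ff)
  RT <- 8.314462618e-3 * 310
  expect_equal(sum(pp$conf_zz) * box[1] * box[2] * g$thickness,
               pf$dz * pf$fz / RT, tolerance = 1e-10)
  # contributions land near both box edges, not across the middle
  expect_equal(sum(pp$conf_zz[abs(g$centers) < 0.5]), 0)
})

test_that("spline smoothing preserves cubics, constants and the integral", {
  g <- profile_grid(1.5, 0.1)
  z <- g$centers
  cub <- new_profile(g, 2 * z^3 - z + 0.5, "P_L", "kBT nm^-3")
  sm <- smooth_profile(cub, lambda = 1e-12)
  expect_lt(max(abs(sm$value - cub$value)), 1e-8)

  cst <- new_profile(g, rep(3.3, g$n), "P_L", "kBT nm^-3")
  smc <- smooth_profile(cst)
  expect_equal(smc$value, cst$value, tolerance = 1e-8)

  set.seed(21)
  truth <- sin(2 * z)
  noisy <- new_profile(g, truth + rnorm(g$n, 0, 0.25), "P_L", "kBT nm^-3")
  smn <- smooth_profile(noisy)
  expect_lt(sqrt(mean((smn$value - truth)^2)),
            sqrt(mean((noisy$value - truth)^2)))
  # integral preserved within 1% of the |raw| integral
  raw_int <- pracma::trapz(z, noisy$value)
  abs_int <- pracma::trapz(z, abs(noisy$value))
  expect_lt(abs(pracma::trapz(z, smn$value) - raw_int), 0.01 * abs_int)

  few <- new_profile(profile_grid(0.15, 0.1), rep(1, 3), "P_L", "kBT nm^-3")
  expect_error(smooth_profile(few), "too few")
})

test_that("monolayer moments match closed forms and symmetry relations", {
  g <- profile_grid(2.2, 0.1)
  zP <- 1.8
  # P_L = 0 -> both moments vanish
  z0 <- integral_moments(new_profile(g, numeric(g$n), "P_L", "kBT nm^-3"), zP)
  expect_equal(z0$P1, 0); expect_equal(z0$P2, 0)

  # constant c over each monolayer of extent L: P1 = c L^2/2, P2 = c L^3/3
  cval <- -2.5
  cst <- integral_moments(new_profile(g, rep(cval, g$n), "P_L", "kBT nm^-3"), zP)
  up <- cst$monolayer[cst$monolayer$leaflet == "upper", ]
  expect_equal(up$P1, cval * zP^2 / 2, tolerance = 1e-10)
  expect_equal(up$P2, cval * zP^3 / 3, tolerance = 1e-10)

  # z-symmetric triangular profile: opposite-sign P1, equal P2
  tri <- new_profile(g, cval * pmax(0, 1 - abs(g$centers) / zP), "P_L", "kBT nm^-3")
  mt <- integral_moments(tri, zP)
  lo <- mt$monolayer[mt$monolayer$leaflet == "lower", ]
  upt <- mt$monolayer[mt$monolayer$leaflet == "upper", ]
  expect_equal(upt$P1, -lo$P1, tolerance = 1e-10)
  expect_equal(upt$P2, lo$P2, tolerance = 1e-10)
  expect_equal(upt$P1, cval * zP^2 / 6, tolerance = 1e-10)

  # bilayer-level value carries the upper sign and the mean magnitude
  expect_equal(mt$P1, upt$P1, tolerance = 1e-12)

  expect_error(integral_moments(tri, 5), "outside the profile grid")
})

test_that("moment unit conversions reproduce the printed elastic values", {
  # k_c = 0.94e-19 J with c_0 = -0.351 1/nm: k_c c_0 = -7.71 kBT/nm at 310 K
  expect_equal(convert_moment_units(0.94e-19 * (-0.351), "J/nm", "kBT/nm", T = 310),
               -7.71, tolerance = 0.005)
  # the rounded product -0.329e-19 J/nm converts to -7.69 kBT/nm
  expect_equal(convert_moment_units(-0.329e-19, "J/nm", "kBT/nm", T = 310),
               -7.69, tolerance = 0.005)
  # first-moment literature value -16.1e-12 J/m = -3.76 kBT/nm
  expect_equal(convert_moment_units(-16.1e-12, "J/m", "kBT/nm", T = 310),
               -3.76, tolerance = 0.005)
  # zero is zero in any units; conversions invert exactly
  expect_equal(convert_moment_units(0, "J", "kBT"), 0)
  x <- -15.4
  expect_equal(convert_moment_units(convert_moment_units(x, "kBT", "J", 310),
                                    "J", "kBT", 310), x, tolerance = 1e-12)
  expect_error(convert_moment_units(1, "J/nm", "kBT"), "incompatible")
})

test_that("conformational work is linear in the moments and matches the direct integral", {
  g <- profile_grid(2.2, 0.1)
  cval <- -2.5; zP <- 1.8
  pp <- new_profile(g, rep(cval, g$n), "P_L", "kBT nm^-3")
  mom <- integral_moments(pp, zP)
  expect_equal(conformational_work(mom, a1 = 0, a2 = 0)$W, 0)
  expect_equal(conformational_work(mom, a1 = 2, a2 = 0)$W, 2 * mom$P1)
  w3 <- conformational_work(mom, a1 = 2, a2 = -3)$W
  expect_equal(w3, 2 * mom$P1 - 3 * mom$P2, tolerance = 1e-12)

  # exchanging contributions that sum to the same total leaves W unchanged
  m2 <- mom; m2$P1 <- mom$P2; m2$P2 <- mom$P1
  expect_equal(conformational_work(m2, a1 = -3, a2 = 2)$W, w3, tolerance = 1e-12)

  # direct form with constant dA equals A0 * integral of P_L
  A0 <- 1.7
  dA <- new_profile(g, rep(A0, g$n), "delta_area", "nm^2")
  wd <- conformational_work(pressure = pp, delta_area = dA)$W
  expect_equal(wd, A0 * pracma::trapz(g$centers, pp$value), tolerance = 1e-12)
  bad <- new_profile(profile_grid(1, 0.1), rep(A0, 21), "delta_area", "nm^2")
  expect_error(conformational_work(pressure = pp, delta_area = bad), "grid")
})
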