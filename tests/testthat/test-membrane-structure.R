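# Order parameters, Voronoi tessellation, thickness, radial and proximity
# statistics.

test_that("order parameters reach the perpendicular limit for all-trans chains", {
  ch <- make_chain(base = c(1, 1, 2), axis = c(0, 0, -1), perp = c(1, 0, 0))
  cfg <- configuration(ch, box = c(4, 4, 8), validate = FALSE)
  os <- order_parameters(cfg)
  expect_equal(os$neg_scd, 0.5, tolerance = 1e-12)
  expect_true(all(abs(os$per_carbon$SCD + 0.5) < 1e-12))
})

test_that("tilted chains match the brute-force geometric oracle", {
  set.seed(14)
  for (k in 1:5) {
    beta <- runif(1, 0, pi / 2)
    psi <- runif(1, 0, 2 * pi)
    axis <- c(sin(beta), 0, -cos(beta))
    e1 <- c(0, 1, 0)
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    perp <- cos(psi) * e1 + sin(psi) * e2
    ch <- make_chain(base = c(2, 2, 2), axis = axis, perp = perp, mol = k)
    cfg <- configuration(ch, box = c(6, 6, 8), validate = FALSE)
    os <- order_parameters(cfg)
    expect_equal(-os$neg_scd, oracle_scd_chain(ch), tolerance = 1e-10)
  }
  # a chain lying in the plane (90-degree tilt) against the same oracle
  ch90 <- make_chain(base = c(1, 1, 0), axis = c(1, 0, 0), perp = c(0, 0, 1))
  cfg90 <- configuration(ch90, box = c(4, 4, 4), validate = FALSE)
  expect_equal(-order_parameters(cfg90)$neg_scd, oracle_scd_chain(ch90),
               tolerance = 1e-10)
})

test_that("isotropically tumbling chains give S_CD near zero", {
  set.seed(31)
  n <- 1500
  chains <- vector("list", n)
  for (i in seq_len(n)) {
    uz <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
    s <- sqrt(1 - uz^2)
    axis <- c(s * cos(phi), s * sin(phi), uz)
    e1 <- c(-axis[2], axis[1], 0)
    if (sum(e1^2) < 1e-9) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    psi <- runif(1, 0, 2 * pi)
    chains[[i]] <- make_chain(base = c(5, 5, 5), axis = axis,
                              perp = cos(psi) * e1 + sin(psi) * e2,
                              n_carbons = 5, mol = i)
  }
  cfg <- configuration(do.call(rbind, chains), box = c(10, 10, 10),
                       validate = FALSE)
  os <- order_parameters(cfg)
  expect_lt(abs(os$neg_scd), 0.01)
})

test_that("double-bond carbons are excluded from the global average", {
  ch <- make_chain(base = c(1, 1, 2), axis = c(0, 0, -1), perp = c(1, 0, 0))
  ch$bond_class[4] <- "double"
  cfg <- configuration(ch, box = c(4, 4, 8), validate = FALSE)
  os <- order_parameters(cfg)
  expect_true("double" %in% os$per_carbon$bond_class)
  # here all carbons share S_CD = -0.5, so exclusion leaves the mean intact
  expect_equal(os$neg_scd, 0.5, tolerance = 1e-12)
  short <- ch[1:2, ]
  expect_error(order_parameters(configuration(short, box = c(4, 4, 8),
                                              validate = FALSE)),
               "shorter than 3")
})

test_that("periodic Voronoi partitions the box for lattices and random seeds", {
  # 4 seeds on a square lattice: equal areas A/4
  v <- voronoi_periodic(expand.grid(x = c(1, 3), y = c(1, 3)), 4, 4)
  expect_equal(v$areas, rep(4, 4), tolerance = 1e-9)

  # random seeds: partition of unity
  set.seed(6)
  v2 <- voronoi_periodic(cbind(runif(60, 0, 5), runif(60, 0, 5)), 5, 5)
  expect_equal(sum(v2$areas), 25, tolerance = 1e-9)
  expect_true(all(v2$areas > 0))

  # honeycomb (offset rows): all hexagonal cells equal
  a <- 1
  rows <- 4; cols <- 4
  pts <- do.call(rbind, lapply(seq_len(rows) - 1, function(r)
    cbind((seq_len(cols) - 1) * a + (r %% 2) * a / 2, r * a * sqrt(3) / 2)))
  Lx <- cols * a; Ly <- rows * a * sqrt(3) / 2
  v3 <- voronoi_periodic(pts, Lx, Ly)
  expect_lt(diff(range(v3$areas)), 1e-9)
  expect_equal(sum(v3$areas), Lx * Ly, tolerance = 1e-9)

  # duplicate seeds: deterministic jitter with warning, still a partition
  dup <- rbind(c(1, 1), c(1, 1), c(3, 3), c(1, 3), c(3, 1))
  expect_warning(v4 <- voronoi_periodic(dup, 4, 4), "duplicate")
  expect_equal(sum(v4$areas), 16, tolerance = 1e-6)
})

test_that("leaflet tessellation assigns one polygon per molecule", {
  sp <- synthetic_spec(lipids_per_leaflet = c(PC_disordered = 36),
                       water_density = 0, seed = 17)
  cfg <- generate_bilayer(sp)$frames[[1]]
  vl <- voronoi_leaflet(cfg, "upper")
  expect_equal(nrow(vl$molecules), 36)
  expect_equal(anyDuplicated(vl$molecules$mol), 0)
  expect_equal(sum(vl$molecules$area), vl$area_box,
               tolerance = 1e-9)
  # mean area recovers the imposed area per lipid
  expect_equal(mean(vl$molecules$area), 0.701, tolerance = 1e-9)
})

test_that("thickness map pairs transbilayer phosphates laterally", {
  cfg <- make_flat_bilayer(z_P = 1.9)
  th <- per_molecule_thickness(cfg)
  expect_equal(th$thickness, rep(3.8, nrow(th)))

  # laterally displaced lipid: Pythagoras against its registered partner
  cfg2 <- make_flat_bilayer(z_P = 1.9)
  i <- which(cfg2$particles$role == "phosphate" & cfg2$particles$z > 0)[1]
  cfg2$particles$x[i] <- cfg2$particles$x[i] + 0.3
  th2 <- per_molecule_thickness(cfg2)
  moved <- th2$thickness[th2$mol == cfg2$particles$mol[i]]
  expect_equal(moved, sqrt(0.3^2 + 3.8^2), tolerance = 1e-12)

  # generator ground truth: imposed plane separation recovered
  sp <- synthetic_spec(lipids_per_leaflet = c(PC_disordered = 25),
                       water_density = 0, seed = 19)
  gen <- generate_bilayer(sp)
  th3 <- per_molecule_thickness(gen$frames[[1]])
  expect_lt(abs(mean(th3$thickness) - 2 * 1.895), 0.1)

  solo <- make_config(x = 1, y = 1, z = 1.9, mass = 95, species = "PC_disordered",
                      role = "phosphate")
  expect_error(suppressWarnings(per_molecule_thickness(solo)), "opposite leaflet")
})

test_that("radial profiles recover imposed composition and thickness steps", {
  sp <- synthetic_spec(
    lipids_per_leaflet = c(PC_ordered = 72, PC_disordered = 72, Chol = 18),
    domain = c(PC_ordered = 72, Chol = 18),
    water_density = 0, seed = 23)
  gen <- generate_patch_membrane(sp)
  R <- gen$truth$domain_radius
  rp <- radial_profiles(gen$frames, domain_species = c("PC_ordered", "Chol"),
                        properties = c("molar_fraction", "thickness"),
                        bin_width = 0.5)
  mf <- rp$molar_fraction
  ord_frac <- mf$PC_ordered + mf$Chol
  inner <- mf$count > 0 & mf$r < R - 1
  outer <- mf$count > 0 & mf$r > R + 1
  expect_true(all(ord_frac[inner] >= 0.9))
  expect_true(all(ord_frac[outer] <= 0.1))
  # thickness transitions between the two imposed plateaus
  th <- rp$thickness
  expect_lt(abs(mean(th$value[inner & th$count > 3]) - 5.02), 0.15)
  expect_lt(abs(mean(th$value[outer & th$count > 3]) - 3.79), 0.15)

  # homogeneous membrane: molar fraction 1 in every populated bin
  sph <- synthetic_spec(lipids_per_leaflet = c(PC_disordered = 36),
                        water_density = 0, seed = 29)
  genh <- generate_bilayer(sph)
  rph <- radial_profiles(genh$frames, domain_species = "PC_disordered",
                         properties = "molar_fraction")
  mfh <- rph$molar_fraction
  expect_true(all(mfh$PC_disordered[mfh$count > 0] == 1))

  expect_error(radial_profiles(genh$frames, domain_species = "Chol"),
               "no domain species")
})

test_that("proximity distributions are normalized and match the binomial baseline", {
  # zero solutes: P(0) = 1 exactly, with a warning
  cfg <- make_flat_bilayer()
  expect_warning(px0 <- proximity_distribution(cfg), "no solutes")
  expect_true(all(px0$dist$P[px0$dist$k == 0] == 1))

  # uniform random placement vs binomial baseline (multinomial GoF)
  sp <- synthetic_spec(lipids_per_leaflet = c(PC_disordered = 64),
                       water_density = 0, n_solute = 32,
                       solute_z_law = "uniform", jitter = 0.02, seed = 41)
  gen <- generate_bilayer(sp, n_frames = 30)
  px <- proximity_distribution(gen$frames, solute_species = "solute_dipolar",
                               rule = "nearest")
  d <- px$dist
  expect_equal(sum(d$P), 1, tolerance = 1e-12)
  # baseline is the binomial of the same totals (tail beyond max k excluded)
  expect_equal(px$baseline$P,
               stats::dbinom(px$baseline$k, px$n_solute, 1 / px$n_lipid))
  nobs <- 128 * 30
  expected <- px$baseline$P * nobs
  keep <- expected >= 5
  X2 <- sum((d$P * nobs - expected)[keep]^2 / expected[keep])
  dfree <- sum(keep) - 1
  expect_lt(X2, stats::qchisq(0.9985, dfree))  # within ~3 sigma of the GoF null
})

test_that("solutes confined to the disordered phase skew the proximity statistics", {
  sp <- synthetic_spec(
    lipids_per_leaflet = c(PC_ordered = 72, PC_disordered = 72, Chol = 18),
    domain = c(PC_ordered = 72, Chol = 18),
    water_density = 0, n_solute = 48, solute_lateral = "disordered_only",
    seed = 43)
  gen <- generate_patch_membrane(sp, n_frames = 3)
  px <- proximity_distribution(gen$frames, solute_species = "solute_dipolar")
  P0 <- vapply(split(px$dist, px$dist$species),
               function(g) g$P[g$k == 0], numeric(1))
  expect_gt(P0[["PC_ordered"]], P0[["PC_disordered"]])
  expect_gt(P0[["Chol"]], P0[["PC_disordered"]])
})

test_that("solute:lipid ratios count assignments per species", {
  # all solutes over one species: ratio = N_solute / N_species
  g <- expand.grid(x = (1:8) - 0.5, y = (1:8) - 0.5)
  key_up <- make_particles(g$x, g$y, rep(1.5, 64), mass = 14, mol = 1:64,
                           species = rep(c("PC_ordered", "PC_disordered"), each = 32),
                           role = "key_atom")
  key_dn <- key_up
  key_dn$z <- -1.5
  key_dn$mol <- 65:128
  sol <- make_particles(rep(g$x[1:32], 4), rep(g$y[1:32], 4),
                        rep(1.2, 128), mass = 119, mol = 200 + 1:128,
                        species = "solute_dipolar", role = "dipole_C")
  cfg <- configuration(rbind(key_up, key_dn, sol), box = c(8, 8, 6),
                       validate = FALSE)
  sr <- solute_lipid_ratio(cfg, solute_species = "solute_dipolar",
                           lipid_species = c("PC_ordered", "PC_disordered"),
                           all_lipid_species = c("PC_ordered", "PC_disordered"))
  # solutes sit on the upper-leaflet ordered sites only
  expect_equal(sr$ratio[sr$species == "PC_ordered"], 128 / 64)
  expect_equal(sr$ratio[sr$species == "PC_disordered"], 0)
  expect_equal(unique(sr$random_expected), 128 / 128)

  expect_error(solute_lipid_ratio(cfg, lipid_species = "Chol",
                                  all_lipid_species = c("PC_ordered", "PC_disordered")),
               "no lipids")
})
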