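# Synthetic bilayer emulator.
#
# Generates coarse bead-rod bilayer configurations and stochastic solute
# trajectories carrying, by construction, the statistical structure the
# analyses assume (leaflet labels, chain order, areas, thickness, solute
# placement and dynamics) with every imposed quantity recorded as ground
# truth. This is an explicit emulation of bilayer geometry and statistics,
# not a force-field model.

#' Synthetic system specification
#'
#' Defaults reflect the study conditions of fluid PC bilayers at 310 K:
#' area per molecule 0.701 nm^2 (disordered PC), 0.452 nm^2 (ordered PC) and
#' 0.363 nm^2 (cholesterol); phosphate planes at +/-1.895 nm (disordered,
#' bilayer thickness 3.79 nm) and +/-2.51 nm (ordered, 5.02 nm); target chain
#' order <-S_CD> of 0.108 (disordered) and 0.341 (ordered); a telegraph
#' interleaflet switching rate of 5 /ns and lateral solute diffusion of
#' 1 nm^2/ns for solute dynamics.
#'
#' @param lipids_per_leaflet named counts per species per leaflet, e.g.
#'   `c(PC_disordered = 64)` or `c(PC_ordered = 64, Chol = 16)`.
#' @param apl named area per molecule targets (nm^2) per species.
#' @param z_P named phosphate-plane positions (nm) per species (`Chol` entries
#'   are ignored; cholesterol rides at its host-leaflet plane minus 0.3 nm).
#' @param target_neg_scd named target <-S_CD> per PC species; realized via a
#'   fixed chain tilt with per-molecule jitter.
#' @param n_carbons chain beads per lipid (default 10).
#' @param double_bond_index chain carbon flagged `bond_class = "double"` on
#'   disordered PC (default 5; `NA` for none).
#' @param head_q,head_dq headgroup dipole charge (e) and spacing (nm).
#' @param water_density coarse water number density (molecules/nm^3,
#'   default 8; 0 disables the water slab).
#' @param water_q,water_dq,water_bias water dipole charge, spacing and
#'   orientational bias toward the membrane (0..1).
#' @param n_solute solute molecule count.
#' @param solute_dipolar logical: chloroform-like (dipolar) or carbon
#'   tetrachloride-like (apolar).
#' @param solute_axis give apolar solutes a chargeless C-H-like axis so the
#'   orientation profile is computable (default TRUE).
#' @param solute_z_law `"interfacial"` (two-Gaussian mixture at +/-z_int) or
#'   `"uniform"` within the membrane.
#' @param solute_z_int,solute_z_sd interfacial mixture centres (|z|, nm;
#'   default 0.75 z_P) and width.
#' @param solute_interfacial_weight mixture weight of the interfacial
#'   component of the placement law (remainder uniform in the interior).
#' @param solute_orient_bias strength of the dipole orientation bias toward
#'   the nearest interface (0 = isotropic).
#' @param solute_lateral `"uniform"` or `"disordered_only"` (place solutes
#'   laterally over disordered lipids only; needs a patch or mixed system).
#' @param domain NULL, or named interior counts per leaflet for a circular
#'   patch, e.g. `c(PC_ordered = 128, Chol = 32)`.
#' @param jitter lateral lattice jitter as a fraction of the spacing.
#' @param rate,z_dwell,z_noise_sd,D,dt,t_total solute z-telegraph switching
#'   rate (/ns), dwell |z| (nm), dwell noise (nm), lateral diffusion
#'   (nm^2/ns), time step (ns) and length (ns) for trajectories.
#' @param seed integer RNG seed; identical spec + seed is bit-identical.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(lipids_per_leaflet = c(PC_disordered = 64),
                           apl = c(PC_disordered = 0.701, PC_ordered = 0.452, Chol = 0.363),
                           z_P = c(PC_disordered = 1.895, PC_ordered = 2.51),
                           target_neg_scd = c(PC_disordered = 0.108, PC_ordered = 0.341),
                           n_carbons = 10,
                           double_bond_index = 5,
                           head_q = 0.7, head_dq = 0.25,
                           water_density = 8, water_q = 0.4, water_dq = 0.1,
                           water_bias = 0.3,
                           n_solute = 0, solute_dipolar = TRUE, solute_axis = TRUE,
                           solute_z_law = c("interfacial", "uniform"),
                           solute_z_int = NULL, solute_z_sd = 0.25,
                           solute_interfacial_weight = 0.7,
                           solute_orient_bias = 2,
                           solute_lateral = c("uniform", "disordered_only"),
                           domain = NULL,
                           jitter = 0.08,
                           rate = 5, z_dwell = 1.4, z_noise_sd = 0.15,
                           D = 1, dt = 0.01, t_total = 100,
                           seed = 1L) {
  solute_z_law <- match.arg(solute_z_law)
  solute_lateral <- match.arg(solute_lateral)
  if (any(lipids_per_leaflet < 0) || n_solute < 0) stop("counts must be >= 0")
  if (any(apl <= 0) || head_dq <= 0) stop("areas and spacings must be > 0")
  if (!is.null(domain)) {
    extra <- setdiff(names(domain), names(lipids_per_leaflet))
    if (length(extra)) stop("domain species absent from lipids_per_leaflet: ",
                            paste(extra, collapse = ", "))
    if (any(domain > lipids_per_leaflet[names(domain)]))
      stop("domain population exceeds leaflet capacity")
  }
  structure(list(lipids_per_leaflet = lipids_per_leaflet, apl = apl, z_P = z_P,
                 target_neg_scd = target_neg_scd, n_carbons = n_carbons,
                 double_bond_index = double_bond_index,
                 head_q = head_q, head_dq = head_dq,
                 water_density = water_density, water_q = water_q,
                 water_dq = water_dq, water_bias = water_bias,
                 n_solute = n_solute, solute_dipolar = solute_dipolar,
                 solute_axis = solute_axis,
                 solute_z_law = solute_z_law, solute_z_int = solute_z_int,
                 solute_z_sd = solute_z_sd,
                 solute_interfacial_weight = solute_interfacial_weight,
                 solute_orient_bias = solute_orient_bias,
                 solute_lateral = solute_lateral,
                 domain = domain, jitter = jitter,
                 rate = rate, z_dwell = z_dwell, z_noise_sd = z_noise_sd,
                 D = D, dt = dt, t_total = t_total, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# tilt angle whose azimuth-averaged S_CD equals -target:
# S_CD(beta) = (3 sin^2(beta)/2 - 1)/2  =>  sin^2 beta = (1 - 2 t)/1.5 ... with
# t = target_neg_scd: S_CD = -t => sin^2 beta = 2(0.5 - t)/1.5
.tilt_for_scd <- function(neg_scd) {
  s2 <- (1 - 2 * neg_scd) / 1.5
  s2 <- min(max(s2, 0), 1)
  asin(sqrt(s2))
}

# unit vector at polar angle beta (from +axis_sign z) and azimuth phi
.tilt_vec <- function(beta, phi, axis_sign) {
  c(sin(beta) * cos(phi), sin(beta) * sin(phi), axis_sign * cos(beta))
}

# sample u in [-1, 1] from density proportional to exp(b * u)
.sample_expcos <- function(n, b) {
  u <- stats::runif(n)
  small <- abs(b) < 1e-8
  out <- numeric(n)
  out[small] <- 2 * u[small] - 1
  if (any(!small)) {
    bb <- b[!small]
    out[!small] <- log(exp(-bb) + u[!small] * (exp(bb) - exp(-bb))) / bb
  }
  out
}

# lay out the per-leaflet lattice and species assignment (shared by frames)
.layout_leaflet <- function(spec, leaflet_sign) {
  counts <- spec$lipids_per_leaflet
  n <- sum(counts)
  area <- sum(counts * spec$apl[names(counts)])
  L <- sqrt(area)
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  gx <- ((seq_len(nx) - 0.5) / nx) * L
  gy <- ((seq_len(ny) - 0.5) / ny) * L
  sites <- expand.grid(x = gx, y = gy)[seq_len(n), ]
  species <- rep(names(counts), counts)
  if (!is.null(spec$domain)) {
    ctr <- c(L / 2, L / 2)
    r <- sqrt(.min_image(sites$x - ctr[1], L)^2 + .min_image(sites$y - ctr[2], L)^2)
    ord <- order(r)
    n_int <- sum(spec$domain)
    interior <- ord[seq_len(n_int)]
    exterior <- ord[(n_int + 1):n]
    sp <- character(n)
    sp[interior] <- sample(rep(names(spec$domain), spec$domain))
    ext_counts <- counts
    ext_counts[names(spec$domain)] <- ext_counts[names(spec$domain)] - spec$domain
    sp[exterior] <- sample(rep(names(ext_counts), ext_counts))
    species <- sp
    in_domain <- logical(n); in_domain[interior] <- TRUE
    radius <- max(r[interior])
    if (radius >= L / 2) stop("domain radius exceeds half the box edge")
  } else {
    species <- sample(species)
    in_domain <- rep(NA, n)
    radius <- NA_real_
  }
  list(sites = sites, species = species, L = L, n = n,
       in_domain = in_domain, radius = radius,
       spacing = L / nx, leaflet_sign = leaflet_sign)
}

# particles of one lipid molecule for one frame
.build_lipid <- function(spec, x, y, species, sgn, mol_id, truth_env) {
  zp <- if (species == "Chol") {
    host <- spec$z_P[setdiff(names(spec$z_P), "Chol")]
    max(host) - 0.3
  } else unname(spec$z_P[species])
  jit <- spec$jitter * 0.3
  zph <- sgn * (zp + stats::rnorm(1, 0, 0.03))
  rows <- list()
  if (species %in% .PC_SPECIES) {
    rows$phos <- data.frame(x = x, y = y, z = zph, mass = 95, charge = -spec$head_q,
                            mol = mol_id, species = species, role = "phosphate",
                            chain_index = NA, bond_class = NA,
                            name = "P", resname = "PC")
    rows$chol_n <- data.frame(x = x + stats::rnorm(1, 0, 0.05),
                              y = y + stats::rnorm(1, 0, 0.05),
                              z = zph + sgn * spec$head_dq,
                              mass = 73, charge = spec$head_q,
                              mol = mol_id, species = species, role = "other",
                              chain_index = NA, bond_class = NA,
                              name = "N", resname = "PC")
    rows$key <- data.frame(x = x, y = y, z = zph - sgn * 0.15, mass = 14, charge = 0,
                           mol = mol_id, species = species, role = "key_atom",
                           chain_index = NA, bond_class = NA,
                           name = "C1", resname = "PC")
    # chain: all-trans zigzag rod tilted from the inward normal
    beta0 <- .tilt_for_scd(spec$target_neg_scd[species])
    beta <- abs(beta0 + stats::rnorm(1, 0, 0.05))
    phi <- stats::runif(1, 0, 2 * pi)
    axis <- .tilt_vec(beta, phi, -sgn)   # chains point toward the midplane
    e1 <- c(-axis[2], axis[1], 0)
    if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
    e1 <- .unit3(e1)
    e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
            axis[3] * e1[1] - axis[1] * e1[3],
            axis[1] * e1[2] - axis[2] * e1[1])
    psi <- stats::runif(1, 0, 2 * pi)    # zigzag plane azimuth about the chain axis
    perp1 <- cos(psi) * e1 + sin(psi) * e2
    b <- 0.153; th <- 111 * pi / 180
    a_step <- b * sin(th / 2)
    r_lat <- b * cos(th / 2) / 2
    base <- c(x, y, zph - sgn * 0.25)
    nc <- spec$n_carbons
    cc <- t(vapply(seq_len(nc), function(k)
      base + k * a_step * axis + ((-1)^k) * r_lat * perp1, numeric(3)))
    bond <- rep("single", nc)
    if (species == "PC_disordered" && !is.na(spec$double_bond_index) &&
        spec$double_bond_index <= nc) bond[spec$double_bond_index] <- "double"
    rows$chain <- data.frame(x = cc[, 1], y = cc[, 2], z = cc[, 3],
                             mass = 14, charge = 0, mol = mol_id,
                             species = species, role = "chain_carbon",
                             chain_index = seq_len(nc), bond_class = bond,
                             name = sprintf("C%d", seq_len(nc) + 1), resname = "PC")
    # realized azimuth-averaged S_CD for interior single-bond carbons
    scd <- (3 * sin(beta)^2 / 2 - 1) / 2
    nint <- sum(bond[2:(nc - 1)] == "single")
    assign("scd_sum", get("scd_sum", truth_env) + scd * nint, truth_env)
    assign("scd_n", get("scd_n", truth_env) + nint, truth_env)
  } else {  # Chol: rigid short rod, hydroxyl key atom, no charges
    rows$key <- data.frame(x = x, y = y, z = zph, mass = 17, charge = 0,
                           mol = mol_id, species = species, role = "key_atom",
                           chain_index = NA, bond_class = NA,
                           name = "O3", resname = "CHO")
    zz <- zph - sgn * c(0.4, 0.8, 1.2)
    rows$body <- data.frame(x = rep(x, 3), y = rep(y, 3), z = zz,
                            mass = 120, charge = 0, mol = mol_id,
                            species = species, role = "other",
                            chain_index = NA, bond_class = NA,
                            name = c("R1", "R2", "R3"), resname = "CHO")
  }
  do.call(rbind, rows)
}

.build_frame <- function(spec, layouts, frame_time, truth_env) {
  L <- layouts$upper$L
  z_max <- max(spec$z_P[intersect(names(spec$z_P), names(spec$lipids_per_leaflet))],
               spec$z_P[1])
  Lz <- 2 * (z_max + 0.6 + if (spec$water_density > 0) 1.6 else 0.6)
  parts <- list()
  mol_id <- 0L
  leaflet_truth <- list()
  for (side in c("upper", "lower")) {
    lay <- layouts[[side]]
    sgn <- lay$leaflet_sign
    for (i in seq_len(lay$n)) {
      mol_id <- mol_id + 1L
      jx <- lay$sites$x[i] + stats::rnorm(1, 0, spec$jitter * lay$spacing)
      jy <- lay$sites$y[i] + stats::rnorm(1, 0, spec$jitter * lay$spacing)
      parts[[length(parts) + 1L]] <-
        .build_lipid(spec, jx %% L, jy %% L, lay$species[i], sgn, mol_id, truth_env)
      leaflet_truth[[length(leaflet_truth) + 1L]] <-
        data.frame(mol = mol_id, species = lay$species[i],
                   leaflet = side, in_domain = lay$in_domain[i])
    }
  }
  lipid_parts <- do.call(rbind, parts)
  truth_mol <- do.call(rbind, leaflet_truth)
  # water slab: coarse two-site dipoles, orientation biased toward the membrane
  if (spec$water_density > 0) {
    z_lo <- z_max + 0.5
    z_hi <- Lz / 2 - 0.1
    nw <- round(spec$water_density * L * L * (z_hi - z_lo))
    for (sgn in c(1, -1)) {
      if (nw == 0) next
      wx <- stats::runif(nw, 0, L); wy <- stats::runif(nw, 0, L)
      wz <- sgn * stats::runif(nw, z_lo, z_hi)
      # H-site toward the membrane with probability (1 + bias)/2
      uz <- .sample_expcos(nw, -sgn * spec$water_bias * 2)
      phi <- stats::runif(nw, 0, 2 * pi)
      sth <- sqrt(pmax(0, 1 - uz^2))
      ids <- mol_id + seq_len(nw)
      mol_id <- mol_id + nw
      parts[[length(parts) + 1L]] <- data.frame(
        x = c(wx, wx + spec$water_dq * sth * cos(phi)),
        y = c(wy, wy + spec$water_dq * sth * sin(phi)),
        z = c(wz, wz + spec$water_dq * uz),
        mass = rep(c(16, 2), each = nw), charge = rep(c(-1, 1) * spec$water_q, each = nw),
        mol = rep(ids, 2), species = "water",
        role = "other", chain_index = NA, bond_class = NA,
        name = rep(c("OW", "HW"), each = nw), resname = "SOL")
    }
  }
  # solutes
  if (spec$n_solute > 0) {
    ns <- spec$n_solute
    z_int <- if (is.null(spec$solute_z_int)) 0.75 * z_max else spec$solute_z_int
    if (spec$solute_z_law == "interfacial") {
      # interfacial two-Gaussian preference over a uniform hydrophobic
      # background, so the density (and hence the PMF) stays finite across
      # the whole membrane interior with minima at the interfaces
      at_int <- stats::runif(ns) < spec$solute_interfacial_weight
      side <- sample(c(-1, 1), ns, replace = TRUE)
      sz <- ifelse(at_int,
                   side * z_int + stats::rnorm(ns, 0, spec$solute_z_sd),
                   stats::runif(ns, -z_max, z_max))
      sz <- pmax(pmin(sz, z_max + 0.3), -z_max - 0.3)
    } else {
      sz <- stats::runif(ns, -z_max, z_max)
    }
    if (spec$solute_lateral == "disordered_only") {
      dis <- lipid_parts[lipid_parts$role == "key_atom" &
                         lipid_parts$species == "PC_disordered", ]
      if (!nrow(dis)) stop("disordered_only placement needs PC_disordered lipids")
      pick <- sample(nrow(dis), ns, replace = TRUE)
      sx <- (dis$x[pick] + stats::rnorm(ns, 0, 0.15)) %% L
      sy <- (dis$y[pick] + stats::rnorm(ns, 0, 0.15)) %% L
    } else {
      sx <- stats::runif(ns, 0, L); sy <- stats::runif(ns, 0, L)
    }
    species <- if (spec$solute_dipolar) "solute_dipolar" else "solute_apolar"
    # dipole orientation: H toward the nearest (same-side) interface
    b <- if (spec$solute_dipolar)
      spec$solute_orient_bias * sign(sz) * exp(-(abs(sz) - z_int)^2 / (2 * 0.4^2))
    else rep(0, ns)
    uz <- .sample_expcos(ns, b)
    phi <- stats::runif(ns, 0, 2 * pi)
    sth <- sqrt(pmax(0, 1 - uz^2))
    qsol <- if (spec$solute_dipolar) 0.2 else 0
    ids <- mol_id + seq_len(ns)
    mol_id <- mol_id + ns
    if (spec$solute_dipolar || spec$solute_axis) {
      dd <- 0.11
      parts[[length(parts) + 1L]] <- data.frame(
        x = c(sx, sx + dd * sth * cos(phi)),
        y = c(sy, sy + dd * sth * sin(phi)),
        z = c(sz, sz + dd * uz),
        mass = rep(c(107.4, 12), each = ns),
        charge = rep(c(-1, 1) * qsol, each = ns),
        mol = rep(ids, 2), species = species,
        role = rep(c("dipole_C", "dipole_H"), each = ns),
        chain_index = NA, bond_class = NA,
        name = rep(c("C", "H"), each = ns), resname = "SOL")
    } else {
      parts[[length(parts) + 1L]] <- data.frame(
        x = sx, y = sy, z = sz, mass = 119.4, charge = 0, mol = ids,
        species = species, role = "other", chain_index = NA, bond_class = NA,
        name = "C", resname = "SOL")
    }
  }
  p <- do.call(rbind, parts)
  rownames(p) <- NULL
  cfg <- configuration(p, box = c(L, L, Lz), time = frame_time, validate = FALSE)
  cfg <- center_on_bilayer_com(cfg)
  list(config = cfg, truth_mol = truth_mol)
}

#' Generate synthetic bilayer frames with ground truth
#'
#' Lipids sit on a jittered lattice at the target area per molecule; chains
#' are all-trans bead rods tilted to realize the target order parameter;
#' phosphate markers, headgroup dipoles, a coarse water slab and solutes are
#' placed per the spec. The ground-truth record carries every imposed
#' quantity. Identical spec + seed is bit-identical.
#'
#' @param spec a `synthetic_spec`.
#' @param n_frames number of statistically independent frames sharing the
#'   lattice and species assignment (a mock trajectory).
#' @return list with `frames` (list of `mem_config`) and `truth`.
#' @export
generate_bilayer <- function(spec, n_frames = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    layouts <- list(upper = .layout_leaflet(spec, 1), lower = .layout_leaflet(spec, -1))
    truth_env <- new.env()
    assign("scd_sum", 0, truth_env); assign("scd_n", 0, truth_env)
    frames <- vector("list", n_frames)
    truth_mol <- NULL
    for (f in seq_len(n_frames)) {
      fr <- .build_frame(spec, layouts, frame_time = (f - 1) * 0.1, truth_env)
      frames[[f]] <- fr$config
      if (is.null(truth_mol)) truth_mol <- fr$truth_mol
    }
    scd_n <- get("scd_n", truth_env)
    truth <- list(
      molecules = truth_mol,
      apl = spec$apl, z_P = spec$z_P,
      box = frames[[1]]$box,
      scd_true = if (scd_n > 0) get("scd_sum", truth_env) / scd_n else NA_real_,
      neg_scd_true = if (scd_n > 0) -get("scd_sum", truth_env) / scd_n else NA_real_,
      domain_radius = layouts$upper$radius,
      solute = list(n = spec$n_solute, dipolar = spec$solute_dipolar,
                    z_law = spec$solute_z_law,
                    lateral = spec$solute_lateral),
      seed = spec$seed)
    list(frames = frames, truth = truth)
  })
}

#' Generate a patch (domain) membrane
#'
#' Convenience wrapper: requires `spec$domain` (interior species counts per
#' leaflet); interior species occupy the sites nearest the box centre, the
#' remainder the exterior, evenly split between leaflets.
#'
#' @inheritParams generate_bilayer
#' @return list with `frames` and `truth` (including `domain_radius` and the
#'   per-molecule `in_domain` flags).
#' @export
generate_patch_membrane <- function(spec, n_frames = 1) {
  if (is.null(spec$domain)) stop("spec has no domain definition")
  generate_bilayer(spec, n_frames)
}

#' Generate a stochastic solute z-trajectory with lateral diffusion
#'
#' z(t) alternates between interfacial dwell states near +/-z_dwell with
#' exponential dwell times at the telegraph switching rate; (x, y) is a
#' periodic random walk at the specified diffusivity. All governing
#' parameters are recorded as ground truth.
#'
#' @param spec a `synthetic_spec` (uses `rate`, `z_dwell`, `z_noise_sd`, `D`,
#'   `dt`, `t_total`, `z_P`, `seed`).
#' @return list with `traj` (a `solute_trajectory`) and `truth`.
#' @export
generate_solute_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (spec$dt <= 0) stop("time step must be positive")
  if (spec$rate < 0 || spec$D < 0) stop("rates must be non-negative")
  withr::with_seed(spec$seed + 7L, {
    n <- floor(spec$t_total / spec$dt) + 1L
    tm <- (0:(n - 1)) * spec$dt
    # telegraph side process: switch probability per step
    psw <- 1 - exp(-spec$rate * spec$dt)
    sw <- stats::runif(n - 1) < psw
    side <- cumprod(c(1, ifelse(sw, -1, 1)))
    # instantaneous jumps between dwell states; noise never flips the side,
    # so every telegraph switch is exactly one midplane crossing
    noise <- stats::rnorm(n, 0, spec$z_noise_sd)
    z <- side * spec$z_dwell + noise
    z <- sign(side) * pmax(abs(z), 1e-3)
    L <- 10
    step <- sqrt(2 * spec$D * spec$dt)
    x <- (cumsum(c(L / 2, stats::rnorm(n - 1, 0, step)))) %% L
    y <- (cumsum(c(L / 2, stats::rnorm(n - 1, 0, step)))) %% L
    # phosphate plane of the host (disordered-first) species
    zp <- if ("PC_disordered" %in% names(spec$z_P)) unname(spec$z_P["PC_disordered"])
          else max(spec$z_P)
    traj <- solute_trajectory(tm, x, y, z, z_P = zp, box = c(L, L, 2 * zp + 4))
    list(traj = traj,
         truth = list(rate = spec$rate, D = spec$D, z_dwell = spec$z_dwell,
                      n_switches = sum(sw), dt = spec$dt, t_total = spec$t_total,
                      seed = spec$seed))
  })
}

#' Capacitor-like charge density profile
#'
#' Two opposite uniform charge sheets assigned to grid slices: the oracle
#' input for the electrostatic potential integrator (parallel-plate closed
#' form sigma*d/eps0).
#'
#' @param sigma surface charge density, e/nm^2 (the plate at `plates[1]`
#'   carries +sigma, at `plates[2]` -sigma).
#' @param plates z positions of the two sheets (nm).
#' @param grid a `profile_grid`.
#' @param spread number of adjacent slices over which each sheet is spread
#'   (default 1; total charge per plate is conserved).
#' @return charge-density `mem_profile` (e/nm^3) integrating to zero.
#' @export
generate_capacitor_density <- function(sigma, plates, grid, spread = 1L) {
  stopifnot(length(plates) == 2)
  idx <- findInterval(plates, grid$edges, rightmost.closed = TRUE)
  if (any(idx < 1 | idx > grid$n)) stop("plates outside grid")
  if (idx[1] == idx[2]) stop("coincident plates")
  v <- numeric(grid$n)
  for (k in 1:2) {
    s <- if (k == 1) sigma else -sigma
    sl <- idx[k] + seq_len(spread) - 1L - (spread %/% 2L)
    sl <- sl[sl >= 1 & sl <= grid$n]
    v[sl] <- v[sl] + s / (grid$thickness * length(sl))
  }
  new_profile(grid, v, quantity = "charge_density", units = "e nm^-3")
}
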