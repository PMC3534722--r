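# Shared fixture builders and independent oracles.

# bare particle table with defaults
make_particles <- function(x, y, z, mass = 1, charge = 0, mol = seq_along(x),
                           species = "gas", role = "other") {
  data.frame(x = x, y = y, z = z, mass = mass, charge = charge, mol = mol,
             species = species, role = role, stringsAsFactors = FALSE)
}

make_config <- function(..., box = c(4, 4, 6)) {
  configuration(make_particles(...), box = box, validate = FALSE)
}

# flat two-leaflet phosphate-only bilayer on an nx x ny lattice
make_flat_bilayer <- function(nx = 4, ny = 4, spacing = 1, z_P = 1.9,
                              species = "PC_disordered") {
  g <- expand.grid(x = (seq_len(nx) - 0.5) * spacing,
                   y = (seq_len(ny) - 0.5) * spacing)
  n <- nrow(g)
  p <- rbind(
    make_particles(g$x, g$y, rep(z_P, n), mass = 95, mol = seq_len(n),
                   species = species, role = "phosphate"),
    make_particles(g$x, g$y, rep(-z_P, n), mass = 95, mol = n + seq_len(n),
                   species = species, role = "phosphate"))
  key <- p
  key$role <- "key_atom"
  key$z <- key$z - sign(key$z) * 0.15
  configuration(rbind(p, key), box = c(nx * spacing, ny * spacing, 2 * z_P + 2))
}

# zigzag all-trans chain along a given unit axis with zigzag plane vector perp
make_chain <- function(base, axis, perp, n_carbons = 8, mol = 1,
                       species = "PC_disordered", bond_class = "single") {
  b <- 0.153; th <- 111 * pi / 180
  a_step <- b * sin(th / 2); r_lat <- b * cos(th / 2) / 2
  pos <- t(vapply(seq_len(n_carbons), function(k)
    base + k * a_step * axis + ((-1)^k) * r_lat * perp, numeric(3)))
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3], mass = 14, charge = 0,
             mol = mol, species = species, role = "chain_carbon",
             chain_index = seq_len(n_carbons),
             bond_class = bond_class, stringsAsFactors = FALSE)
}

# independent brute-force S_CD oracle for one chain (explicit geometry,
# no shared code with the implementation)
oracle_scd_chain <- function(chain) {
  chain <- chain[order(chain$chain_index), ]
  pos <- as.matrix(chain[, c("x", "y", "z")])
  n <- nrow(pos)
  vals <- c()
  for (i in 2:(n - 1)) {
    u <- pos[i + 1, ] - pos[i - 1, ]
    u <- u / sqrt(sum(u^2))
    m <- (pos[i - 1, ] + pos[i + 1, ]) / 2
    w <- m - pos[i, ]                       # C -> backbone bisector midpoint
    wp <- w - sum(w * u) * u
    if (sqrt(sum(wp^2)) < 1e-12) next
    ex <- -wp / sqrt(sum(wp^2))             # H side: opposite the bisector
    ey <- c(u[2] * ex[3] - u[3] * ex[2],
            u[3] * ex[1] - u[1] * ex[3],
            u[1] * ex[2] - u[2] * ex[1])
    g <- 54.735 * pi / 180
    for (sgn in c(1, -1)) {
      h <- cos(g) * ex + sgn * sin(g) * ey
      vals <- c(vals, (3 * h[3]^2 - 1) / 2)
    }
  }
  mean(vals)
}

# naive all-pairs MSD (double loop over lags)
oracle_msd_naive <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(m) {
    if (m == 0) return(0)
    mean((x[(1 + m):n] - x[1:(n - m)])^2)
  }, numeric(1))
}

# direct global virial pressure tensor diagonal (kJ/mol/nm^3) by double loop
oracle_virial_tensor <- function(config, ff) {
  p <- config$particles
  box <- config$box
  n <- nrow(p)
  acc <- c(xx = 0, yy = 0, zz = 0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ff$exclude_intramolecular && p$mol[i] == p$mol[j]) next
      d <- c(p$x[i] - p$x[j], p$y[i] - p$y[j], p$z[i] - p$z[j])
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      f <- 0
      lj <- memprofiler:::.lj_lookup(ff, p$species[i], p$species[j])
      if (lj$eps > 0 && r <= ff$lj_cutoff) {
        sr6 <- (lj$sig / r)^6
        f <- f + 24 * lj$eps * (2 * sr6^2 - sr6) / r
      }
      if (ff$coulomb && r <= ff$coulomb_cutoff)
        f <- f + 138.935458 * p$charge[i] * p$charge[j] / r^2
      if (f != 0) acc <- acc + d * (f * d / r)
    }
  }
  acc / prod(box)
}

# LJ + truncated-Coulomb pair energy (for numeric force gradients)
pair_energy <- function(r, eps, sig, qq = 0, coul = FALSE) {
  e <- 0
  if (eps > 0) e <- e + 4 * eps * ((sig / r)^12 - (sig / r)^6)
  if (coul) e <- e + 138.935458 * qq / r
  e
}
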