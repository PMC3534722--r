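# Transversal profiles: mass/charge/number density, electrostatic potential
# by double integration of the Poisson equation, Boltzmann-inversion PMF, and
# solute dipole orientation.

#' Transversal density profile
#'
#' Per-slice sum of particle weights divided by slice volume, averaged over
#' frames. Weights: `"mass"` (amu/nm^3), `"charge"` (e/nm^3) or `"number"`
#' (1/nm^3). Frames must be centered on the bilayer COM beforehand.
#'
#' @param frames `mem_config` or list of them.
#' @param selection particle selection (see [select_particles()]).
#' @param grid a `profile_grid`; default covers the first frame's box with
#'   0.1 nm slices.
#' @param weight one of `"mass"`, `"charge"`, `"number"`.
#' @return `mem_profile`; `counts` holds mean per-slice particle counts.
#' @export
density_profile <- function(frames, selection = NULL, grid = NULL,
                            weight = c("mass", "charge", "number")) {
  weight <- match.arg(weight)
  frames <- .as_frames(frames)
  if (is.null(grid)) grid <- grid_from_box(frames[[1]]$box, exact = FALSE)
  acc <- numeric(grid$n)
  cnt <- numeric(grid$n)
  area_sum <- 0
  n_sel_total <- 0
  for (cfg in frames) {
    keep <- select_particles(cfg, selection)
    p <- cfg$particles[keep, ]
    n_sel_total <- n_sel_total + nrow(p)
    area_sum <- area_sum + cfg$box[1] * cfg$box[2]
    if (!nrow(p)) next
    idx <- findInterval(p$z, grid$edges, rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= grid$n
    w <- switch(weight, mass = p$mass, charge = p$charge, number = rep(1, nrow(p)))
    acc <- acc + as.numeric(tapply(w[ok], factor(idx[ok], levels = seq_len(grid$n)),
                                   sum, default = 0))
    cnt <- cnt + tabulate(idx[ok], nbins = grid$n)
  }
  if (n_sel_total == 0) stop("empty selection in all frames")
  nf <- length(frames)
  vol <- (area_sum / nf) * grid$thickness
  units <- switch(weight, mass = "amu nm^-3", charge = "e nm^-3", number = "nm^-3")
  new_profile(grid, acc / nf / vol,
              quantity = paste0(weight, "_density"), units = units,
              frames = nf, counts = cnt / nf)
}

#' Electrostatic potential profile by Poisson double integration
#'
#' V(z) = -(1/eps0) * double integral of the charge density rho_q(z),
#' integrating the Poisson equation twice. The charge density is treated as
#' constant within each slice, so the field is piecewise linear and the
#' potential piecewise quadratic; the integration is then exact slab by slab
#' (no quadrature error for sheet-like charges).
#'
#' Boundary conventions: `"midplane"` (default, the bilayer convention) sets
#' V(0) = 0 and E(0) = 0 at the bilayer center; `"bulk"` sets V = 0 and
#' E = 0 at the lower grid boundary (bulk solvent), which reproduces the
#' parallel-plate closed form sigma*d/eps0 for an isolated capacitor. The two
#' differ by a linear gauge term whenever the two half-spaces carry opposite
#' net charge.
#'
#' @param charge_density a `mem_profile` with units e/nm^3 on a grid spanning
#'   z = 0.
#' @param boundary `"midplane"` or `"bulk"` (see above).
#' @return object of class `potential_profile` (a `mem_profile` in volts with
#'   fields `field` (V/nm at slice centers) and `boundary`).
#' @export
potential_profile <- function(charge_density, boundary = c("midplane", "bulk")) {
  boundary <- match.arg(boundary)
  if (min(charge_density$z) > 0 || max(charge_density$z) < 0)
    stop("charge-density grid does not span z = 0")
  grid <- charge_density$grid
  rho <- charge_density$value
  rho[!is.finite(rho)] <- 0
  h <- grid$thickness
  e <- grid$edges
  n <- grid$n
  # work in reduced units (charge in e, length in nm); convert to SI at the end
  E_edge <- c(0, cumsum(rho * h))            # field/eps0 at slice edges
  V_edge <- c(0, cumsum(-(utils::head(E_edge, -1) * h + rho * h^2 / 2)))
  at <- function(z) {                        # exact in-slab evaluation
    k <- pmin(pmax(findInterval(z, e, rightmost.closed = TRUE), 1L), n)
    dz <- z - e[k]
    list(V = V_edge[k] - E_edge[k] * dz - rho[k] * dz^2 / 2,
         E = E_edge[k] + rho[k] * dz)
  }
  Vc <- at(grid$centers)
  V <- Vc$V
  E <- Vc$E
  if (boundary == "midplane") {
    g0 <- at(0)
    V <- V - g0$V + g0$E * (grid$centers - 0)
    E <- E - g0$E
  }
  vfac <- .E_CHARGE * 1e9 / .EPS0            # (e/nm^2)/eps0 -> V/nm; (e/nm)/eps0 -> V
  p <- new_profile(grid, V * vfac, quantity = "electrostatic_potential",
                   units = "V", frames = charge_density$frames)
  p$field <- E * vfac                         # E = -dV/dz, V/nm
  p$boundary <- boundary
  class(p) <- c("potential_profile", class(p))
  p
}

#' Potential of mean force by Boltzmann inversion
#'
#' PMF(z) = -k_B T ln(rho(z)/rho_0) with rho_0 the density in the slice whose
#' center is nearest the bilayer midplane (the reference state). Values are in
#' k_B T units; empty slices are flagged `NA`, never stored as infinities.
#'
#' @param density solute density `mem_profile` (non-negative).
#' @param T temperature in K (default 310).
#' @return object of class `pmf_profile` (a `mem_profile` in k_B T with
#'   fields `rho0` and `T`).
#' @export
pmf_profile <- function(density, T = 310) {
  z <- density$z
  v <- density$value
  if (any(v < 0, na.rm = TRUE)) stop("density must be non-negative")
  i0 <- which.min(abs(z))
  rho0 <- v[i0]
  if (!is.finite(rho0) || rho0 <= 0) stop("reference density vanishes")
  pmf <- rep(NA_real_, length(v))
  ok <- is.finite(v) & v > 0
  pmf[ok] <- -log(v[ok] / rho0)
  p <- new_profile(density$grid, pmf, quantity = "pmf", units = "kBT",
                   frames = density$frames, counts = density$counts,
                   z_esc = density$z_esc)
  p$rho0 <- rho0
  p$T <- T
  class(p) <- c("pmf_profile", class(p))
  p
}

#' Solute dipole orientation profile
#'
#' Mean angle alpha(z) between the solute C->H (dipole) vector and the
#' positive z axis, binned by the solute carbon position. Slices never visited
#' by a solute are `NA` (flagged empty).
#'
#' @param frames `mem_config` or list of them (centered).
#' @param grid a `profile_grid` (default: first frame's box, 0.1 nm slices).
#' @param solute_species species tags of the solutes to analyse.
#' @return `mem_profile` of alpha in degrees, `counts` = visits per slice.
#' @export
dipole_orientation_profile <- function(frames, grid = NULL,
                                       solute_species = c("solute_dipolar", "solute_apolar")) {
  frames <- .as_frames(frames)
  if (is.null(grid)) grid <- grid_from_box(frames[[1]]$box, exact = FALSE)
  sum_a <- numeric(grid$n)
  cnt <- numeric(grid$n)
  seen_any <- FALSE
  for (cfg in frames) {
    p <- cfg$particles
    sol <- p[p$species %in% solute_species, ]
    if (!nrow(sol)) next
    cs <- sol[sol$role == "dipole_C", ]
    hs <- sol[sol$role == "dipole_H", ]
    if (!nrow(cs) || !nrow(hs)) stop("no dipole atoms in selected solute species")
    seen_any <- TRUE
    hs <- hs[match(cs$mol, hs$mol), ]
    u <- cbind(hs$x - cs$x, hs$y - cs$y, hs$z - cs$z)
    u <- u / sqrt(rowSums(u^2))
    alpha <- acos(pmin(1, pmax(-1, u[, 3]))) * 180 / pi
    idx <- findInterval(cs$z, grid$edges, rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= grid$n
    sum_a <- sum_a + as.numeric(tapply(alpha[ok], factor(idx[ok], levels = seq_len(grid$n)),
                                       sum, default = 0))
    cnt <- cnt + tabulate(idx[ok], nbins = grid$n)
  }
  if (!seen_any) stop("no dipole atoms in selected solute species")
  val <- ifelse(cnt > 0, sum_a / cnt, NA_real_)
  new_profile(grid, val, quantity = "dipole_orientation", units = "deg",
              frames = length(frames), counts = cnt)
}
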