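# Local stress: pairwise forces, Irving-Kirkwood lateral pressure profile,
# spline smoothing, monolayer integral moments and conformational work.
#
# The kinetic stress contribution is taken as rho_N(z) k_B T at the thermostat
# temperature (isothermal runs; coordinate files carry no velocities). The
# configurational part distributes each pair virial along the straight
# minimum-image segment joining the two particles (Irving-Kirkwood contour),
# each slice receiving the fraction of the segment it contains, with periodic
# wrapping of segments that leave the principal box.

#' Pairwise force field for emulated systems
#'
#' Lennard-Jones parameters per species pair plus optional truncated Coulomb
#' interactions under the minimum-image convention. The entry with species
#' `"*"` applies to every pair without a specific entry.
#'
#' @param lj data.frame with columns `species_a`, `species_b`, `epsilon`
#'   (kJ/mol), `sigma` (nm); NULL for no LJ interactions.
#' @param lj_cutoff LJ cutoff radius (nm, default 1.0).
#' @param coulomb logical; include truncated Coulomb forces.
#' @param coulomb_cutoff Coulomb truncation radius (nm, default 2.0).
#' @param exclude_intramolecular skip pairs within the same molecule
#'   (default TRUE; bonded interactions are not modelled).
#' @return object of class `pair_force_field`.
#' @export
pair_force_field <- function(lj = NULL, lj_cutoff = 1.0,
                             coulomb = FALSE, coulomb_cutoff = 2.0,
                             exclude_intramolecular = TRUE) {
  if (!is.null(lj)) {
    stopifnot(all(c("species_a", "species_b", "epsilon", "sigma") %in% names(lj)))
    if (any(lj$epsilon < 0) || any(lj$sigma < 0)) stop("epsilon and sigma must be >= 0")
  }
  stopifnot(lj_cutoff > 0, coulomb_cutoff > 0)
  structure(list(lj = lj, lj_cutoff = lj_cutoff, coulomb = coulomb,
                 coulomb_cutoff = coulomb_cutoff,
                 exclude_intramolecular = exclude_intramolecular),
            class = "pair_force_field")
}

.lj_lookup <- function(ff, sp_a, sp_b) {
  # returns epsilon/sigma vectors for species-pair vectors
  n <- length(sp_a)
  eps <- numeric(n); sig <- numeric(n)
  if (is.null(ff$lj)) return(list(eps = eps, sig = sig))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  tab_key <- key(ff$lj$species_a, ff$lj$species_b)
  idx <- match(key(sp_a, sp_b), tab_key)
  star <- which(tab_key == key("*", "*"))
  if (length(star)) idx[is.na(idx)] <- star[1]
  hit <- !is.na(idx)
  eps[hit] <- ff$lj$epsilon[idx[hit]]
  sig[hit] <- ff$lj$sigma[idx[hit]]
  list(eps = eps, sig = sig)
}

#' Pairwise forces under minimum image
#'
#' Analytic Lennard-Jones and truncated-Coulomb forces for all interacting
#' pairs within cutoff. Newton's third law holds exactly pair by pair
#' (the record stores the force acting on particle `i`).
#'
#' @param config a `mem_config`.
#' @param ff a `pair_force_field`.
#' @return data.frame with columns `i`, `j`, `dx`, `dy`, `dz` (minimum-image
#'   r_i - r_j, nm), `r`, `fx`, `fy`, `fz` (force on i, kJ/mol/nm).
#' @export
pair_forces <- function(config, ff) {
  p <- config$particles
  box <- config$box
  cutoff <- max(ff$lj_cutoff, if (ff$coulomb) ff$coulomb_cutoff else 0)
  if (cutoff > min(box) / 2)
    stop("cutoff exceeds half the smallest box edge")
  n <- nrow(p)
  if (n < 2) return(data.frame(i = integer(), j = integer(), dx = numeric(),
                               dy = numeric(), dz = numeric(), r = numeric(),
                               fx = numeric(), fy = numeric(), fz = numeric()))
  ii <- rep.int(seq_len(n - 1L), rev(seq_len(n - 1L)))
  jj <- sequence(rev(seq_len(n - 1L))) + ii
  dx <- .min_image(p$x[ii] - p$x[jj], box[1])
  dy <- .min_image(p$y[ii] - p$y[jj], box[2])
  dz <- .min_image(p$z[ii] - p$z[jj], box[3])
  r2 <- dx^2 + dy^2 + dz^2
  keep <- r2 <= cutoff^2
  if (ff$exclude_intramolecular) keep <- keep & (p$mol[ii] != p$mol[jj])
  ii <- ii[keep]; jj <- jj[keep]
  dx <- dx[keep]; dy <- dy[keep]; dz <- dz[keep]; r2 <- r2[keep]
  if (any(r2 < 1e-12)) stop("overlapping particles (r < 1e-6 nm)")
  r <- sqrt(r2)
  lj <- .lj_lookup(ff, p$species[ii], p$species[jj])
  fmag <- numeric(length(r))  # magnitude along r-hat; >0 means repulsion
  has_lj <- lj$eps > 0 & r <= ff$lj_cutoff
  if (any(has_lj)) {
    sr6 <- (lj$sig[has_lj] / r[has_lj])^6
    fmag[has_lj] <- fmag[has_lj] +
      24 * lj$eps[has_lj] * (2 * sr6^2 - sr6) / r[has_lj]
  }
  if (ff$coulomb) {
    qq <- p$charge[ii] * p$charge[jj]
    has_c <- qq != 0 & r <= ff$coulomb_cutoff
    fmag[has_c] <- fmag[has_c] + .F_COUL * qq[has_c] / r2[has_c]
  }
  act <- fmag != 0
  data.frame(i = ii[act], j = jj[act],
             dx = dx[act], dy = dy[act], dz = dz[act], r = r[act],
             fx = fmag[act] * dx[act] / r[act],
             fy = fmag[act] * dy[act] / r[act],
             fz = fmag[act] * dz[act] / r[act])
}

# fractions of each pair segment falling in each slice, with periodic wrap.
# za, zb: segment endpoints (za inside the principal box, |za-zb| <= Lz/2).
.segment_fractions <- function(za, zb, edges, Lz) {
  npair <- length(za)
  ns <- length(edges) - 1L
  lo <- pmin(za, zb); hi <- pmax(za, zb)
  len <- hi - lo
  pt <- len < 1e-12
  M <- matrix(0, npair, ns)
  eL <- edges[-length(edges)]; eH <- edges[-1]
  for (sh in c(-Lz, 0, Lz)) {
    ov <- pmin(outer(hi - sh, eH, pmin) - outer(lo - sh, eL, pmax), Inf)
    ov[ov < 0] <- 0
    M <- M + ov
  }
  if (any(!pt)) M[!pt, ] <- M[!pt, , drop = FALSE] / len[!pt]
  if (any(pt)) {
    zw <- za[pt] - Lz * round(za[pt] / Lz)
    idx <- findInterval(zw, edges, rightmost.closed = TRUE)
    idx <- pmin(pmax(idx, 1L), ns)
    M[pt, ] <- 0
    M[cbind(which(pt), idx)] <- 1
  }
  M
}

#' Irving-Kirkwood lateral pressure profile
#'
#' Kinetic part rho_N(z) k_B T plus the configurational (virial) part from the
#' pairwise forces, assigned along the minimum-image straight contour between
#' each pair and divided by the slice volume. Averaged over frames.
#'
#' @param frames `mem_config` or list of them (centered).
#' @param ff a `pair_force_field`.
#' @param grid `profile_grid` tiling the box exactly (default
#'   `grid_from_box(box)`); slices thinner than 1e-3 nm are rejected.
#' @param T temperature in K.
#' @param units `"kBT"` (k_B T/nm^3, default) or `"bar"`.
#' @return object of class `pressure_profile`: fields `z`, `P_L`, `P_N`,
#'   `kinetic`, `conf_xx`, `conf_yy`, `conf_zz`, `grid`, `units`, `T`.
#' @export
lateral_pressure_profile <- function(frames, ff, grid = NULL, T = 310,
                                     units = c("kBT", "bar")) {
  units <- match.arg(units)
  frames <- .as_frames(frames)
  if (T <= 0) stop("temperature must be positive")
  if (is.null(grid)) grid <- grid_from_box(frames[[1]]$box)
  if (grid$thickness < 1e-3) stop("slice thinner than 1e-3 nm (contour fraction degeneracy)")
  ns <- grid$n
  kin <- numeric(ns)
  cxx <- numeric(ns); cyy <- numeric(ns); czz <- numeric(ns)
  RT <- .R_KJ * T  # kJ/mol
  for (cfg in frames) {
    box <- cfg$box
    vol_slice <- box[1] * box[2] * grid$thickness
    idx <- findInterval(cfg$particles$z, grid$edges, rightmost.closed = TRUE)
    ok <- idx >= 1 & idx <= ns
    kin <- kin + tabulate(idx[ok], nbins = ns) / vol_slice * RT
    pf <- pair_forces(cfg, ff)
    if (nrow(pf)) {
      za <- cfg$particles$z[pf$i]
      zb <- za - pf$dz
      M <- .segment_fractions(za, zb, grid$edges, box[3])
      cxx <- cxx + as.vector(crossprod(M, pf$dx * pf$fx)) / vol_slice
      cyy <- cyy + as.vector(crossprod(M, pf$dy * pf$fy)) / vol_slice
      czz <- czz + as.vector(crossprod(M, pf$dz * pf$fz)) / vol_slice
    }
  }
  nf <- length(frames)
  kin <- kin / nf; cxx <- cxx / nf; cyy <- cyy / nf; czz <- czz / nf
  fac <- if (units == "kBT") 1 / RT else .KJ_MOL_NM3_TO_BAR
  structure(list(grid = grid, z = grid$centers,
                 P_L = (kin + (cxx + cyy) / 2) * fac,
                 P_N = (kin + czz) * fac,
                 kinetic = kin * fac,
                 conf_xx = cxx * fac, conf_yy = cyy * fac, conf_zz = czz * fac,
                 units = if (units == "kBT") "kBT nm^-3" else "bar",
                 T = T, frames = nf),
            class = "pressure_profile")
}

#' @export
print.pressure_profile <- function(x, ...) {
  cat(sprintf("<pressure_profile> %d slices, units %s, T = %g K, %d frame(s)\n",
              x$grid$n, x$units, x$T, x$frames))
  invisible(x)
}

#' Convert a pressure profile to a `mem_profile` of P_L
#' @param pressure a `pressure_profile`.
#' @param component `"P_L"`, `"P_N"`, or `"kinetic"`.
#' @return `mem_profile`.
#' @export
as_profile <- function(pressure, component = "P_L") {
  new_profile(pressure$grid, pressure[[component]], quantity = component,
              units = pressure$units, frames = pressure$frames)
}

#' Smooth a profile with a cubic smoothing spline
#'
#' Fits `stats::smooth.spline` and evaluates at the slice centers. The
#' smoothing strength (`spar`) defaults to generalized cross-validation and is
#' automatically reduced until the integral of the smoothed profile agrees
#' with the raw integral within `integral_tol` of the integral of |raw|.
#'
#' @param profile a `mem_profile` with at least 4 populated slices.
#' @param spar smoothing parameter passed to `smooth.spline`; NULL = GCV.
#' @param lambda explicit penalty passed to `smooth.spline` (overrides
#'   `spar`); a vanishing penalty reproduces the data at the slice centers.
#' @param integral_tol maximum allowed relative change of the integral
#'   (default 0.01).
#' @return smoothed `mem_profile` with attribute fields `spar` and `raw`.
#' @export
smooth_profile <- function(profile, spar = NULL, lambda = NULL,
                           integral_tol = 0.01) {
  ok <- is.finite(profile$value)
  if (sum(ok) < 4) stop("too few populated slices for spline smoothing (need >= 4)")
  z <- profile$z[ok]; y <- profile$value[ok]
  raw_int <- pracma::trapz(z, y)
  abs_int <- pracma::trapz(z, abs(y))
  if (!is.null(lambda)) {
    fit <- stats::smooth.spline(z, y, lambda = lambda, all.knots = TRUE)
    sm <- stats::predict(fit, z)$y
    sp <- fit$spar
  } else {
  fit1 <- if (is.null(spar)) stats::smooth.spline(z, y) else stats::smooth.spline(z, y, spar = spar)
  sp <- fit1$spar
  for (k in 1:25) {
    fit <- stats::smooth.spline(z, y, spar = sp)
    sm <- stats::predict(fit, z)$y
    dint <- abs(pracma::trapz(z, sm) - raw_int)
    if (abs_int == 0 || dint <= integral_tol * abs_int) break
    sp <- sp * 0.8
  }
  }
  out <- profile
  out$value[ok] <- sm
  out$quantity <- paste0(profile$quantity, "_smoothed")
  out$spar <- sp
  out$raw <- profile$value
  out
}

#' Integral moments of the lateral pressure profile
#'
#' Per-monolayer first and second moments of P_L(z), integrated (trapezoid,
#' with interpolated endpoint nodes) from the bilayer midplane out to the
#' phosphate plane scaled position |z_esc| = limit. The first moment uses the
#' signed bilayer-frame z, so a z-symmetric profile yields equal-magnitude,
#' opposite-sign monolayer P1 (both monolayers bear the same spontaneous
#' curvature with opposite sign); the second moment uses z^2. The
#' bilayer-level value is the mean of the two monolayer magnitudes carrying
#' the upper monolayer's sign.
#'
#' First-moment units k_B T/nm map onto the bending term k_c c_0; the second
#' moment (k_B T) maps onto the Gaussian curvature modulus k_g.
#'
#' @param pressure a `pressure_profile` (or `mem_profile` of P_L) in
#'   k_B T/nm^3.
#' @param scaled a `scaled_coordinate` giving phosphate peak positions, or a
#'   single numeric z_P (nm) used symmetrically.
#' @param limit integration limit in z_esc units (default 1).
#' @return object of class `elastic_moments` with per-monolayer and bilayer
#'   `P1` (k_B T/nm) and `P2` (k_B T), plus `kc_c0` and `kg` interpretation
#'   fields.
#' @export
integral_moments <- function(pressure, scaled, limit = 1) {
  if (inherits(pressure, "pressure_profile")) {
    z <- pressure$z; y <- pressure$P_L
  } else { z <- pressure$z; y <- pressure$value }
  if (is.numeric(scaled) && !inherits(scaled, "scaled_coordinate"))
    scaled <- structure(list(z_P_minus = -abs(scaled), z_P_plus = abs(scaled)),
                        class = "scaled_coordinate")
  zl_up <- limit * scaled$z_P_plus
  zl_dn <- limit * scaled$z_P_minus
  if (zl_up > max(z) + 1e-9 || zl_dn < min(z) - 1e-9)
    stop("integration limits outside the profile grid")
  ok <- is.finite(y)
  fy <- stats::approxfun(z[ok], y[ok], rule = 2)
  # the profile is piecewise linear between slice centers, so z^k * P_L is a
  # cubic at most per segment: two-point Gauss-Legendre integrates it exactly
  monolayer <- function(z0, z1) {
    inner <- z[z > min(z0, z1) & z < max(z0, z1)]
    nodes <- sort(unique(c(z0, inner, z1)))
    a <- utils::head(nodes, -1); b <- utils::tail(nodes, -1)
    mid <- (a + b) / 2; half <- (b - a) / 2
    gp <- 1 / sqrt(3)
    quad <- function(f) sum(half * (f(mid - gp * half) + f(mid + gp * half)))
    list(P1 = quad(function(t) t * fy(t)),
         P2 = quad(function(t) t^2 * fy(t)))
  }
  up <- monolayer(0, zl_up)
  dn <- monolayer(zl_dn, 0)
  comb <- function(u, l) sign(u) * mean(c(abs(u), abs(l)))
  P1 <- comb(up$P1, dn$P1)
  P2 <- comb(up$P2, dn$P2)
  structure(list(P1 = P1, P2 = P2,
                 monolayer = data.frame(leaflet = c("upper", "lower"),
                                        P1 = c(up$P1, dn$P1),
                                        P2 = c(up$P2, dn$P2)),
                 limit_zesc = limit,
                 z_P = c(lower = scaled$z_P_minus, upper = scaled$z_P_plus),
                 kc_c0 = P1, kg = P2,
                 units = c(P1 = "kBT/nm", P2 = "kBT")),
            class = "elastic_moments")
}

#' @export
print.elastic_moments <- function(x, ...) {
  cat(sprintf("<elastic_moments> P1 = %.4g kBT/nm, P2 = %.4g kBT (|z_esc| <= %g)\n",
              x$P1, x$P2, x$limit_zesc))
  print(x$monolayer)
  invisible(x)
}

#' Conformational work of a protein cross-section change
#'
#' Mechanical work the lateral pressure field exerts on a change of inserted
#' cross-sectional area: W = a1 P1 + a2 P2 (Taylor-expanded area-difference
#' profile), or the direct form W = int dA(z) P_L(z) dz when `delta_area` is
#' supplied as a profile on the same grid.
#'
#' @param moments an `elastic_moments` (used by the expansion form).
#' @param a1 expansion coefficient, nm^2.
#' @param a2 expansion coefficient, nm^3 ... matching the moment units so W is
#'   in k_B T.
#' @param pressure optional `pressure_profile` for the direct form.
#' @param delta_area optional `mem_profile` of the cross-sectional area
#'   difference (nm^2) on the pressure grid.
#' @return object of class `conformational_work` with field `W` (k_B T).
#' @export
conformational_work <- function(moments = NULL, a1 = 0, a2 = 0,
                                pressure = NULL, delta_area = NULL) {
  if (!is.null(delta_area)) {
    if (is.null(pressure)) stop("direct form needs a pressure profile")
    zp <- if (inherits(pressure, "pressure_profile")) pressure$z else pressure$z
    if (length(delta_area$z) != length(zp) || max(abs(delta_area$z - zp)) > 1e-9)
      stop("delta-area grid does not match the pressure grid")
    y <- if (inherits(pressure, "pressure_profile")) pressure$P_L else pressure$value
    ok <- is.finite(y) & is.finite(delta_area$value)
    W <- pracma::trapz(zp[ok], delta_area$value[ok] * y[ok])
    return(structure(list(W = W, form = "direct"), class = "conformational_work"))
  }
  if (is.null(moments)) stop("either moments or a delta-area profile is required")
  structure(list(W = a1 * moments$P1 + a2 * moments$P2, a1 = a1, a2 = a2,
                 form = "expansion"),
            class = "conformational_work")
}

#' @export
print.conformational_work <- function(x, ...) {
  cat(sprintf("<conformational_work> W = %.4g kBT (%s form)\n", x$W, x$form))
  invisible(x)
}
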