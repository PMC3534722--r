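# Transversal profile grid and the common profile container.

#' Uniform transversal slicing grid
#'
#' Builds a uniform grid of slices along z, symmetric about the bilayer
#' midplane z = 0. With `center_slice = TRUE` (default) the slice count is odd
#' so one slice center sits exactly on the midplane, giving midplane-referenced
#' quantities (PMF, potential) an exact reference node.
#'
#' @param z_max half-extent of the grid in nm (grid spans at least \[-z_max, z_max\]).
#' @param thickness slice thickness in nm (default 0.1).
#' @param center_slice logical; if TRUE, place one slice centered at z = 0.
#' @return an object of class `profile_grid` with fields `thickness`, `n`,
#'   `edges`, `centers`.
#' @export
profile_grid <- function(z_max, thickness = 0.1, center_slice = TRUE) {
  stopifnot(thickness > 0, z_max > 0)
  if (center_slice) {
    m <- ceiling((z_max - thickness / 2) / thickness)
    edges <- seq(-(m + 0.5) * thickness, (m + 0.5) * thickness, by = thickness)
  } else {
    m <- ceiling(z_max / thickness)
    edges <- seq(-m * thickness, m * thickness, by = thickness)
  }
  structure(list(thickness = thickness,
                 n = length(edges) - 1L,
                 edges = edges,
                 centers = (utils::head(edges, -1) + utils::tail(edges, -1)) / 2),
            class = "profile_grid")
}

#' Grid spanning a simulation box exactly
#'
#' For stress profiles the grid must tile the box height exactly (edges at
#' +/- Lz/2) so that periodic Irving-Kirkwood contour fractions sum to one;
#' the slice thickness is adjusted to the nearest exact divisor of Lz.
#'
#' @param box orthorhombic box edge lengths (nm), length 3.
#' @param thickness requested slice thickness (nm, default 0.1).
#' @param exact if TRUE (default) tile \[-Lz/2, Lz/2\] exactly; otherwise
#'   delegate to [profile_grid()] with a midplane-centered slice.
#' @return a `profile_grid`.
#' @export
grid_from_box <- function(box, thickness = 0.1, exact = TRUE) {
  Lz <- box[3]
  stopifnot(Lz > 0, thickness > 0)
  if (!exact) return(profile_grid(Lz / 2, thickness, center_slice = TRUE))
  n <- max(1L, as.integer(round(Lz / thickness)))
  h <- Lz / n
  edges <- seq(-Lz / 2, Lz / 2, length.out = n + 1L)
  structure(list(thickness = h, n = n, edges = edges,
                 centers = (utils::head(edges, -1) + utils::tail(edges, -1)) / 2),
            class = "profile_grid")
}

#' Profile container
#'
#' Common container for transversal per-slice quantities (mass/charge density,
#' V(z), PMF, lateral pressure, dipole angle). Slices never visited are stored
#' as `NA`, not zero.
#'
#' @param grid a `profile_grid`.
#' @param value numeric vector, one value per slice (`NA` = empty slice).
#' @param quantity short tag, e.g. `"mass_density"`.
#' @param units unit string, e.g. `"amu nm^-3"`.
#' @param frames number of frames averaged (>= 1).
#' @param counts optional per-slice sample counts.
#' @param z_esc optional scaled-coordinate axis (see [scale_to_phosphate_coordinates()]).
#' @return object of class `mem_profile`.
#' @export
new_profile <- function(grid, value, quantity = "value", units = "",
                        frames = 1L, counts = NULL, z_esc = NULL) {
  stopifnot(inherits(grid, "profile_grid"), length(value) == grid$n, frames >= 1)
  structure(list(grid = grid, z = grid$centers, value = value,
                 quantity = quantity, units = units, frames = as.integer(frames),
                 counts = counts, z_esc = z_esc),
            class = "mem_profile")
}

#' @export
print.mem_profile <- function(x, ...) {
  cat(sprintf("<mem_profile> %s [%s], %d slices (h = %.4g nm), %d frame(s)%s\n",
              x$quantity, x$units, x$grid$n, x$grid$thickness, x$frames,
              if (!is.null(x$z_esc)) ", scaled axis attached" else ""))
  invisible(x)
}

#' @export
as.data.frame.mem_profile <- function(x, ...) {
  d <- data.frame(z = x$z, value = x$value)
  if (!is.null(x$z_esc)) d$z_esc <- x$z_esc
  if (!is.null(x$counts)) d$count <- x$counts
  d
}

# trapezoidal integral of a profile (NA slices dropped)
.profile_integral <- function(p, absolute = FALSE) {
  ok <- is.finite(p$value)
  y <- p$value[ok]
  if (absolute) y <- abs(y)
  if (sum(ok) < 2) return(0)
  pracma::trapz(p$z[ok], y)
}

# cumulative integral from z = 0 outward, on slice centers; a node at z = 0 is
# inserted (linear interpolation) when no center sits exactly on the midplane.
.cumint_from_zero <- function(z, y) {
  stopifnot(length(z) == length(y), !is.unsorted(z))
  if (min(z) > 0 || max(z) < 0) stop("grid does not span z = 0")
  out <- numeric(length(z))
  has0 <- any(abs(z) < 1e-12)
  if (has0) {
    i0 <- which.min(abs(z))
    up <- i0:length(z)
    out[up] <- as.vector(pracma::cumtrapz(z[up], y[up]))
    dn <- i0:1  # indices walking down from the midplane slice
    out[dn] <- -as.vector(pracma::cumtrapz(-z[dn], y[dn]))
  } else {
    y0 <- stats::approx(z, y, xout = 0)$y
    up <- which(z > 0)
    out[up] <- as.vector(pracma::cumtrapz(c(0, z[up]), c(y0, y[up])))[-1]
    dn <- rev(which(z < 0))
    out[dn] <- -as.vector(pracma::cumtrapz(c(0, -z[dn]), c(y0, y[dn])))[-1]
  }
  out
}
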