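# Periodic 2-D Voronoi tessellation by half-plane clipping.
#
# Each seed's cell is the intersection of the half-planes bounded by the
# perpendicular bisectors against all other seeds, with seeds replicated over
# the 8 periodic images so cells close across the box boundary. Neighbours are
# visited in distance order and clipping stops once the next bisector can no
# longer cut the cell (d/2 beyond the farthest vertex), which makes the
# construction exact, not cutoff-approximate. No installed R package provides
# a periodic planar Voronoi, hence the in-package engine.

# Sutherland-Hodgman clip of polygon (matrix nx2) by half-plane
# {p : (p - m) . d <= 0}
.clip_halfplane <- function(poly, m, d) {
  n <- nrow(poly)
  if (n == 0) return(poly)
  s <- (poly[, 1] - m[1]) * d[1] + (poly[, 2] - m[2]) * d[2]
  inside <- s <= 0
  if (all(inside)) return(poly)
  if (!any(inside)) return(poly[0, , drop = FALSE])
  nxt <- c(2:n, 1L)
  out <- matrix(0, 2L * n, 2)
  k <- 0L
  for (i in seq_len(n)) {
    j <- nxt[i]
    if (inside[i]) {
      k <- k + 1L; out[k, ] <- poly[i, ]
    }
    if (inside[i] != inside[j]) {
      t <- s[i] / (s[i] - s[j])
      k <- k + 1L
      out[k, ] <- poly[i, ] + t * (poly[j, ] - poly[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

.polygon_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  nxt <- c(2:n, 1L)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

#' Periodic planar Voronoi tessellation
#'
#' @param xy seed points, matrix/data.frame with two columns (nm).
#' @param Lx,Ly periodic box edges (nm).
#' @return list with `polygons` (list of nx2 vertex matrices, one per seed)
#'   and `areas` (numeric); areas partition Lx*Ly exactly.
#' @export
voronoi_periodic <- function(xy, Lx, Ly) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 seed points")
  # wrap seeds into the principal box
  xy[, 1] <- xy[, 1] %% Lx
  xy[, 2] <- xy[, 2] %% Ly
  # deterministic jitter for duplicate seeds
  key <- paste(round(xy[, 1] / 1e-9), round(xy[, 2] / 1e-9))
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate seed point(s); applying deterministic 1e-6 nm jitter")
    idx <- which(dup)
    xy[idx, 1] <- (xy[idx, 1] + 1e-6 * seq_along(idx)) %% Lx
    xy[idx, 2] <- (xy[idx, 2] + 1e-6 * seq_along(idx)) %% Ly
  }
  shifts <- as.matrix(expand.grid(sx = c(-Lx, 0, Lx), sy = c(-Ly, 0, Ly)))
  all_pts <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(k)
    cbind(xy[, 1] + shifts[k, 1], xy[, 2] + shifts[k, 2])))
  polygons <- vector("list", n)
  areas <- numeric(n)
  half <- max(Lx, Ly)
  for (i in seq_len(n)) {
    s <- xy[i, ]
    # big starting square around the seed
    poly <- cbind(s[1] + c(-half, half, half, -half),
                  s[2] + c(-half, -half, half, half))
    d2 <- (all_pts[, 1] - s[1])^2 + (all_pts[, 2] - s[2])^2
    ord <- order(d2)
    for (k in ord) {
      if (d2[k] < 1e-18) next  # the seed itself (central image)
      # prune: bisector at distance d/2 cannot cut if all vertices closer
      rmax2 <- max((poly[, 1] - s[1])^2 + (poly[, 2] - s[2])^2)
      if (d2[k] / 4 > rmax2) break
      m <- (s + all_pts[k, ]) / 2
      dvec <- all_pts[k, ] - s
      poly <- .clip_halfplane(poly, m, dvec)
      if (nrow(poly) == 0) break
    }
    polygons[[i]] <- poly
    areas[i] <- .polygon_area(poly)
  }
  list(polygons = polygons, areas = areas, seeds = xy)
}
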