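# Time-resolved solute statistics: interleaflet crossings, interfacial
# confinement episodes and lateral diffusivity from mean-squared displacement.

#' Solute trajectory container
#'
#' @param time strictly increasing times (ns) at a uniform step.
#' @param x,y,z positions (nm); x, y may be box-wrapped, z is in the centered
#'   bilayer frame (midplane at 0).
#' @param z_P phosphate peak position (nm) used by the confinement rule
#'   (symmetric +/- z_P).
#' @param box optional box edges (nm) for lateral unwrapping.
#' @return object of class `solute_trajectory`.
#' @export
solute_trajectory <- function(time, x, y, z, z_P, box = NULL) {
  n <- length(time)
  stopifnot(length(x) == n, length(y) == n, length(z) == n, n >= 2)
  dt <- diff(time)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(abs(dt - dt[1])) > 1e-9 * dt[1]) stop("time step must be uniform")
  structure(list(time = time, x = x, y = y, z = z, z_P = z_P, box = box,
                 dt = dt[1]),
            class = "solute_trajectory")
}

#' Interleaflet crossing and confinement statistics
#'
#' Crossings are sign changes of z(t) across the interleaflet plane z = 0; a
#' sample exactly at z = 0 counts with its previous side (no double counting).
#' Confinement episodes are maximal runs in which the solute is closer to the
#' phosphate peak of its side than to the midplane (|z - sign(z) z_P| < |z|).
#'
#' @param traj a `solute_trajectory`.
#' @return object of class `crossing_stats`: `n_crossings`, `rate_per_ns`,
#'   `episodes` (data.frame start/end/duration/side), `mean_confinement_ns`.
#' @export
crossing_stats <- function(traj) {
  z <- traj$z
  n <- length(z)
  s <- sign(z)
  # zeros inherit the previous side (leading zeros inherit the first side seen)
  if (any(s == 0)) {
    nz <- which(s != 0)
    if (!length(nz)) s[] <- 1 else {
      first <- nz[1]
      if (first > 1) s[1:(first - 1)] <- s[first]
      for (i in which(s == 0)) if (i > 1) s[i] <- s[i - 1]
    }
  }
  n_cross <- sum(diff(s) != 0)
  total_t <- traj$time[n] - traj$time[1]
  conf <- abs(z - s * traj$z_P) < abs(z)
  r <- rle(conf)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ep <- which(r$values)
  episodes <- data.frame(start = traj$time[starts[ep]],
                         end = traj$time[ends[ep]],
                         side = s[starts[ep]])
  episodes$duration <- episodes$end - episodes$start + traj$dt
  structure(list(n_crossings = n_cross,
                 rate_per_ns = n_cross / total_t,
                 episodes = episodes,
                 mean_confinement_ns = if (nrow(episodes)) mean(episodes$duration) else NA_real_,
                 total_time_ns = total_t),
            class = "crossing_stats")
}

#' @export
print.crossing_stats <- function(x, ...) {
  cat(sprintf("<crossing_stats> %d crossings over %.3g ns (%.3g /ns); mean confinement %.3g ns (%d episodes)\n",
              x$n_crossings, x$total_time_ns, x$rate_per_ns,
              x$mean_confinement_ns, nrow(x$episodes)))
  invisible(x)
}

# unwrap a periodic coordinate series (box crossings must not reset MSD)
.unwrap <- function(v, L) {
  if (is.null(L)) return(v)
  d <- diff(v)
  d <- d - L * round(d / L)
  v[1] + c(0, cumsum(d))
}

# all-pairs-lag MSD of one coordinate via the FFT autocorrelation identity
.msd_fft_1d <- function(x) {
  n <- length(x)
  X <- stats::fft(c(x, rep(0, n)))
  S2 <- Re(stats::fft(X * Conj(X), inverse = TRUE))[1:n] / (2 * n)
  sq <- x^2
  Q <- 2 * sum(sq)
  S1 <- numeric(n)
  for (m in 0:(n - 1)) {
    if (m > 0) Q <- Q - sq[m] - sq[n - m + 1]
    S1[m + 1] <- Q / (n - m)
  }
  S1 - 2 * S2 / (n - (0:(n - 1)))
}

#' Lateral diffusion coefficient from the MSD
#'
#' D is slope/4 of a linear fit of the lateral (x, y) mean-squared
#' displacement against lag time, over a window of lags (default 10-50% of
#' the series length), with all-pairs lag averaging and periodic unwrapping.
#' 1 nm^2/ns = 1000 um^2/s exactly. A log-log slope far from 1 over the fit
#' window flags non-diffusive (e.g. ballistic) behaviour.
#'
#' @param trajs a `solute_trajectory` or list of them (equal steps).
#' @param fit_window lag window as fractions of the series length
#'   (default c(0.1, 0.5)).
#' @return object of class `diffusivity_estimate` with `D_nm2_ns`, `D_um2_s`,
#'   `slope`, `msd` (data.frame lag/msd), `diffusive` flag and `exponent`.
#' @export
lateral_diffusivity <- function(trajs, fit_window = c(0.1, 0.5)) {
  if (inherits(trajs, "solute_trajectory")) trajs <- list(trajs)
  n <- length(trajs[[1]]$time)
  if (length(trajs) < 2 && n < 100)
    stop("need >= 2 trajectories or >= 100 samples")
  if (fit_window[2] > 1) stop("fit window longer than the series")
  dt <- trajs[[1]]$dt
  msd <- numeric(n)
  for (tr in trajs) {
    if (length(tr$time) != n || abs(tr$dt - dt) > 1e-12)
      stop("trajectories must share length and time step")
    Lx <- if (!is.null(tr$box)) tr$box[1] else NULL
    Ly <- if (!is.null(tr$box)) tr$box[2] else NULL
    msd <- msd + .msd_fft_1d(.unwrap(tr$x, Lx)) + .msd_fft_1d(.unwrap(tr$y, Ly))
  }
  msd <- msd / length(trajs)
  lag <- (0:(n - 1)) * dt
  i0 <- max(2L, floor(fit_window[1] * n))
  i1 <- max(i0 + 2L, floor(fit_window[2] * n))
  i1 <- min(i1, n)
  w <- i0:i1
  fit <- stats::lm(msd[w] ~ lag[w])
  slope <- unname(stats::coef(fit)[2])
  pos <- w[msd[w] > 0]
  expo <- if (length(pos) >= 3)
    unname(stats::coef(stats::lm(log(msd[pos]) ~ log(lag[pos])))[2]) else NA_real_
  D <- max(slope, 0) / 4
  structure(list(D_nm2_ns = D, D_um2_s = D * 1000, slope = slope,
                 exponent = expo,
                 diffusive = is.na(expo) || abs(expo - 1) < 0.35,
                 msd = data.frame(lag = lag[w], msd = msd[w]),
                 fit_window = fit_window),
            class = "diffusivity_estimate")
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat(sprintf("<diffusivity_estimate> D = %.4g nm^2/ns (%.4g um^2/s)%s\n",
              x$D_nm2_ns, x$D_um2_s,
              if (!x$diffusive) sprintf(" [non-diffusive: MSD exponent %.2f]", x$exponent) else ""))
  invisible(x)
}
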