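# Physical constants (CODATA 2018) and unit conversion helpers.
# Internal energy unit: kJ/mol; length: nm; time: ns; charge: elementary charge.

.kB_J <- 1.380649e-23          # Boltzmann constant, J/K
.AVOGADRO <- 6.02214076e23     # 1/mol
.R_KJ <- 8.314462618e-3        # molar gas constant, kJ/(mol K)
.E_CHARGE <- 1.602176634e-19   # elementary charge, C
.EPS0 <- 8.8541878128e-12      # vacuum permittivity, F/m
.F_COUL <- 138.935458          # Coulomb prefactor 1/(4 pi eps0), kJ mol^-1 nm e^-2
.KJ_MOL_NM3_TO_BAR <- 16.6054  # 1 kJ/mol/nm^3 expressed in bar

#' Thermal energy
#'
#' @param T temperature in kelvin.
#' @param unit `"J"` (per molecule) or `"kJ/mol"`.
#' @return k_B T in the requested unit.
#' @export
kbt <- function(T = 310, unit = c("J", "kJ/mol")) {
  unit <- match.arg(unit)
  if (unit == "J") .kB_J * T else .R_KJ * T
}

.normalize_unit <- function(u) {
  u <- tolower(gsub("[[:space:]_]", "", u))
  u <- gsub("kbt|kt", "kbt", u)
  map <- c("j/nm" = "J/nm", "j/m" = "J/m", "kbt/nm" = "kBT/nm",
           "j" = "J", "kbt" = "kBT")
  if (!u %in% names(map)) stop("unknown unit: ", u)
  unname(map[u])
}

#' Convert pressure-profile moment values between unit systems
#'
#' First moments (`P1`, `k_c c_0`) carry units of energy per length
#' (J/nm, J/m, k_BT/nm); second moments (`P2`, `k_g`) carry units of energy
#' (J, k_BT). Conversion between the molecular (k_BT-based) and SI scales is
#' exact at the stated temperature.
#'
#' @param value numeric value(s) to convert.
#' @param from,to unit strings among `"J/nm"`, `"J/m"`, `"J"`, `"kBT/nm"`, `"kBT"`.
#' @param T temperature (K) defining k_B T; default 310.
#' @return converted numeric value.
#' @examples
#' convert_moment_units(-16.1e-12, "J/m", "kBT/nm", T = 310)  # about -3.76
#' @export
convert_moment_units <- function(value, from, to, T = 310) {
  from <- .normalize_unit(from)
  to <- .normalize_unit(to)
  dim_of <- function(u) if (u %in% c("J/nm", "J/m", "kBT/nm")) "per_length" else "energy"
  if (dim_of(from) != dim_of(to))
    stop("incompatible dimensions: ", from, " vs ", to)
  # factor to base unit (J/nm for per-length, J for energy)
  fac <- function(u) switch(u,
    "J/nm" = 1, "J/m" = 1e-9, "kBT/nm" = .kB_J * T,
    "J" = 1, "kBT" = .kB_J * T)
  value * fac(from) / fac(to)
}
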