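# Annotated particle configuration: the shared snapshot type.
#
# A configuration holds one frame of a bilayer-like system: positions (nm),
# masses (amu), partial charges (e), molecule ids, species tags and per-atom
# role annotations, in an orthorhombic box. All analyses consume this type.

.LIPID_SPECIES <- c("PC_disordered", "PC_ordered", "Chol")
.PC_SPECIES <- c("PC_disordered", "PC_ordered")
.ROLES <- c("phosphate", "key_atom", "dipole_C", "dipole_H", "chain_carbon", "other")

#' Construct a particle configuration
#'
#' @param particles data.frame with columns `x`, `y`, `z` (nm), `mass` (amu),
#'   `charge` (e), `mol` (integer molecule id), `species` (string tag, e.g.
#'   `"PC_disordered"`, `"Chol"`, `"water"`, `"solute_dipolar"`),
#'   `role` (one of `phosphate`, `key_atom`, `dipole_C`, `dipole_H`,
#'   `chain_carbon`, `other`), and optionally
#'   `chain_index` (integer) and `bond_class` (`"single"`/`"double"`) for
#'   chain carbons, plus `name`/`resname` used on file output.
#' @param box orthorhombic box edge lengths in nm, length 3, all > 0.
#' @param time frame time in ns.
#' @param validate run invariant checks (default TRUE).
#' @return object of class `mem_config`.
#' @export
configuration <- function(particles, box, time = 0, validate = TRUE) {
  need <- c("x", "y", "z", "mass", "charge", "mol", "species", "role")
  miss <- setdiff(need, names(particles))
  if (length(miss)) stop("particles missing columns: ", paste(miss, collapse = ", "))
  if (!"chain_index" %in% names(particles)) particles$chain_index <- NA_integer_
  if (!"bond_class" %in% names(particles)) particles$bond_class <- NA_character_
  cfg <- structure(list(particles = particles, box = as.numeric(box), time = time),
                   class = "mem_config")
  if (validate) validate_configuration(cfg)
  cfg
}

#' Validate configuration invariants
#'
#' Checks box positivity, finiteness of positions, and that PC molecules carry
#' at most one phosphate and one key atom.
#' @param config a `mem_config`.
#' @return the configuration, invisibly; errors on violation.
#' @export
validate_configuration <- function(config) {
  p <- config$particles
  if (length(config$box) != 3 || any(!is.finite(config$box)) || any(config$box <= 0))
    stop("box edges must be three positive finite lengths")
  if (any(!is.finite(p$x)) || any(!is.finite(p$y)) || any(!is.finite(p$z)))
    stop("non-finite particle positions")
  pc <- p[p$species %in% .PC_SPECIES, ]
  if (nrow(pc)) {
    for (r in c("phosphate", "key_atom")) {
      cnt <- table(pc$mol[pc$role == r])
      if (length(cnt) && any(cnt > 1))
        stop("a PC molecule carries more than one ", r, " atom")
    }
  }
  invisible(config)
}

#' @export
print.mem_config <- function(x, ...) {
  cat(sprintf("<mem_config> %d particles, %d molecules, box %.3f x %.3f x %.3f nm, t = %g ns\n",
              nrow(x$particles), length(unique(x$particles$mol)),
              x$box[1], x$box[2], x$box[3], x$time))
  invisible(x)
}

# minimum-image displacement along one axis
.min_image <- function(d, L) d - L * round(d / L)

# coerce a single config to a one-element frame list
.as_frames <- function(frames) {
  if (inherits(frames, "mem_config")) list(frames) else frames
}

#' Select particles of a configuration
#'
#' `selection` is either NULL (all particles), a logical/integer index vector,
#' a predicate `function(particles) -> logical`, or a filter list with any of
#' the fields `species`, `role`, `mol` (values to keep).
#'
#' @param config a `mem_config`.
#' @param selection see description.
#' @return logical vector over particles.
#' @export
select_particles <- function(config, selection = NULL) {
  p <- config$particles
  if (is.null(selection)) return(rep(TRUE, nrow(p)))
  if (is.function(selection)) return(as.logical(selection(p)))
  if (is.logical(selection)) return(selection)
  if (is.numeric(selection)) {
    keep <- rep(FALSE, nrow(p)); keep[selection] <- TRUE; return(keep)
  }
  keep <- rep(TRUE, nrow(p))
  if (!is.null(selection$species)) keep <- keep & p$species %in% selection$species
  if (!is.null(selection$role)) keep <- keep & p$role %in% selection$role
  if (!is.null(selection$mol)) keep <- keep & p$mol %in% selection$mol
  keep
}

#' Center a configuration on the bilayer center of mass
#'
#' Shifts all z so the mass-weighted z of the membrane species is zero, then
#' wraps coordinates into the principal box \[-L/2, L/2). The bilayer COM
#' fluctuates along a trajectory, so each frame is centered independently
#' before any profile accumulation. x and y are unchanged.
#'
#' @param config a `mem_config`.
#' @param membrane_species species tags defining the membrane (default the
#'   lipid species).
#' @param wrap wrap z into the principal box after shifting (default TRUE).
#' @return centered `mem_config`.
#' @export
center_on_bilayer_com <- function(config,
                                  membrane_species = .LIPID_SPECIES,
                                  wrap = TRUE) {
  p <- config$particles
  mem <- p$species %in% membrane_species
  if (!any(mem)) stop("no membrane particles")
  zcom <- sum(p$mass[mem] * p$z[mem]) / sum(p$mass[mem])
  p$z <- p$z - zcom
  if (wrap) {
    Lz <- config$box[3]
    p$z <- p$z - Lz * round(p$z / Lz)
  }
  config$particles <- p
  config
}

#' Assign lipid molecules to leaflets
#'
#' Each lipid is labelled `upper`/`lower` by the sign of the z coordinate of
#' its phosphate atom (key atom for molecules without phosphate, e.g.
#' cholesterol). Requires a centered configuration. A reference atom exactly
#' at z = 0 is assigned `upper` with a warning (deterministic tie-break).
#'
#' @param config centered `mem_config`.
#' @param lipid_species species tags treated as lipids.
#' @return data.frame with columns `mol`, `species`, `leaflet`, `z_ref`.
#' @export
assign_leaflets <- function(config, lipid_species = .LIPID_SPECIES) {
  p <- config$particles
  lip <- p[p$species %in% lipid_species, ]
  if (!nrow(lip)) stop("no lipid molecules in configuration")
  ref <- do.call(rbind, lapply(split(lip, lip$mol), function(m) {
    i <- which(m$role == "phosphate")
    if (!length(i)) i <- which(m$role == "key_atom")
    if (!length(i)) i <- seq_len(nrow(m))  # fall back to molecule COM
    data.frame(mol = m$mol[1], species = m$species[1],
               z_ref = sum(m$z[i] * m$mass[i]) / sum(m$mass[i]))
  }))
  if (any(ref$z_ref == 0))
    warning("lipid reference atom exactly at z = 0; assigned to upper leaflet")
  ref$leaflet <- ifelse(ref$z_ref >= 0, "upper", "lower")
  if (length(unique(ref$leaflet)) == 1L)
    warning("all lipids in a single leaflet (degenerate monolayer)")
  rownames(ref) <- NULL
  ref[, c("mol", "species", "leaflet", "z_ref")]
}

#' Locate phosphate density peaks
#'
#' Finds the per-half-space maxima of a (phosphate) density profile with
#' parabolic refinement over the three bins around each maximum, decoupling
#' the peak position from bin placement.
#'
#' @param phosphate_density a `mem_profile` of phosphate density.
#' @return object of class `scaled_coordinate` with fields `z_P_minus`,
#'   `z_P_plus`.
#' @export
locate_phosphate_peaks <- function(phosphate_density) {
  z <- phosphate_density$z
  v <- phosphate_density$value
  v[!is.finite(v)] <- 0
  peak_half <- function(idx) {
    if (!length(idx) || all(v[idx] <= 0)) stop("no phosphate density maximum in a half-space")
    i <- idx[which.max(v[idx])]
    if (i > 1 && i < length(v)) {
      y1 <- v[i - 1]; y2 <- v[i]; y3 <- v[i + 1]
      den <- (y1 - 2 * y2 + y3)
      off <- if (abs(den) > 0) 0.5 * (y1 - y3) / den else 0
      off <- max(min(off, 0.5), -0.5)
      z[i] + off * (z[2] - z[1])
    } else z[i]
  }
  zp <- peak_half(which(z > 0))
  zm <- peak_half(which(z < 0))
  if (!(zm < 0 && zp > 0)) stop("phosphate peaks do not bracket the midplane")
  structure(list(z_P_minus = zm, z_P_plus = zp), class = "scaled_coordinate")
}

#' Map z to the scaled coordinate z_esc
#'
#' Per-half-space linear rescaling placing the phosphate density maxima at
#' z_esc = +/-1: z_esc = z / z_P+ for z >= 0, z / |z_P-| for z < 0.
#'
#' @param scaled a `scaled_coordinate`.
#' @param z positions (nm).
#' @return z_esc values.
#' @export
z_to_zesc <- function(scaled, z) {
  ifelse(z >= 0, z / scaled$z_P_plus, z / abs(scaled$z_P_minus))
}

#' Attach a scaled (z_esc) axis to a profile
#'
#' @param profile a `mem_profile`.
#' @param phosphate_density phosphate mass-density `mem_profile` (one maximum
#'   per half-space), or a precomputed `scaled_coordinate`.
#' @return the profile with a `z_esc` axis.
#' @export
scale_to_phosphate_coordinates <- function(profile, phosphate_density) {
  sc <- if (inherits(phosphate_density, "scaled_coordinate")) phosphate_density
        else locate_phosphate_peaks(phosphate_density)
  profile$z_esc <- z_to_zesc(sc, profile$z)
  profile$scaled <- sc
  profile
}
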