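# End-to-end orchestration: a single YAML/list run-config drives
# synth/read -> analyses -> written profiles, tables and a structural summary.

.KNOWN_ANALYSES <- c("density", "charge_density", "potential", "pmf", "dipole",
                     "pressure", "order", "voronoi", "thickness", "radial",
                     "proximity", "crossings", "diffusivity", "summary")

#' Run an analysis pipeline from a run configuration
#'
#' The run config (YAML file path or list) has fields:
#' \describe{
#'   \item{synthetic}{arguments for [synthetic_spec()] (mutually exclusive
#'     with `input`), plus optional `n_frames`.}
#'   \item{input}{list with `coordinates` and `topology` paths.}
#'   \item{analyses}{list of analysis entries; each a string name or a list
#'     with `name` plus parameters. Names: density, charge_density,
#'     potential, pmf, dipole, pressure, order, voronoi, thickness, radial,
#'     proximity, crossings, diffusivity, summary.}
#'   \item{outdir}{output directory (created if missing).}
#'   \item{seed}{integer; overrides the synthetic spec seed.}
#' }
#' Analysis names are validated before any computation. Profiles are written
#' as XVG-compatible text, tables as TSV; `summary` writes a per-system
#' structural table (area per PC, area per Chol, thickness, <-S_CD>, and P1,
#' P2 when `pressure` ran) plus a run log.
#'
#' @param config YAML path or list.
#' @param outdir optional override of the output directory.
#' @return invisible list of analysis results.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  outdir <- outdir %||% config$outdir %||% "memprofiler_run"
  analyses <- lapply(config$analyses, function(a) if (is.character(a)) list(name = a) else a)
  nm <- vapply(analyses, function(a) a$name %||% "", "")
  bad <- setdiff(nm, .KNOWN_ANALYSES)
  if (length(bad)) stop("unknown analysis name(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outdir, "run_log.txt")
  logline <- function(...) cat(sprintf(...), "\n", file = log, append = TRUE, sep = "")
  cat("", file = log)
  logline("memprofiler %s | R %s | %s", as.character(utils::packageVersion("memprofiler")),
          paste(R.version$major, R.version$minor, sep = "."), format(Sys.time()))
  truth <- NULL
  stage <- "input"
  res <- list()
  out <- try({
    if (!is.null(config$synthetic)) {
      sargs <- config$synthetic
      nfr <- sargs$n_frames %||% 1
      sargs$n_frames <- NULL
      # YAML maps arrive as lists; the spec wants named numeric vectors
      sargs <- lapply(sargs, function(v)
        if (is.list(v) && all(vapply(v, is.numeric, TRUE))) unlist(v) else v)
      if (!is.null(config$seed)) sargs$seed <- config$seed
      spec <- do.call(synthetic_spec, sargs)
      gen <- generate_bilayer(spec, n_frames = nfr)
      frames <- gen$frames
      truth <- gen$truth
      logline("synthetic system: %d frames, seed %d", length(frames), spec$seed)
    } else if (!is.null(config$input)) {
      frames <- read_frames(config$input$coordinates, config$input$topology)
      frames <- lapply(frames, center_on_bilayer_com)
      logline("read %d frame(s) from %s", length(frames), config$input$coordinates)
    } else stop("run config needs either 'synthetic' or 'input'")
    grid <- grid_from_box(frames[[1]]$box, exact = FALSE)
    summary_row <- list()
    for (a in analyses) {
      stage <- a$name
      logline("stage: %s", stage)
      res[[stage]] <- switch(stage,
        density = {
          pr <- density_profile(frames, selection = a$selection, grid = grid, weight = "mass")
          write_profile(pr, file.path(outdir, "density.xvg")); pr
        },
        charge_density = {
          pr <- density_profile(frames, grid = grid, weight = "charge")
          write_profile(pr, file.path(outdir, "charge_density.xvg")); pr
        },
        potential = {
          qd <- density_profile(frames, grid = grid, weight = "charge")
          pr <- potential_profile(qd)
          write_profile(pr, file.path(outdir, "potential.xvg")); pr
        },
        pmf = {
          dens <- density_profile(frames,
            selection = list(species = a$species %||% c("solute_dipolar", "solute_apolar")),
            grid = grid, weight = "mass")
          pr <- pmf_profile(dens, T = a$temperature %||% 310)
          write_profile(pr, file.path(outdir, "pmf.xvg")); pr
        },
        dipole = {
          pr <- dipole_orientation_profile(frames, grid = grid)
          write_profile(pr, file.path(outdir, "dipole_orientation.xvg")); pr
        },
        pressure = {
          ff <- do.call(pair_force_field, a$forcefield %||%
                          list(lj = data.frame(species_a = "*", species_b = "*",
                                               epsilon = 0.5, sigma = 0.35)))
          pp <- lateral_pressure_profile(frames, ff, T = a$temperature %||% 310)
          write_profile(as_profile(pp), file.path(outdir, "lateral_pressure.xvg"))
          phos <- density_profile(frames, selection = list(role = "phosphate"),
                                  grid = grid, weight = "mass")
          mom <- integral_moments(pp, locate_phosphate_peaks(phos),
                                  limit = a$limits_zesc %||% 1)
          utils::write.table(mom$monolayer, file.path(outdir, "moments.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          summary_row$P1 <- mom$P1; summary_row$P2 <- mom$P2
          list(profile = pp, moments = mom)
        },
        order = {
          os <- order_parameters(frames)
          utils::write.table(os$per_carbon, file.path(outdir, "order_parameters.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          summary_row$neg_SCD <- os$neg_scd
          os
        },
        voronoi = {
          vs <- lapply(c("upper", "lower"), function(lf) voronoi_leaflet(frames[[1]], lf))
          mols <- do.call(rbind, lapply(vs, function(v)
            cbind(v$molecules, leaflet = v$leaflet)))
          utils::write.table(mols, file.path(outdir, "voronoi_areas.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          pc <- mols$species %in% .PC_SPECIES
          summary_row$area_per_PC <- if (any(pc)) mean(mols$area[pc]) else NA
          summary_row$area_per_Chol <- if (any(mols$species == "Chol"))
            mean(mols$area[mols$species == "Chol"]) else NA
          vs
        },
        thickness = {
          th <- per_molecule_thickness(frames[[1]])
          utils::write.table(th, file.path(outdir, "thickness.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          summary_row$thickness <- mean(th$thickness)
          th
        },
        radial = {
          rp <- radial_profiles(frames, domain_species = a$domain_species %||%
                                  c("PC_ordered", "Chol"),
                                properties = a$properties %||% c("molar_fraction", "thickness"))
          for (pn in names(rp))
            utils::write.table(rp[[pn]], file.path(outdir, paste0("radial_", pn, ".tsv")),
                               sep = "\t", quote = FALSE, row.names = FALSE)
          rp
        },
        proximity = {
          px <- proximity_distribution(frames, r_prox = a$r_prox %||% 0.7)
          utils::write.table(px$dist, file.path(outdir, "proximity.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          px
        },
        crossings = ,
        diffusivity = {
          sp <- do.call(synthetic_spec, c(config$synthetic[setdiff(names(config$synthetic),
                                                                   "n_frames")] %||% list(),
                                          if (!is.null(config$seed)) list(seed = config$seed)))
          gtr <- generate_solute_trajectory(sp)
          if (stage == "crossings") crossing_stats(gtr$traj) else lateral_diffusivity(gtr$traj)
        },
        summary = NULL)
    }
    stage <- "summary"
    if (length(summary_row)) {
      utils::write.table(as.data.frame(summary_row), file.path(outdir, "summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      logline("summary written (%s)", paste(names(summary_row), collapse = ", "))
    }
    res
  }, silent = TRUE)
  if (inherits(out, "try-error")) {
    logline("ERROR in stage %s: %s", stage, conditionMessage(attr(out, "condition")))
    stop("pipeline failed in stage '", stage, "': ",
         conditionMessage(attr(out, "condition")), call. = FALSE)
  }
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
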