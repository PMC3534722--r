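# Coordinate/topology/profile text I/O.
#
# Coordinates travel as GRO (fixed-column, nm) or PDB (via bio3d, angstrom);
# species/role/charge/mass annotations live in a sidecar delimited topology
# table, never inferred from force-field-specific atom names.

#' Read a sidecar topology table
#'
#' Tab-delimited text, one record per atom, header row, columns `mol`,
#' `species`, `role`, `mass`, `charge` and optionally `chain_index`,
#' `bond_class`, `name`, `resname`.
#'
#' @param path file path.
#' @return data.frame of per-atom annotations.
#' @export
read_topology <- function(path) {
  top <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  need <- c("mol", "species", "role", "mass", "charge")
  miss <- setdiff(need, names(top))
  if (length(miss)) stop("topology missing columns: ", paste(miss, collapse = ", "))
  qtot <- sum(top$charge)
  if (abs(qtot) > 1e-6)
    warning(sprintf("topology charges sum to %.4g e (expected ~0 for a complete system)", qtot))
  top
}

#' Write a sidecar topology table
#' @param config a `mem_config` (or a bare particle data.frame).
#' @param path file path.
#' @export
write_topology <- function(config, path) {
  p <- if (inherits(config, "mem_config")) config$particles else config
  cols <- intersect(c("mol", "species", "role", "mass", "charge",
                      "chain_index", "bond_class", "name", "resname"), names(p))
  utils::write.table(p[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GRO ------------------------------------------------------------------
# Fixed-column GROMACS coordinate format (nm); velocity columns tolerated and
# ignored. No R package in scope reads GRO, hence the in-package parser.

.read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) stop("truncated GRO file: missing atom count")
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("truncated or malformed GRO file: bad atom count line")
    if (i + 1L + nat + 1L > length(lines)) stop("truncated GRO file: incomplete frame")
    at <- lines[(i + 2L):(i + 1L + nat)]
    x <- as.numeric(substr(at, 21, 28))
    y <- as.numeric(substr(at, 29, 36))
    z <- as.numeric(substr(at, 37, 44))
    if (any(is.na(x)) || any(is.na(y)) || any(is.na(z)))
      stop("malformed GRO coordinate record")
    boxline <- strsplit(trimws(lines[i + 2L + nat]), "[[:space:]]+")[[1]]
    box <- as.numeric(boxline[1:3])
    if (length(box) < 3 || any(is.na(box))) stop("missing or malformed GRO box line")
    tm <- 0
    mt <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
    if (length(mt) == 2) tm <- as.numeric(mt[2])
    frames[[length(frames) + 1L]] <- list(
      x = x, y = y, z = z, box = box, time = tm,
      resname = trimws(substr(at, 6, 10)),
      name = trimws(substr(at, 11, 15)))
    i <- i + 3L + nat
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (!length(frames)) stop("no frames in GRO file")
  frames
}

#' Write configuration frames as a GRO file
#'
#' @param frames a `mem_config` or list of them.
#' @param path output path.
#' @export
write_gro <- function(frames, path) {
  frames <- .as_frames(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (cfg in frames) {
    p <- cfg$particles
    resname <- if ("resname" %in% names(p)) p$resname else substr(p$species, 1, 5)
    name <- if ("name" %in% names(p)) p$name else substr(p$role, 1, 5)
    writeLines(sprintf("membrane emulation t= %g", cfg$time), con)
    writeLines(sprintf("%5d", nrow(p)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       p$mol %% 100000L, substr(resname, 1, 5), substr(name, 1, 5),
                       seq_len(nrow(p)) %% 100000L, p$x, p$y, p$z), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", cfg$box[1], cfg$box[2], cfg$box[3]), con)
  }
  invisible(path)
}

# ---- PDB (via bio3d) ------------------------------------------------------

.read_pdb_frames <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  # bio3d does not surface CRYST1; parse the record directly
  cl <- grep("^CRYST1", readLines(path), value = TRUE)
  abc <- if (length(cl)) suppressWarnings(as.numeric(c(
    substr(cl[1], 7, 15), substr(cl[1], 16, 24), substr(cl[1], 25, 33)))) else NA
  if (any(!is.finite(abc)) || any(abc <= 0))
    stop("missing box: PDB file has no usable CRYST1 record")
  box <- abc / 10  # angstrom -> nm
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(k) {
    m <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10
    list(x = m[, 1], y = m[, 2], z = m[, 3], box = box, time = 0,
         resname = pdb$atom$resid, name = pdb$atom$elety)
  })
}

#' Write configuration frames as a PDB file (coordinates only, angstrom)
#' @param frames a `mem_config` or list of them.
#' @param path output path.
#' @export
write_pdb <- function(frames, path) {
  frames <- .as_frames(frames)
  con <- file(path, "w")
  on.exit(close(con))
  b <- frames[[1]]$box * 10
  writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     b[1], b[2], b[3], 90, 90, 90), con)
  multi <- length(frames) > 1
  for (k in seq_along(frames)) {
    cfg <- frames[[k]]
    p <- cfg$particles
    resname <- if ("resname" %in% names(p)) p$resname else substr(p$species, 1, 3)
    name <- if ("name" %in% names(p)) p$name else substr(p$role, 1, 4)
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
                       seq_len(nrow(p)) %% 100000L, substr(name, 1, 4),
                       substr(resname, 1, 4), p$mol %% 10000L,
                       p$x * 10, p$y * 10, p$z * 10), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read coordinate frames with a sidecar topology
#'
#' Dispatches on file extension (`.gro` or `.pdb`); positions are returned in
#' nm (PDB angstrom converted), box parsed, and the topology annotations
#' (species, roles, masses, charges) attached to every frame.
#'
#' @param path coordinate file (GRO or PDB dialect).
#' @param topology_path sidecar topology table (see [read_topology()]).
#' @return list of `mem_config` frames in file order.
#' @export
read_frames <- function(path, topology_path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                gro = .read_gro_frames(path),
                pdb = .read_pdb_frames(path),
                stop("unsupported coordinate format: .", ext))
  top <- read_topology(topology_path)
  lapply(raw, function(fr) {
    n <- length(fr$x)
    if (n != nrow(top))
      stop(sprintf("atom count mismatch: coordinates have %d atoms, topology has %d rows",
                   n, nrow(top)))
    p <- data.frame(x = fr$x, y = fr$y, z = fr$z,
                    mass = top$mass, charge = top$charge, mol = top$mol,
                    species = top$species, role = top$role,
                    stringsAsFactors = FALSE)
    p$chain_index <- if ("chain_index" %in% names(top)) top$chain_index else NA_integer_
    p$bond_class <- if ("bond_class" %in% names(top)) top$bond_class else NA_character_
    p$name <- if ("name" %in% names(top)) top$name else fr$name
    p$resname <- if ("resname" %in% names(top)) top$resname else fr$resname
    configuration(p, fr$box, time = fr$time)
  })
}

# ---- profile text ---------------------------------------------------------

#' Write a profile as XVG-compatible plain text
#'
#' Two/three columns (z, value\[, z_esc\]) at full decimal precision with `#`
#' unit header lines and `@` axis labels; [read_profile()] reproduces the
#' values exactly.
#'
#' @param profile a `mem_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# quantity: %s", profile$quantity),
               sprintf("# units: %s", profile$units),
               sprintf("# frames: %d", profile$frames),
               sprintf("# slice_thickness_nm: %.17g", profile$grid$thickness),
               "@ xaxis label \"z (nm)\"",
               sprintf("@ yaxis label \"%s (%s)\"", profile$quantity, profile$units)),
             con)
  has_esc <- !is.null(profile$z_esc)
  for (i in seq_along(profile$z)) {
    row <- sprintf("%.17g %.17g", profile$z[i], profile$value[i])
    if (has_esc) row <- sprintf("%s %.17g", row, profile$z_esc[i])
    writeLines(row, con)
  }
  invisible(path)
}

#' Read back a profile written by [write_profile()]
#' @param path file path.
#' @return a `mem_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^[#@]", lines)]
  dat <- lines[!grepl("^[#@]", lines) & nzchar(trimws(lines))]
  grab <- function(key, default = "") {
    m <- hdr[grepl(paste0("^# ", key, ":"), hdr)]
    if (!length(m)) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", m[1]))
  }
  vals <- do.call(rbind, lapply(strsplit(trimws(dat), "[[:space:]]+"),
                                function(s) as.numeric(s)))
  z <- vals[, 1]
  h <- as.numeric(grab("slice_thickness_nm", as.character(diff(z[1:2]))))
  edges <- c(z - h / 2, z[length(z)] + h / 2)
  grid <- structure(list(thickness = h, n = length(z), edges = edges, centers = z),
                    class = "profile_grid")
  new_profile(grid, vals[, 2], quantity = grab("quantity"), units = grab("units"),
              frames = max(1L, as.integer(grab("frames", "1"))),
              z_esc = if (ncol(vals) >= 3) vals[, 3] else NULL)
}
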