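# Lateral / structural analysis: deuterium order parameters, per-leaflet
# Voronoi tessellation with per-molecule areas, transbilayer thickness map,
# domain radial profiles and solute proximity statistics.

.unit3 <- function(v) v / sqrt(sum(v^2))

# C-H unit vectors reconstructed at a united-atom chain carbon i from its
# neighbours: both perpendicular to the C_{i-1} -> C_{i+1} axis, split by the
# tetrahedral H-C-H angle about the backbone-bisector plane.
.ch_vectors <- function(p_prev, p_i, p_next) {
  u <- .unit3(p_next - p_prev)
  w <- p_prev + p_next - 2 * p_i
  wp <- w - sum(w * u) * u
  nw <- sqrt(sum(wp^2))
  if (nw < 1e-12) {
    # collinear backbone: any perpendicular (degenerate but defined)
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    wp <- a - sum(a * u) * u
    nw <- sqrt(sum(wp^2))
  }
  ex <- -wp / nw                 # H atoms point away from the backbone bisector
  ey <- c(u[2] * ex[3] - u[3] * ex[2],
          u[3] * ex[1] - u[1] * ex[3],
          u[1] * ex[2] - u[2] * ex[1])
  g <- 54.735 * pi / 180         # half the tetrahedral H-C-H angle
  list(h1 = cos(g) * ex + sin(g) * ey,
       h2 = cos(g) * ex - sin(g) * ey)
}

#' Deuterium order parameters of united-atom chains
#'
#' S_CD = <(3 cos^2 theta - 1)/2> with theta the angle between a reconstructed
#' C-H vector and the bilayer normal (+z), averaged over the two H positions,
#' frames and molecules. The global `neg_scd` is the negated mean over carbons
#' flagged `bond_class == "single"`; double-bond carbons are reported
#' individually but excluded from the global average.
#'
#' @param frames `mem_config` or list of them.
#' @param species lipid species to include (default the PC species).
#' @return object of class `order_parameter_set`: `per_carbon` (chain_index,
#'   species, bond_class, SCD, n), `per_molecule` (mol, species, SCD),
#'   `per_species`, and `neg_scd` (the global <-S_CD>).
#' @export
order_parameters <- function(frames, species = .PC_SPECIES) {
  frames <- .as_frames(frames)
  samples <- list()
  for (f in seq_along(frames)) {
    p <- frames[[f]]$particles
    cc <- p[p$role == "chain_carbon" & p$species %in% species, ]
    if (!nrow(cc)) next
    for (m in split(cc, cc$mol)) {
      m <- m[order(m$chain_index), ]
      nc <- nrow(m)
      if (nc < 3) stop("chain shorter than 3 carbons")
      pos <- as.matrix(m[, c("x", "y", "z")])
      for (i in 2:(nc - 1)) {
        hv <- .ch_vectors(pos[i - 1, ], pos[i, ], pos[i + 1, ])
        s <- mean(c((3 * hv$h1[3]^2 - 1) / 2, (3 * hv$h2[3]^2 - 1) / 2))
        samples[[length(samples) + 1L]] <- data.frame(
          mol = m$mol[1], species = m$species[1],
          chain_index = m$chain_index[i],
          bond_class = if (is.na(m$bond_class[i])) "single" else m$bond_class[i],
          SCD = s)
      }
    }
  }
  if (!length(samples)) stop("no chain carbons found for the requested species")
  d <- do.call(rbind, samples)
  agg <- function(by) {
    out <- stats::aggregate(SCD ~ ., data = d[, c(by, "SCD")], FUN = mean)
    n <- stats::aggregate(d$SCD, by = d[by], FUN = length)
    out$n <- n$x
    out
  }
  per_carbon <- agg(c("chain_index", "species", "bond_class"))
  per_molecule <- agg(c("mol", "species"))
  per_species <- agg("species")
  single <- d$bond_class == "single"
  structure(list(per_carbon = per_carbon,
                 per_molecule = per_molecule,
                 per_species = per_species,
                 neg_scd = -mean(d$SCD[single]),
                 n_samples = nrow(d)),
            class = "order_parameter_set")
}

#' @export
print.order_parameter_set <- function(x, ...) {
  cat(sprintf("<order_parameter_set> <-S_CD> = %.4f over %d samples\n",
              x$neg_scd, x$n_samples))
  invisible(x)
}

#' Voronoi tessellation of one leaflet
#'
#' Key atoms (PC: the glycerol-phosphate linking carbon; Chol: the hydroxyl)
#' of the leaflet's lipids are projected on the (x,y) plane and tessellated
#' periodically; each molecule owns exactly one polygon and the areas
#' partition the box cross-section.
#'
#' @param config centered `mem_config`.
#' @param leaflet `"upper"` or `"lower"`.
#' @param leaflets optional precomputed [assign_leaflets()] table.
#' @return object of class `voronoi_leaflet`: `molecules` data.frame (mol,
#'   species, x, y, area), `polygons`, `leaflet`, `area_box`.
#' @export
voronoi_leaflet <- function(config, leaflet = c("upper", "lower"), leaflets = NULL) {
  leaflet <- match.arg(leaflet)
  if (is.null(leaflets)) leaflets <- assign_leaflets(config)
  mols <- leaflets$mol[leaflets$leaflet == leaflet]
  p <- config$particles
  key <- p[p$role == "key_atom" & p$mol %in% mols, ]
  if (nrow(key) < 3) stop("fewer than 3 key atoms in the ", leaflet, " leaflet")
  vor <- voronoi_periodic(key[, c("x", "y")], config$box[1], config$box[2])
  structure(list(leaflet = leaflet,
                 molecules = data.frame(mol = key$mol, species = key$species,
                                        x = vor$seeds[, 1], y = vor$seeds[, 2],
                                        area = vor$areas),
                 polygons = vor$polygons,
                 area_box = config$box[1] * config$box[2]),
            class = "voronoi_leaflet")
}

#' @export
print.voronoi_leaflet <- function(x, ...) {
  cat(sprintf("<voronoi_leaflet> %s leaflet, %d molecules, area sum %.4f / box %.4f nm^2\n",
              x$leaflet, nrow(x$molecules), sum(x$molecules$area), x$area_box))
  invisible(x)
}

#' Per-molecule transbilayer thickness map
#'
#' For each PC molecule, the transbilayer neighbour is the opposite-leaflet PC
#' whose phosphorus is nearest in the lateral minimum-image metric (ties
#' broken by molecule id); the thickness is the 3-D distance between the two
#' phosphorus atoms.
#'
#' @param config centered `mem_config`.
#' @return data.frame `mol`, `species`, `leaflet`, `partner`, `thickness` (nm).
#' @export
per_molecule_thickness <- function(config) {
  p <- config$particles
  ph <- p[p$role == "phosphate" & p$species %in% .PC_SPECIES, ]
  if (!nrow(ph)) stop("no PC phosphate atoms")
  lf <- assign_leaflets(config)
  ph$leaflet <- lf$leaflet[match(ph$mol, lf$mol)]
  up <- ph[ph$leaflet == "upper", ]
  dn <- ph[ph$leaflet == "lower", ]
  if (!nrow(up) || !nrow(dn)) stop("empty opposite leaflet")
  box <- config$box
  pair_up <- function(a, b) {
    # for each row of a, nearest row of b laterally (min image)
    out <- data.frame(mol = a$mol, species = a$species, leaflet = a$leaflet,
                      partner = NA_integer_, thickness = NA_real_)
    b <- b[order(b$mol), ]  # deterministic tie-break by molecule id
    for (i in seq_len(nrow(a))) {
      dx <- .min_image(a$x[i] - b$x, box[1])
      dy <- .min_image(a$y[i] - b$y, box[2])
      d2 <- dx^2 + dy^2
      j <- which.min(d2)
      out$partner[i] <- b$mol[j]
      out$thickness[i] <- sqrt(d2[j] + (a$z[i] - b$z[j])^2)
    }
    out
  }
  res <- rbind(pair_up(up, dn), pair_up(dn, up))
  rownames(res) <- NULL
  res
}

# lateral circular-mean centre of a set of (x, y) points in a periodic box
.circular_com <- function(x, y, Lx, Ly) {
  cm <- function(v, L) {
    th <- v / L * 2 * pi
    (atan2(mean(sin(th)), mean(cos(th))) %% (2 * pi)) * L / (2 * pi)
  }
  c(cm(x, Lx), cm(y, Ly))
}

#' Radial profiles around a lipid domain
#'
#' Bins per-molecule properties by the lateral minimum-image distance r_CM to
#' the domain centre of mass (circular mean of the domain species' key atoms,
#' respecting periodicity), averaged over frames.
#'
#' @param frames `mem_config` or list of them (centered).
#' @param domain_species species forming the domain (e.g. ordered PC + Chol).
#' @param properties subset of `"molar_fraction"`, `"area"`, `"thickness"`,
#'   `"order"`.
#' @param bin_width radial bin width in nm (default 0.5).
#' @param r_max maximum radius (default half the box diagonal extent).
#' @return named list of data.frames, one per property. Molar fractions carry
#'   one column per species; the others carry per-bin means and counts.
#' @export
radial_profiles <- function(frames, domain_species,
                            properties = c("molar_fraction", "area", "thickness"),
                            bin_width = 0.5, r_max = NULL) {
  frames <- .as_frames(frames)
  properties <- match.arg(properties, c("molar_fraction", "area", "thickness", "order"),
                          several.ok = TRUE)
  box <- frames[[1]]$box
  if (is.null(r_max)) r_max <- sqrt((box[1] / 2)^2 + (box[2] / 2)^2)
  edges <- seq(0, r_max + bin_width, by = bin_width)
  nb <- length(edges) - 1L
  mid <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  samp <- list()
  for (cfg in frames) {
    p <- cfg$particles
    key <- p[p$role == "key_atom", ]
    dom <- key[key$species %in% domain_species, ]
    if (!nrow(dom)) stop("no domain species present")
    ctr <- .circular_com(dom$x, dom$y, box[1], box[2])
    lf <- assign_leaflets(cfg)
    per_mol <- data.frame(mol = key$mol, species = key$species,
                          x = key$x, y = key$y)
    per_mol$r <- sqrt(.min_image(per_mol$x - ctr[1], box[1])^2 +
                      .min_image(per_mol$y - ctr[2], box[2])^2)
    if ("area" %in% properties) {
      ar <- rbind(voronoi_leaflet(cfg, "upper", lf)$molecules,
                  voronoi_leaflet(cfg, "lower", lf)$molecules)
      per_mol$area <- ar$area[match(per_mol$mol, ar$mol)]
    }
    if ("thickness" %in% properties) {
      th <- per_molecule_thickness(cfg)
      per_mol$thickness <- th$thickness[match(per_mol$mol, th$mol)]
    }
    if ("order" %in% properties) {
      os <- order_parameters(cfg)
      per_mol$order <- -os$per_molecule$SCD[match(per_mol$mol, os$per_molecule$mol)]
    }
    samp[[length(samp) + 1L]] <- per_mol
  }
  d <- do.call(rbind, samp)
  d$bin <- findInterval(d$r, edges, rightmost.closed = TRUE)
  d <- d[d$bin >= 1 & d$bin <= nb, ]
  out <- list()
  if ("molar_fraction" %in% properties) {
    tab <- table(factor(d$bin, levels = seq_len(nb)), d$species)
    tot <- rowSums(tab)
    mf <- data.frame(r = mid, count = as.numeric(tot))
    for (sp in colnames(tab)) mf[[sp]] <- ifelse(tot > 0, tab[, sp] / tot, NA_real_)
    out$molar_fraction <- mf
  }
  for (prop in setdiff(properties, "molar_fraction")) {
    v <- d[[prop]]
    ok <- is.finite(v)
    mu <- tapply(v[ok], factor(d$bin[ok], levels = seq_len(nb)), mean)
    nn <- tapply(v[ok], factor(d$bin[ok], levels = seq_len(nb)), length)
    out[[prop]] <- data.frame(r = mid, value = as.numeric(mu),
                              count = ifelse(is.na(nn), 0, as.numeric(nn)))
  }
  out
}

# solute reference centres: dipole_C atom when present, else molecule COM
.solute_centers <- function(p, solute_species) {
  sol <- p[p$species %in% solute_species, ]
  if (!nrow(sol)) return(sol[0, c("x", "y", "z", "mol", "species")])
  do.call(rbind, lapply(split(sol, sol$mol), function(m) {
    i <- which(m$role == "dipole_C")
    if (!length(i)) {
      data.frame(x = sum(m$x * m$mass) / sum(m$mass),
                 y = sum(m$y * m$mass) / sum(m$mass),
                 z = sum(m$z * m$mass) / sum(m$mass),
                 mol = m$mol[1], species = m$species[1])
    } else m[i[1], c("x", "y", "z", "mol", "species")]
  }))
}

# per-lipid solute counts for one frame under a proximity rule
.proximal_counts <- function(cfg, solute_species, lipid_species, r_prox, rule) {
  p <- cfg$particles
  key <- p[p$role == "key_atom" & p$species %in% lipid_species, ]
  if (!nrow(key)) stop("no lipid key atoms for the requested species")
  key$side <- ifelse(key$z >= 0, 1, -1)
  sol <- .solute_centers(p, solute_species)
  cnt <- integer(nrow(key))
  if (nrow(sol)) {
    sol$side <- ifelse(sol$z >= 0, 1, -1)
    box <- cfg$box
    for (s in seq_len(nrow(sol))) {
      same <- key$side == sol$side[s]
      if (!any(same)) next
      dx <- .min_image(sol$x[s] - key$x[same], box[1])
      dy <- .min_image(sol$y[s] - key$y[same], box[2])
      d2 <- dx^2 + dy^2
      if (rule == "nearest") {
        j <- which(same)[which.min(d2)]
        cnt[j] <- cnt[j] + 1L
      } else {
        hit <- which(same)[d2 <= r_prox^2]
        cnt[hit] <- cnt[hit] + 1L
      }
    }
  }
  data.frame(mol = key$mol, species = key$species, k = cnt,
             n_solute = nrow(sol))
}

#' Probability distribution of proximal solutes per lipid
#'
#' For each lipid molecule, counts the solutes satisfying the proximity rule
#' (default: solute centre within a lateral cutoff `r_prox` of the lipid key
#' atom on the same leaflet side), accumulating P(k) per species over frames.
#' The random-assignment baseline is the binomial distribution of the same
#' solute total dropped uniformly over all lipids,
#' P(k) = Binom(k; N_solute, 1/N_lipid).
#'
#' @param frames `mem_config` or list of them (centered).
#' @param solute_species solute species tags.
#' @param lipid_species lipid species tags (default all lipid species present).
#' @param r_prox lateral proximity cutoff in nm (default 0.7, about one lipid
#'   diameter).
#' @param rule `"lateral_cutoff"` (default) or `"nearest"` (each solute
#'   assigned to its laterally nearest same-side lipid).
#' @return object of class `proximity_distribution`: `dist` (data.frame
#'   species x k probabilities), `baseline`, `rule`, `r_prox`, `n_solute`,
#'   `n_lipid`.
#' @export
proximity_distribution <- function(frames, solute_species = c("solute_dipolar", "solute_apolar"),
                                   lipid_species = .LIPID_SPECIES,
                                   r_prox = 0.7,
                                   rule = c("lateral_cutoff", "nearest")) {
  rule <- match.arg(rule)
  frames <- .as_frames(frames)
  recs <- lapply(frames, .proximal_counts, solute_species = solute_species,
                 lipid_species = lipid_species, r_prox = r_prox, rule = rule)
  d <- do.call(rbind, recs)
  if (all(d$n_solute == 0)) warning("no solutes present: P(0) = 1 for all species")
  kmax <- max(d$k)
  ks <- 0:max(kmax, 1L)
  dist <- do.call(rbind, lapply(split(d, d$species), function(g) {
    pk <- tabulate(g$k + 1L, nbins = length(ks)) / nrow(g)
    data.frame(species = g$species[1], k = ks, P = pk)
  }))
  rownames(dist) <- NULL
  n_lip_frame <- nrow(recs[[1]])
  n_sol_frame <- recs[[1]]$n_solute[1]
  baseline <- data.frame(k = ks,
                         P = stats::dbinom(ks, size = n_sol_frame, prob = 1 / n_lip_frame))
  structure(list(dist = dist, baseline = baseline, rule = rule, r_prox = r_prox,
                 n_solute = n_sol_frame, n_lipid = n_lip_frame,
                 frames = length(frames)),
            class = "proximity_distribution")
}

#' @export
print.proximity_distribution <- function(x, ...) {
  cat(sprintf("<proximity_distribution> rule %s (r_prox = %g nm), %d solutes over %d lipids\n",
              x$rule, x$r_prox, x$n_solute, x$n_lipid))
  invisible(x)
}

#' Solute-to-lipid ratio per lipid species
#'
#' Each solute is assigned to its laterally nearest same-side lipid key atom
#' (over all lipids); the ratio for a species is the mean assigned solute
#' count divided by the number of lipids of that species. The uniform-random
#' expectation N_solute / N_lipid_total is reported alongside.
#'
#' @param frames `mem_config` or list of them (centered).
#' @param solute_species solute species tags.
#' @param lipid_species species for which ratios are reported.
#' @param all_lipid_species the full lipid set over which solutes are
#'   assigned (default all lipid species).
#' @return data.frame `species`, `ratio`, `random_expected`, `n_lipid`.
#' @export
solute_lipid_ratio <- function(frames, solute_species = c("solute_dipolar", "solute_apolar"),
                               lipid_species = .PC_SPECIES,
                               all_lipid_species = .LIPID_SPECIES) {
  frames <- .as_frames(frames)
  recs <- lapply(frames, .proximal_counts, solute_species = solute_species,
                 lipid_species = all_lipid_species, r_prox = Inf, rule = "nearest")
  d <- do.call(rbind, recs)
  n_lip_total <- nrow(recs[[1]])
  n_sol <- recs[[1]]$n_solute[1]
  lipid_species <- intersect(lipid_species, unique(d$species))
  if (!length(lipid_species)) stop("no lipids of the requested species")
  out <- do.call(rbind, lapply(lipid_species, function(sp) {
    g <- d[d$species == sp, ]
    n_sp <- nrow(recs[[1]][recs[[1]]$species == sp, ])
    if (n_sp == 0) stop("zero lipids of species ", sp)
    data.frame(species = sp,
               ratio = sum(g$k) / length(frames) / n_sp,
               random_expected = n_sol / n_lip_total,
               n_lipid = n_sp)
  }))
  rownames(out) <- NULL
  out
}
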