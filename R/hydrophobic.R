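# The hydrophobic-contact descriptor log P_C: hydrophobicity density
# integrated over the ligand's solvent-accessible surface restricted to the
# contact region with the hydrophobic pocket.

#' van der Waals radii used for surface construction
#' @return named numeric vector (Angstrom), Bondi-style values.
#' @export
vdw_radii <- function() {
  c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47, Si = 2.10,
    P = 1.80, S = 1.80, Cl = 1.75, Fe = 2.00, Zn = 1.39, Se = 1.90,
    Br = 1.85, I = 1.98)
}

#' Atomic hydrophobicity contributions (surrogate density model)
#'
#' Per-atom logP-style increments distributed uniformly over each atom's
#' exposed accessible surface.  This is a deliberately simple, pluggable
#' density model: the pipeline's contract is "integrate hydrophobicity
#' density over the contact surface", and any per-atom-conserving density
#' preserves that structure (the QSAR coefficient rescales the descriptor).
#' Negative contributions (polar atoms) are permitted and not clamped.
#'
#' @return named numeric vector of contributions (log units per atom).
#' @export
hydrophobicity_contributions <- function() {
  c(C = 0.12, H = 0.03, N = -0.10, O = -0.12, S = 0.10, F = 0.05,
    Cl = 0.15, Br = 0.20, P = 0.05, Fe = 0)
}

# Deterministic near-uniform point layout on the unit sphere
# (Fibonacci/golden-spiral lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Sample the solvent-accessible surface of a pose
#'
#' Shrake-Rupley style sampling: each atom's accessible sphere (vdW radius
#' plus probe radius) carries a deterministic Fibonacci point lattice; points
#' buried inside another atom's accessible sphere are discarded.  Each
#' surviving point carries an equal area element of its parent sphere, so an
#' atom's point areas sum exactly to its estimated exposed accessible area.
#'
#' @param pose a \code{ligand_pose}.
#' @param probe_radius solvent probe radius (Angstrom, default 1.4).
#' @param point_density target points per square Angstrom (default 4).
#' @return data.frame of class \code{surface_points}: \code{x,y,z},
#'   \code{area} (Angstrom^2), \code{owner} (atom index), \code{density}
#'   (NA until \code{\link{assign_density}}); attribute \code{exposed_area}
#'   = per-atom exposed area vector.
#' @export
sample_surface <- function(pose, probe_radius = 1.4, point_density = 4) {
  stopifnot(nrow(pose$atoms) >= 1, probe_radius >= 0, point_density > 0)
  rv <- vdw_radii()
  el <- pose$atoms$element
  if (any(!el %in% names(rv)))
    stop("no van der Waals radius for element(s): ",
         paste(setdiff(el, names(rv)), collapse = ", "))
  R <- unname(rv[el]) + probe_radius
  xyz <- atom_coords(pose)
  n_atoms <- nrow(xyz)
  pts <- vector("list", n_atoms)
  exposed <- numeric(n_atoms)
  for (i in seq_len(n_atoms)) {
    sphere_area <- 4 * pi * R[i]^2
    n_i <- max(12L, as.integer(ceiling(sphere_area * point_density)))
    p <- fibonacci_sphere(n_i) * R[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    keep <- rep(TRUE, n_i)
    for (j in seq_len(n_atoms)) {
      if (j == i) next
      d2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 + (p[, 3] - xyz[j, 3])^2
      keep <- keep & d2 >= R[j]^2
      if (!any(keep)) break
    }
    if (any(keep)) {
      kept <- p[keep, , drop = FALSE]
      area_el <- sphere_area / n_i
      exposed[i] <- sum(keep) * area_el
      pts[[i]] <- data.frame(x = kept[, 1], y = kept[, 2], z = kept[, 3],
                             area = area_el, owner = i, density = NA_real_)
    }
  }
  out <- do.call(rbind, pts)
  if (is.null(out))
    out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      area = numeric(0), owner = integer(0), density = numeric(0))
  rownames(out) <- NULL
  structure(out, exposed_area = exposed, class = c("surface_points", "data.frame"))
}

#' Assign hydrophobicity density to surface points
#'
#' Each point's density is its owner atom's hydrophobicity contribution
#' divided by that atom's total exposed area, so the integral of density
#' over an atom's points reproduces the atomic contribution exactly
#' (conservation); fully buried atoms contribute nothing.
#'
#' @param points a \code{surface_points} object from
#'   \code{\link{sample_surface}}.
#' @param pose the pose the surface was sampled from.
#' @param contributions named per-element contribution vector (see
#'   \code{\link{hydrophobicity_contributions}}).
#' @return the \code{surface_points} with \code{density} filled in.
#' @export
assign_density <- function(points, pose,
                           contributions = hydrophobicity_contributions()) {
  el <- pose$atoms$element
  if (any(!el %in% names(contributions)))
    stop("no hydrophobicity contribution for element(s): ",
         paste(setdiff(el, names(contributions)), collapse = ", "))
  exposed <- attr(points, "exposed_area")
  if (is.null(exposed)) stop("points lack the exposed_area attribute; use sample_surface()")
  dens_per_atom <- ifelse(exposed > 0, unname(contributions[el]) / exposed, 0)
  points$density <- dens_per_atom[points$owner]
  points
}

# Is each point inside the convex access-channel region?
in_access_channel <- function(pts_xyz, channel) {
  rel <- sweep(pts_xyz, 2, channel$ref, "-")
  proj <- as.numeric(rel %*% channel$direction)
  perp2 <- rowSums(rel^2) - proj^2
  proj >= 0 & perp2 <= channel$radius^2
}

#' Hydrophobic contact descriptor log P_C
#'
#' Integrates hydrophobicity density over the ligand surface points that are
#' (i) owned by a non-excluded atom, (ii) within \code{contact_cutoff} of at
#' least one hydrophobic pocket atom, and (iii) outside the access-channel
#' region.  Atoms of flexible substituents and access-channel occupants are
#' excluded because a rotatable group without a pinning interaction does not
#' form a stable hydrophobic contact.
#'
#' @param points a \code{surface_points} with densities assigned.
#' @param site a \code{binding_site}.
#' @param contact_cutoff maximum surface-point to hydrophobic-atom distance
#'   (Angstrom, default 4.5).
#' @param excluded_atoms ligand atom indices excluded from the integral.
#' @return log P_C (dimensionless log-units value).
#' @export
log_pc <- function(points, site, contact_cutoff = 4.5,
                   excluded_atoms = integer(0)) {
  stopifnot(contact_cutoff > 0)
  if (nrow(points) == 0) return(0)
  if (anyNA(points$density))
    stop("surface points lack densities; call assign_density() first")
  keep <- !(points$owner %in% excluded_atoms)
  if (!any(keep)) return(0)
  pts <- as.matrix(points[keep, c("x", "y", "z")])
  hp <- as.matrix(site$hydrophobic_atoms[, c("x", "y", "z")])
  d2 <- outer(rowSums(pts^2), rowSums(hp^2), "+") - 2 * pts %*% t(hp)
  in_contact <- apply(d2, 1, min) <= contact_cutoff^2
  in_channel <- in_access_channel(pts, site$access_channel)
  sel <- in_contact & !in_channel
  sum(points$density[keep][sel] * points$area[keep][sel])
}

#' Flag atoms of flexible substituents
#'
#' Operationalises the exclusion rule for log P_C: an atom belongs to a
#' flexible substituent when it is acyclic and its bond chain back to the
#' ring system crosses at least two consecutive rotatable bonds (single,
#' non-terminal, both ends heavy), and the substituent is not pinned by a
#' detected hydrogen bond or steric contact.  Without such a pin a rotatable
#' group samples alternate conformations and its transient hydrophobic
#' contact does not contribute to affinity.
#'
#' @param pose a \code{ligand_pose}.
#' @param anchored_atoms indices of atoms held by a hydrogen bond or clash
#'   contact; substituent branches containing one are retained.
#' @return integer vector of flexible-substituent atom indices (possibly
#'   empty).
#' @export
flag_flexible_atoms <- function(pose, anchored_atoms = integer(0)) {
  n <- nrow(pose$atoms)
  b <- pose$bonds
  if (nrow(b) == 0) return(integer(0))
  ring <- ring_atom_indices(pose)
  if (length(ring) == 0) return(integer(0))
  el <- pose$atoms$element
  deg <- integer(n)
  tab <- table(factor(c(b$i, b$j), levels = seq_len(n)))
  deg <- as.integer(tab)
  rotatable <- function(i, j) {
    o <- b$order[(b$i == i & b$j == j) | (b$i == j & b$j == i)]
    length(o) && o[1] == 1L && el[i] != "H" && el[j] != "H" &&
      deg[i] > 1 && deg[j] > 1
  }
  nb_list <- lapply(seq_len(n), function(i) c(b$j[b$i == i], b$i[b$j == i]))
  # BFS out of the ring system counting consecutive rotatable bonds
  rotdepth <- rep(NA_real_, n)
  rotdepth[ring] <- 0
  queue <- ring
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    for (j in nb_list[[i]]) {
      step <- if (rotatable(i, j)) rotdepth[i] + 1 else rotdepth[i]
      if (is.na(rotdepth[j]) || step < rotdepth[j]) {
        rotdepth[j] <- step
        queue <- c(queue, j)
      }
    }
  }
  flex <- which(!is.na(rotdepth) & rotdepth >= 2 & !(seq_len(n) %in% ring))
  if (length(anchored_atoms)) {
    # retain any branch that contains an anchored atom: drop flagged atoms
    # connected (through non-ring atoms) to an anchored one
    keep_branch <- integer(0)
    g <- igraph::graph_from_data_frame(b[, c("i", "j")], directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    g2 <- igraph::delete_vertices(g, as.character(ring))
    comp <- igraph::components(g2)$membership
    for (i in flex) {
      ci <- comp[as.character(i)]
      anchored_here <- any(comp[as.character(intersect(anchored_atoms, as.integer(names(comp))))] == ci)
      if (anchored_here) keep_branch <- c(keep_branch, i)
    }
    flex <- setdiff(flex, keep_branch)
  }
  as.integer(flex)
}
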