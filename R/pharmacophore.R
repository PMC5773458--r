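# Block-function scoring of protein-ligand interaction features and the
# binary fingerprint bits FP1-FP7.

#' Block-function parameter presets
#'
#' Each putative interaction is scored by the product of three piecewise
#' linear block functions of the H...A distance deviation and the D-H...A
#' and H...A-X angle deviations.  Three named presets cover the feature
#' classes: ordinary hydrogen bonds, the 19-hydroxyl/19-keto oxygen to
#' heme-iron interaction, and azaheterocyclic nitrogen coordination of the
#' heme-iron.
#'
#' @param preset one of \code{"hydrogen_bond"}, \code{"heme_c19_oxygen"},
#'   \code{"heme_azaheterocycle"}, or \code{"custom"} (supply all values).
#' @param r_ideal,dr_ideal,dr_max ideal H...A distance (Angstrom), its
#'   tolerance window and maximum deviation.
#' @param alpha_ideal,da_ideal,da_max ideal D-H...A angle (degrees),
#'   tolerance and maximum deviation.
#' @param beta_ideal,db_ideal,db_max ideal H...A-X angle (degrees),
#'   tolerance and maximum deviation.
#' @return an object of class \code{block_params}.
#' @export
block_params <- function(preset = c("hydrogen_bond", "heme_c19_oxygen",
                                    "heme_azaheterocycle", "custom"),
                         r_ideal = NULL, dr_ideal = NULL, dr_max = NULL,
                         alpha_ideal = NULL, da_ideal = NULL, da_max = NULL,
                         beta_ideal = NULL, db_ideal = NULL, db_max = NULL) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    hydrogen_bond = list(2.00, 0.50, 0.65, 180, 45, 80, 180, 80, 100),
    heme_c19_oxygen = list(2.40, 0.25, 0.65, 180, 10, 40, 180, 80, 100),
    heme_azaheterocycle = list(2.25, 0.25, 0.65, 180, 20, 40, 180, 60, 100),
    custom = list(r_ideal, dr_ideal, dr_max, alpha_ideal, da_ideal, da_max,
                  beta_ideal, db_ideal, db_max)
  )
  given <- list(r_ideal, dr_ideal, dr_max, alpha_ideal, da_ideal, da_max,
                beta_ideal, db_ideal, db_max)
  vals <- mapply(function(g, d) if (is.null(g)) d else g, given, defaults,
                 SIMPLIFY = FALSE)
  names(vals) <- c("r_ideal", "dr_ideal", "dr_max", "alpha_ideal", "da_ideal",
                   "da_max", "beta_ideal", "db_ideal", "db_max")
  if (any(vapply(vals, is.null, logical(1))))
    stop("custom block_params require all nine values")
  with(vals, {
    if (!(0 <= dr_ideal && dr_ideal < dr_max)) stop("need 0 <= dr_ideal < dr_max")
    if (!(0 <= da_ideal && da_ideal < da_max)) stop("need 0 <= da_ideal < da_max")
    if (!(0 <= db_ideal && db_ideal < db_max)) stop("need 0 <= db_ideal < db_max")
  })
  structure(vals, class = "block_params", preset = preset)
}

#' Piecewise-linear block function
#'
#' Maps a non-negative deviation \code{x} from an ideal value to [0, 1]:
#' 1 for \code{x <= x_ideal}, linearly decreasing to 0 at \code{x_max},
#' 0 beyond.  Continuous and non-increasing.
#'
#' @param x non-negative deviation (vectorised).
#' @param x_ideal tolerance window within which the interaction is ideal.
#' @param x_max maximum deviation beyond which the interaction is absent.
#' @return value(s) in [0, 1].
#' @export
block <- function(x, x_ideal, x_max) {
  if (!(0 <= x_ideal && x_ideal < x_max)) stop("need 0 <= x_ideal < x_max")
  if (any(x < 0)) stop("deviation x must be non-negative")
  ifelse(x <= x_ideal, 1,
         ifelse(x > x_max, 0, 1 - (x - x_ideal) / (x_max - x_ideal)))
}

#' Interaction geometry between a donor-H pair and an acceptor
#'
#' @param d_HA hydrogen-acceptor distance (Angstrom), > 0.
#' @param angle_DHA donor-hydrogen-acceptor angle (degrees, [0, 180]).
#' @param angle_HAX hydrogen-acceptor-attached-heavy-atom angle (degrees).
#' @return object of class \code{interaction_geometry}.
#' @export
interaction_geometry <- function(d_HA, angle_DHA, angle_HAX) {
  stopifnot(d_HA > 0, angle_DHA >= 0, angle_DHA <= 180,
            angle_HAX >= 0, angle_HAX <= 180)
  structure(list(d_HA = d_HA, angle_DHA = angle_DHA, angle_HAX = angle_HAX),
            class = "interaction_geometry")
}

# Geometry from the four atom positions (h = hydrogen, a = acceptor,
# d = donor heavy atom, x = heavy atom attached to the acceptor).
geometry_from_points <- function(h, a, d, x) {
  interaction_geometry(
    d_HA = vnorm(h - a),
    angle_DHA = vangle(d, h, a),
    angle_HAX = vangle(h, a, x)
  )
}

#' Interaction score: product of three block functions
#'
#' \eqn{\Delta R = B(|d - r|) B(|\alpha_{DHA} - \alpha|) B(|\beta_{HAX} - \beta|)},
#' each block taking the absolute deviation of the measured variable from its
#' ideal value.
#'
#' @param geom an \code{\link{interaction_geometry}} (or a list with fields
#'   \code{d_HA}, \code{angle_DHA}, \code{angle_HAX}).
#' @param params a \code{\link{block_params}} preset.
#' @return value in [0, 1].
#' @export
delta_R <- function(geom, params = block_params("hydrogen_bond")) {
  block(abs(geom$d_HA - params$r_ideal), params$dr_ideal, params$dr_max) *
    block(abs(geom$angle_DHA - params$alpha_ideal), params$da_ideal, params$da_max) *
    block(abs(geom$angle_HAX - params$beta_ideal), params$db_ideal, params$db_max)
}

#' Binarise an interaction score
#'
#' A fingerprint bit is 1 when the block-function product is at least 0.6
#' (boundary inclusive).
#'
#' @param delta_R_value score in [0, 1] (vectorised).
#' @param threshold bit threshold (default 0.6).
#' @return 0 or 1 (integer).
#' @export
feature_bit <- function(delta_R_value, threshold = 0.6) {
  stopifnot(all(delta_R_value >= 0), all(delta_R_value <= 1))
  as.integer(delta_R_value >= threshold)
}

#' C19 carbon to heme-iron distance bit
#'
#' The interaction of the steroid C19 carbon with the heme-iron is defined
#' purely by distance: the bit is 1 iff the distance is strictly below
#' 4.3 Angstrom.
#'
#' @param d distance (Angstrom), > 0 (vectorised).
#' @param cutoff distance cutoff (default 4.3).
#' @return 0 or 1 (integer).
#' @export
c19_iron_bit <- function(d, cutoff = 4.3) {
  stopifnot(all(d > 0))
  as.integer(d < cutoff)
}

#' Default preset bundle used by the feature detector
#' @return named list of the three \code{\link{block_params}} presets.
#' @export
default_block_presets <- function() {
  list(hydrogen_bond = block_params("hydrogen_bond"),
       heme_c19_oxygen = block_params("heme_c19_oxygen"),
       heme_azaheterocycle = block_params("heme_azaheterocycle"))
}

# Best (maximum) delta_R over candidate ligand atoms for one anchored
# feature; ties broken by lowest atom index (iteration order).
best_delta_r <- function(pose, cand_idx, anchor, params, ligand_is_donor) {
  best <- 0
  best_atom <- NA_integer_
  coords <- atom_coords(pose)
  for (i in cand_idx) {
    if (ligand_is_donor) {
      # ligand H -> protein acceptor (anchor position = acceptor A,
      # anchor attached = heavy atom X bonded to A)
      d_idx <- atom_neighbours(pose, i, heavy_only = TRUE)
      if (length(d_idx) == 0) next
      g <- geometry_from_points(h = coords[i, ], a = anchor$position,
                                d = coords[d_idx[1], ], x = anchor$attached)
      v <- delta_R(g, params)
      if (v > best) { best <- v; best_atom <- i }
    } else {
      # protein donor H (anchor position) -> ligand acceptor atom i;
      # X is each heavy neighbour of the acceptor (best over X)
      x_idx <- atom_neighbours(pose, i, heavy_only = TRUE)
      if (length(x_idx) == 0) next
      for (x in x_idx) {
        g <- geometry_from_points(h = anchor$position, a = coords[i, ],
                                  d = anchor$attached, x = coords[x, ])
        v <- delta_R(g, params)
        if (v > best) { best <- v; best_atom <- i }
      }
    }
  }
  list(delta_R = best, atom = best_atom)
}

# Ligand donor hydrogens; when the pose carries no explicit polar hydrogens,
# idealised H positions are synthesised on hydroxyl oxygens and
# under-substituted nitrogens, pointing at the acceptor (so the donor angle
# term is ideal and the distance term decides).
donor_h_candidates <- function(pose) {
  atoms_with_role(pose, "hbond_donor_H")
}

implicit_donor_heavies <- function(pose) {
  oh <- atoms_with_role(pose, "hydroxyl_O")
  ns <- which(pose$atoms$element == "N")
  ns <- ns[vapply(ns, function(i) {
    nb <- atom_neighbours(pose, i)
    length(nb) <= 2 && !any(pose$atoms$element[nb] == "H")
  }, logical(1))]
  ns <- setdiff(ns, atoms_with_role(pose, "aromatic_ring_N"))
  ns <- setdiff(ns, atoms_with_role(pose, "nitrile_N"))
  union(oh, ns)
}

# delta_R of an implicitly-placed donor H on heavy atom `i` toward the
# anchor acceptor: H sits 1.0 A from the heavy donor on the line to A.
implicit_donor_delta_r <- function(pose, heavy_idx, anchor, params) {
  best <- 0; best_atom <- NA_integer_
  coords <- atom_coords(pose)
  for (i in heavy_idx) {
    dvec <- anchor$position - coords[i, ]
    if (vnorm(dvec) < 1e-9) next
    h <- coords[i, ] + 1.0 * vunit(dvec)
    g <- geometry_from_points(h = h, a = anchor$position,
                              d = coords[i, ], x = anchor$attached)
    v <- delta_R(g, params)
    if (v > best) { best <- v; best_atom <- i }
  }
  list(delta_R = best, atom = best_atom)
}

#' Detect interaction features and emit fingerprint bits FP1-FP7
#'
#' Scores every candidate ligand atom against the six hydrogen-bond anchors
#' and the heme-iron, taking the best block-function product per feature
#' (ties broken by lowest atom index), and binarises at 0.6.  FP7 is set if
#' either a C19 oxygen satisfies the heme-oxygen geometry preset (with the
#' iron playing the hydrogen role and Cys437 S the donor role) and the C19
#' substituent environment is admissible, or the C19 carbon lies within
#' 4.3 Angstrom of the iron.  Two additional candidate features (hydroxyl
#' oxygen and nitro oxygen to Met374) and the azaheterocycle-nitrogen
#' coordination geometry are computed and reported in the
#' \code{"candidates"} attribute but never enter the fingerprint.
#'
#' @param pose a \code{ligand_pose} with role tags assigned.
#' @param site a \code{binding_site}.
#' @param c19_carbon,c19_oxygen optional atom indices overriding pose role
#'   tags (C19 identity is annotation, not connectivity).
#' @param c19_env_ok logical: is the C19-oxygen substituent environment
#'   admissible (R1/R2 hydrogens, R3 hydrogen or ketone)?  Supplied as an
#'   annotation.
#' @param presets list of the three block-parameter presets (see
#'   \code{\link{default_block_presets}}).
#' @param threshold bit threshold on the block-function product.
#' @return named numeric vector \code{FP1..FP9} (class
#'   \code{interaction_fingerprint}; FP8 and FP9 are zero here), with
#'   attributes \code{delta_R} (best score per feature) and
#'   \code{candidates} (unselected features and the coordination geometry).
#' @export
detect_features <- function(pose, site, c19_carbon = NULL, c19_oxygen = NULL,
                            c19_env_ok = FALSE,
                            presets = default_block_presets(),
                            threshold = 0.6) {
  if (!inherits(site, "binding_site")) stop("site must be a binding_site")
  hb <- presets$hydrogen_bond
  if (!is.null(c19_carbon) || !is.null(c19_oxygen))
    pose <- tag_c19(pose, c19_carbon, c19_oxygen)
  coords <- atom_coords(pose)
  an <- site$anchors

  # FP1: ligand donor -> Ala306 carbonyl oxygen.  Idealised hydrogens are
  # synthesised only when the pose carries no explicit donor hydrogens.
  donor_h <- donor_h_candidates(pose)
  fp1 <- if (length(donor_h)) {
    best_delta_r(pose, donor_h, an$Ala306_carbonyl_O, hb, ligand_is_donor = TRUE)
  } else {
    implicit_donor_delta_r(pose, implicit_donor_heavies(pose),
                           an$Ala306_carbonyl_O, hb)
  }

  acceptors <- atoms_with_role(pose, "hbond_acceptor")
  fp2 <- best_delta_r(pose, acceptors, an$Asp309_COOH, hb, FALSE)
  fp3 <- best_delta_r(pose, acceptors, an$Thr310_OH, hb, FALSE)
  fp4 <- best_delta_r(pose, atoms_with_role(pose, "keto_or_ether_O"),
                      an$Met374_amide_NH, hb, FALSE)
  fp5 <- best_delta_r(pose, atoms_with_role(pose, "nitrile_N"),
                      an$Met374_amide_NH, hb, FALSE)
  fp6 <- best_delta_r(pose, atoms_with_role(pose, "aromatic_ring_N"),
                      an$Met374_amide_NH, hb, FALSE)
  # candidate features that were evaluated but never selected into the model
  cand_oh <- best_delta_r(pose, atoms_with_role(pose, "hydroxyl_O"),
                          an$Met374_amide_NH, hb, FALSE)
  cand_no <- best_delta_r(pose, atoms_with_role(pose, "nitro_O"),
                          an$Met374_amide_NH, hb, FALSE)

  # FP7 oxygen route: iron plays H, Cys437 S plays D, C19 oxygen plays A
  fe <- an$heme_iron$position
  s <- an$Cys437_S$position
  o_idx <- atoms_with_role(pose, "C19_oxygen")
  fp7_o <- 0
  for (i in o_idx) {
    x_idx <- atom_neighbours(pose, i, heavy_only = TRUE)
    for (x in x_idx) {
      g <- geometry_from_points(h = fe, a = coords[i, ], d = s, x = coords[x, ])
      fp7_o <- max(fp7_o, delta_R(g, presets$heme_c19_oxygen))
    }
  }
  c_idx <- atoms_with_role(pose, "C19_carbon")
  d_c19 <- if (length(c_idx)) min(vapply(c_idx, function(i) vnorm(coords[i, ] - fe),
                                         numeric(1))) else Inf
  fp7_bit <- as.integer(
    (feature_bit(fp7_o, threshold) == 1L && isTRUE(c19_env_ok)) ||
      (is.finite(d_c19) && c19_iron_bit(d_c19) == 1L)
  )

  # coordination geometry (candidate feature 10): aromatic ring N vs iron
  arN <- atoms_with_role(pose, "aromatic_ring_N")
  coord <- 0; coord_atom <- NA_integer_
  for (i in arN) {
    x_idx <- atom_neighbours(pose, i, heavy_only = TRUE)
    for (x in x_idx) {
      g <- geometry_from_points(h = fe, a = coords[i, ], d = s, x = coords[x, ])
      v <- delta_R(g, presets$heme_azaheterocycle)
      if (v > coord) { coord <- v; coord_atom <- i }
    }
  }

  fp <- c(FP1 = feature_bit(fp1$delta_R, threshold),
          FP2 = feature_bit(fp2$delta_R, threshold),
          FP3 = feature_bit(fp3$delta_R, threshold),
          FP4 = feature_bit(fp4$delta_R, threshold),
          FP5 = feature_bit(fp5$delta_R, threshold),
          FP6 = feature_bit(fp6$delta_R, threshold),
          FP7 = fp7_bit, FP8 = 0, FP9 = 0)
  structure(as.numeric(fp), names = names(fp),
            class = "interaction_fingerprint",
            delta_R = c(FP1 = fp1$delta_R, FP2 = fp2$delta_R, FP3 = fp3$delta_R,
                        FP4 = fp4$delta_R, FP5 = fp5$delta_R, FP6 = fp6$delta_R,
                        FP7_oxygen = fp7_o),
            c19_iron_distance = d_c19,
            candidates = list(
              hydroxyl_O_Met374 = list(delta_R = cand_oh$delta_R,
                                       bit = feature_bit(cand_oh$delta_R, threshold)),
              nitro_O_Met374 = list(delta_R = cand_no$delta_R,
                                    bit = feature_bit(cand_no$delta_R, threshold)),
              coordination = list(delta_R = coord,
                                  bit = feature_bit(coord, threshold),
                                  atom = coord_atom)))
}

# Apply C19 annotations to a pose's role tags.
tag_c19 <- function(pose, c19_carbon, c19_oxygen) {
  n <- nrow(pose$atoms)
  if (!is.null(c19_carbon) && any(c19_carbon < 1 | c19_carbon > n))
    stop("C19 annotation out of range for ligand ", pose$ligand_id)
  if (!is.null(c19_oxygen) && any(c19_oxygen < 1 | c19_oxygen > n))
    stop("C19 annotation out of range for ligand ", pose$ligand_id)
  for (i in c19_carbon)
    pose$atoms$roles[[i]] <- union(pose$atoms$roles[[i]], "C19_carbon")
  for (i in c19_oxygen) {
    if (pose$atoms$element[i] != "O")
      stop("C19 oxygen annotation names a non-oxygen atom (", i, ")")
    pose$atoms$roles[[i]] <- union(pose$atoms$roles[[i]], "C19_oxygen")
  }
  pose
}

#' @export
print.interaction_fingerprint <- function(x, ...) {
  cat("<interaction_fingerprint>\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}
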