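# Synthetic binding-site geometry, poses, ensembles and activity cohorts
# with known ground truth, so every pipeline stage is testable without
# structure downloads.

#' Parameters of the synthetic cohort generator
#'
#' Defaults emulate the study conditions of the aromatase data set the
#' package models: 122 steroidal and 87 azaheterocyclic training compounds;
#' class-specific hydrophobic-contact ranges (steroids 1.286-2.125, azoles
#' 0.203-1.910 log units); a right-skewed smallest-dual-descriptor
#' distribution whose FP8 transform spans roughly 1.4-7.2 log units of
#' coordination contribution (few azoles are letrozole-class coordinators);
#' Gaussian activity noise; and a coordination "misfit" term expressing that
#' the electronic descriptor explains only ~60 percent of the coordination
#' contribution's variance.
#'
#' @param seed RNG seed.
#' @param n_steroid,n_aza cohort sizes per class.
#' @param feature_prevalence named FP1..FP7 Bernoulli prevalences (FP5/FP6
#'   apply only within the azaheterocycle class, FP7 only within steroids).
#' @param logpc_range list of per-class \code{c(min, max)} intervals for FP9
#'   (clipped uniform sampling).
#' @param dfs_range interval for the smallest dual descriptor.
#' @param dfs_shape Beta shape parameters of the (rescaled) dfs draw;
#'   \code{c(1, 1)} gives the uniform distribution.
#' @param coord_fraction fraction of azaheterocycles that coordinate the
#'   heme iron (training-cohort default: all of them).
#' @param coord_sigma SD (log units) of the coordination contribution not
#'   captured by the FP8 descriptor.
#' @param noise_sigma SD of the Gaussian pIC50 noise (log units).
#' @param jitter_sigma per-atom Gaussian jitter for pose ensembles (Angstrom).
#' @param decoy_count decoy poses per ensemble.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(seed = 1, n_steroid = 122, n_aza = 87,
                           feature_prevalence = c(FP1 = 0.15, FP2 = 0.35,
                                                  FP3 = 0.25, FP4 = 0.60,
                                                  FP5 = 0.35, FP6 = 0.05,
                                                  FP7 = 0.60),
                           logpc_range = list(steroid = c(1.286, 2.125),
                                              azaheterocycle = c(0.203, 1.910)),
                           dfs_range = c(-0.065, 0.085),
                           dfs_shape = c(2, 5),
                           coord_fraction = 1.0,
                           coord_sigma = 0.74,
                           noise_sigma = 0.3,
                           jitter_sigma = 0.05,
                           decoy_count = 5) {
  stopifnot(all(feature_prevalence >= 0 & feature_prevalence <= 1),
            dfs_range[1] < dfs_range[2], noise_sigma >= 0,
            jitter_sigma >= 0, coord_sigma >= 0,
            coord_fraction >= 0, coord_fraction <= 1)
  if (is.numeric(logpc_range))
    logpc_range <- list(steroid = logpc_range, azaheterocycle = logpc_range)
  stopifnot(logpc_range$steroid[1] < logpc_range$steroid[2],
            logpc_range$azaheterocycle[1] < logpc_range$azaheterocycle[2])
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Build the toy binding-site model
#'
#' A schematic aromatase pocket in a canonical frame: heme iron at the
#' origin; the four heme nitrogens 2.0 Angstrom away on the x/y axes in the
#' z = 0 plane; the Cys437 thiolate 2.3 Angstrom below the iron on the -z
#' axis (so the S-Fe axis is perpendicular to the heme plane); the four
#' hydrogen-bond anchors 6.4-7.2 Angstrom above the plane with their donor
#' hydrogens / acceptor lone pairs pointing at the pocket centre (0, 0,
#' 5.5); eight hydrophobic pocket atoms lining a 5.2-Angstrom-radius ring;
#' and a cylindrical access-channel region on the +x flank.  Ligands bind
#' with their beta face toward the heme, which this geometry mimics.
#'
#' @param seed accepted for interface uniformity; the geometry is fixed.
#' @return a \code{binding_site}.
#' @export
make_toy_site <- function(seed = 1) {
  centre <- c(0, 0, 5.5)
  place_towards <- function(pos, target, len) pos + len * vunit(target - pos)
  away_from <- function(pos, target, len) pos + len * vunit(pos - target)
  ala_o <- c(-3.2, 1.6, 7.0)
  asp_o <- c(-1.8, -3.4, 6.4)
  thr_o <- c(2.8, -2.4, 6.8)
  met_n <- c(3.4, 1.8, 7.2)
  anchors <- list(
    Ala306_carbonyl_O = list(position = ala_o,
                             attached = away_from(ala_o, centre, 1.23),
                             role = "acceptor", element = "O",
                             attached_element = "C"),
    Asp309_COOH = list(position = place_towards(asp_o, centre, 0.96),
                       attached = asp_o, role = "donor", element = "H",
                       attached_element = "O"),
    Thr310_OH = list(position = place_towards(thr_o, centre, 0.96),
                     attached = thr_o, role = "donor", element = "H",
                     attached_element = "O"),
    Met374_amide_NH = list(position = place_towards(met_n, centre, 1.01),
                           attached = met_n, role = "donor", element = "H",
                           attached_element = "N"),
    heme_iron = list(position = c(0, 0, 0), role = "iron", element = "Fe"),
    Cys437_S = list(position = c(0, 0, -2.3), attached = c(0, 0, -3.9),
                    role = "donor", element = "S", attached_element = "C"),
    heme_N = rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0))
  )
  res <- c("Ile133", "Phe134", "Phe221", "Trp224", "Val369", "Val370",
           "Leu477", "Ser478")
  ang <- seq(0, 2 * pi, length.out = 9)[-9] + pi / 8
  hydrophobic <- data.frame(
    x = 5.2 * cos(ang), y = 5.2 * sin(ang),
    z = rep(c(4.5, 6.5), 4), residue = res
  )
  channel <- list(ref = c(4.0, 0, 5.5), direction = c(1, 0, 0), radius = 2.2)
  binding_site(anchors, hydrophobic, channel)
}

# Feature placement geometry: each "on" feature is realised at the ideal
# window (block product 1); "off" outside the distance cutoff; "marginal"
# at a distance deviation giving a block product inside [0.55, 0.65].
POSE_FEATURES <- c("FP1", "FP2", "FP3", "FP4", "FP5", "FP6", "FP7", "coordination")

#' Construct a pose realising requested interaction features
#'
#' Builds a minimal atom cloud (not a chemically realistic molecule; the
#' scored quantities are purely geometric) whose groups sit at controlled
#' geometry relative to the toy-site anchors.  \code{"on"} features land in
#' the ideal block-function window, \code{"off"} beyond the distance
#' cutoff, \code{"marginal"} at a block product inside [0.55, 0.65] for
#' boundary tests.  FP7 is realised through the C19-carbon distance rule
#' (carbon drawn 3.8-4.2 Angstrom from the iron).  The returned pose
#' carries attributes \code{truth} (the FP1-FP7 bit vector the detector
#' must reproduce for on/off requests), \code{coordinated}, and
#' \code{c19_carbon} (annotation index, when present).
#'
#' @param site the toy \code{binding_site}.
#' @param want named character vector over
#'   \code{FP1..FP7}/\code{coordination} with values \code{"on"},
#'   \code{"off"} or \code{"marginal"}; omitted features are absent.
#' @param seed RNG seed.
#' @param ligand_id,pose_id,source_run identifiers.
#' @return a \code{ligand_pose} with role tags assigned.
#' @export
make_pose_with_features <- function(site, want = character(0), seed = 1,
                                    ligand_id = "synlig", pose_id = NULL,
                                    source_run = 1L) {
  bad <- setdiff(names(want), POSE_FEATURES)
  if (length(bad)) stop("unknown feature request(s): ", paste(bad, collapse = ", "))
  if (is.null(pose_id)) pose_id <- paste0(ligand_id, "_p1")
  an <- site$anchors
  centre <- c(0, 0, 5.5)
  hb <- block_params("hydrogen_bond")

  with_seed(seed, {
    atoms <- list()
    bonds <- list()
    roles <- list()
    add_atom <- function(element, pos, role = character(0)) {
      atoms[[length(atoms) + 1]] <<- c(pos)
      roles[[length(roles) + 1]] <<- role
      names(atoms)[length(atoms)] <<- element
      length(atoms)
    }
    add_bond <- function(i, j, order = 1L) {
      bonds[[length(bonds) + 1]] <<- c(i, j, order)
    }
    # scaffold: two plain carbons near the pocket centre
    sc1 <- add_atom("C", centre + c(0.0, 0.3, 0.0))
    sc2 <- add_atom("C", centre + c(1.2, 0.3, 0.6))
    add_bond(sc1, sc2)

    # distance for a given regime, along the ideal approach line
    dist_for <- function(mode, params) {
      switch(mode,
        on = params$r_ideal + stats::runif(1, -0.6, 0.6) * params$dr_ideal,
        off = params$r_ideal + params$dr_max + stats::runif(1, 0.5, 2.0),
        marginal = params$r_ideal + params$dr_ideal +
          stats::runif(1, 0.35, 0.45) * (params$dr_max - params$dr_ideal)
      )
    }
    # "off" groups are parked on a ring far above the pocket so they sit
    # outside every anchor's distance window (an atom placed merely beyond
    # its own anchor could still satisfy a neighbouring one)
    n_parked <- 0L
    park_spot <- function() {
      n_parked <<- n_parked + 1L
      theta <- n_parked * 2.39996  # golden angle: spots never coincide
      c(8 * cos(theta), 8 * sin(theta), 13 + 0.8 * n_parked)
    }

    truth <- c(FP1 = 0, FP2 = 0, FP3 = 0, FP4 = 0, FP5 = 0, FP6 = 0, FP7 = 0)
    coordinated <- FALSE
    c19_idx <- NULL

    # ligand-donor feature (FP1): H at controlled distance from the
    # acceptor anchor along the A->pocket line; donor heavy behind the H.
    if (!is.na(want["FP1"])) {
      a <- an$Ala306_carbonyl_O
      dir <- vunit(centre - a$position)
      if (want[["FP1"]] == "off") {
        h <- park_spot()
      } else {
        d <- dist_for(want[["FP1"]], hb)
        h <- a$position + d * dir
      }
      o <- h + 0.97 * dir
      oi <- add_atom("O", o, c("hydroxyl_O", "hbond_acceptor"))
      hi <- add_atom("H", h, "hbond_donor_H")
      add_bond(oi, hi); add_bond(sc1, oi)
      if (want[["FP1"]] == "on") truth["FP1"] <- 1
    }

    # protein-donor features: acceptor atom on the D->H line extended.
    place_acceptor <- function(anchor, mode, acc_element, acc_roles,
                               x_element = "C", bond_order = 1L) {
      dir <- vunit(anchor$position - anchor$attached)  # D -> H direction
      if (mode == "off") {
        a_pos <- park_spot()
      } else {
        d <- dist_for(mode, hb)
        a_pos <- anchor$position + d * dir
      }
      x_pos <- a_pos + 1.35 * dir
      ai <- add_atom(acc_element, a_pos, acc_roles)
      xi <- add_atom(x_element, x_pos)
      add_bond(ai, xi, bond_order)
      add_bond(sc2, xi)
      ai
    }
    if (!is.na(want["FP2"])) {
      place_acceptor(an$Asp309_COOH, want[["FP2"]], "O",
                     c("hbond_acceptor", "keto_or_ether_O"), bond_order = 2L)
      if (want[["FP2"]] == "on") truth["FP2"] <- 1
    }
    if (!is.na(want["FP3"])) {
      place_acceptor(an$Thr310_OH, want[["FP3"]], "O",
                     c("hbond_acceptor", "keto_or_ether_O"), bond_order = 2L)
      if (want[["FP3"]] == "on") truth["FP3"] <- 1
    }
    if (!is.na(want["FP4"])) {
      place_acceptor(an$Met374_amide_NH, want[["FP4"]], "O",
                     c("hbond_acceptor", "keto_or_ether_O"), bond_order = 2L)
      if (want[["FP4"]] == "on") truth["FP4"] <- 1
    }
    if (!is.na(want["FP5"])) {
      place_acceptor(an$Met374_amide_NH, want[["FP5"]], "N",
                     c("hbond_acceptor", "nitrile_N"), bond_order = 3L)
      if (want[["FP5"]] == "on") truth["FP5"] <- 1
    }
    if (!is.na(want["FP6"])) {
      ai <- place_acceptor(an$Met374_amide_NH, want[["FP6"]], "N",
                           c("hbond_acceptor", "aromatic_ring_N"),
                           bond_order = 4L)
      # close a minimal ring so connectivity-based tagging also fires
      xi <- length(atoms)  # the X carbon just added
      ci <- add_atom("C", atoms[[ai]] + c(0.0, 1.35, 0.0))
      add_bond(ai, ci, 4L); add_bond(ci, xi, 4L)
      if (want[["FP6"]] == "on") truth["FP6"] <- 1
    }
    if (!is.na(want["FP7"])) {
      d <- switch(want[["FP7"]],
                  on = stats::runif(1, 3.8, 4.2),
                  off = stats::runif(1, 5.5, 7.0),
                  marginal = stats::runif(1, 4.25, 4.35))
      pos <- an$heme_iron$position + d * c(0, 0, 1)
      c19_idx <- add_atom("C", pos, "C19_carbon")
      add_bond(sc1, c19_idx)
      if (want[["FP7"]] == "on") truth["FP7"] <- 1
    }
    if (!is.na(want["coordination"])) {
      params <- block_params("heme_azaheterocycle")
      dir <- vunit(an$heme_iron$position - an$Cys437_S$position)  # +z
      d <- dist_for(want[["coordination"]], params)
      npos <- an$heme_iron$position + d * dir
      ni <- add_atom("N", npos, c("hbond_acceptor", "aromatic_ring_N"))
      xi <- add_atom("C", npos + 1.35 * dir)
      # third ring atom extends up and away from the heme plane so an
      # "on" coordination geometry is clash-free ground truth
      ci <- add_atom("C", npos + c(0.7, 0, 1.2))
      add_bond(ni, xi, 4L); add_bond(xi, ci, 4L); add_bond(ci, ni, 4L)
      add_bond(sc1, xi)
      coordinated <- want[["coordination"]] == "on"
    }

    atom_df <- data.frame(
      index = seq_along(atoms),
      element = names(atoms),
      do.call(rbind, atoms),
      formal_charge = 0,
      stringsAsFactors = FALSE
    )
    names(atom_df)[3:5] <- c("x", "y", "z")
    atom_df$roles <- roles
    bond_df <- as.data.frame(do.call(rbind, bonds))
    names(bond_df) <- c("i", "j", "order")
    pose <- ligand_pose(ligand_id, pose_id, atom_df, bond_df, source_run)
    attr(pose, "truth") <- truth
    attr(pose, "coordinated") <- coordinated
    attr(pose, "c19_carbon") <- c19_idx
    pose
  })
}

#' Generate a jittered pose ensemble with decoys
#'
#' \code{n_copies} replicas of the input pose with independent per-atom
#' Gaussian jitter plus \code{decoys} poses rigidly displaced by at least
#' 3 Angstrom in distinct directions, emulating the output of repeated
#' docking runs.  Ground-truth cluster labels are attached (0 = replica of
#' the input pose, k = decoy k).
#'
#' @param pose the reference \code{ligand_pose}.
#' @param n_copies number of jittered replicas (>= 0).
#' @param jitter_sigma per-atom Gaussian SD (Angstrom).
#' @param decoys number of displaced decoy poses.
#' @param seed RNG seed (equal seeds give bitwise-identical ensembles).
#' @return list of poses with attribute \code{cluster_id}.
#' @export
make_ensemble <- function(pose, n_copies, jitter_sigma = 0.05, decoys = 0,
                          seed = 1) {
  stopifnot(n_copies >= 0, decoys >= 0)
  with_seed(seed, {
    out <- list()
    labels <- integer(0)
    for (k in seq_len(n_copies)) {
      p <- pose
      n <- nrow(p$atoms)
      p$atoms$x <- p$atoms$x + stats::rnorm(n, 0, jitter_sigma)
      p$atoms$y <- p$atoms$y + stats::rnorm(n, 0, jitter_sigma)
      p$atoms$z <- p$atoms$z + stats::rnorm(n, 0, jitter_sigma)
      p$pose_id <- sprintf("%s_rep%d", pose$pose_id, k)
      p$source_run <- k
      out[[length(out) + 1]] <- p
      labels <- c(labels, 0L)
    }
    # decoys: rigid displacements 3.5k Angstrom along varied directions so
    # decoy-decoy and decoy-replica RMSDs all exceed the cluster threshold
    dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                  c(-1, 0, 0), c(0, -1, 0), c(0, 0, -1))
    for (k in seq_len(decoys)) {
      d <- dirs[((k - 1) %% nrow(dirs)) + 1, ] * (3.5 * ceiling(k / nrow(dirs)))
      p <- pose
      p$atoms$x <- p$atoms$x + d[1]
      p$atoms$y <- p$atoms$y + d[2]
      p$atoms$z <- p$atoms$z + d[3]
      p$pose_id <- sprintf("%s_decoy%d", pose$pose_id, k)
      p$source_run <- n_copies + k
      out[[length(out) + 1]] <- p
      labels <- c(labels, k)
    }
    attr(out, "cluster_id") <- labels
    out
  })
}

#' Generate a fingerprint/activity cohort with known coefficients
#'
#' Binary bits are Bernoulli draws at the spec prevalences with class
#' constraints (FP5, FP6 and FP8 only for azaheterocycles, FP7 only for
#' steroids); FP9 is uniform over the class-specific log P_C interval;
#' coordinated azoles receive a smallest-dual-descriptor draw and its FP8
#' transform; pIC50 is the generating model's prediction plus a
#' coordination-misfit term (azoles; the part of the coordination
#' contribution the descriptor does not capture) plus Gaussian noise.  The
#' generating model and true coordination contributions are stored for
#' recovery tests.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param model the generating \code{qsar_model} (default: the generalized
#'   preset).
#' @return data.frame with columns \code{ligand_id}, \code{class},
#'   \code{FP1..FP9}, \code{dfs}, \code{coordinated}, \code{pIC50};
#'   attributes \code{model}, \code{spec}, \code{coord_true}.
#' @export
make_cohort <- function(spec = synthetic_spec(),
                        model = qsar_preset("table2_generalized")) {
  with_seed(spec$seed, {
    n <- spec$n_steroid + spec$n_aza
    cls <- c(rep("steroid", spec$n_steroid), rep("azaheterocycle", spec$n_aza))
    prev <- spec$feature_prevalence
    draw_bit <- function(fp, active) {
      p <- if (fp %in% names(prev)) prev[[fp]] else 0
      as.numeric(active & stats::runif(n) < p)
    }
    is_ster <- cls == "steroid"
    is_aza <- !is_ster
    tbl <- data.frame(
      ligand_id = sprintf("syn%03d", seq_len(n)),
      class = cls,
      FP1 = draw_bit("FP1", TRUE),
      FP2 = draw_bit("FP2", TRUE),
      FP3 = draw_bit("FP3", TRUE),
      FP4 = draw_bit("FP4", TRUE),
      FP5 = draw_bit("FP5", is_aza),
      FP6 = draw_bit("FP6", is_aza),
      FP7 = draw_bit("FP7", is_ster),
      stringsAsFactors = FALSE
    )
    tbl$coordinated <- is_aza & stats::runif(n) < spec$coord_fraction
    dfs <- rep(NA_real_, n)
    b <- stats::rbeta(sum(tbl$coordinated), spec$dfs_shape[1], spec$dfs_shape[2])
    dfs[tbl$coordinated] <- spec$dfs_range[1] +
      b * (spec$dfs_range[2] - spec$dfs_range[1])
    tbl$dfs <- dfs
    tbl$FP8 <- fp8_term(dfs, tbl$coordinated)
    lr <- spec$logpc_range
    tbl$FP9 <- ifelse(is_ster,
                      stats::runif(n, lr$steroid[1], lr$steroid[2]),
                      stats::runif(n, lr$azaheterocycle[1], lr$azaheterocycle[2]))
    base <- predict_pic50(model, tbl[, paste0("FP", 1:9)])
    misfit <- ifelse(tbl$coordinated, stats::rnorm(n, 0, spec$coord_sigma), 0)
    noise <- stats::rnorm(n, 0, spec$noise_sigma)
    tbl$pIC50 <- base + misfit + noise
    attr(tbl, "model") <- model
    attr(tbl, "spec") <- spec
    attr(tbl, "coord_true") <- ifelse(tbl$coordinated, tbl$FP8 + misfit, 0)
    tbl
  })
}

#' Generate a per-atom Fukui table consistent with given dfs values
#'
#' For each coordinated ligand, fabricates a five-membered azaheterocycle's
#' condensed Fukui values such that the ring-wise minimum dual descriptor
#' equals the supplied \code{dfs} (one ring atom attains it; the
#' coordinating nitrogen is ring atom 1 and need not be the minimiser).
#'
#' @param ligand_ids character vector.
#' @param dfs matching smallest-dual-descriptor values.
#' @param seed RNG seed.
#' @return data.frame in the \code{\link{read_fukui_table}} layout.
#' @export
make_fukui_table <- function(ligand_ids, dfs, seed = 1) {
  stopifnot(length(ligand_ids) == length(dfs))
  with_seed(seed, {
    rows <- lapply(seq_along(ligand_ids), function(k) {
      n_ring <- 5L
      duals <- dfs[k] + c(0, sort(stats::runif(n_ring - 1, 0.005, 0.08)))
      duals <- sample(duals)  # the minimiser sits at a random ring position
      f_minus <- stats::runif(n_ring, 0.01, 0.10)
      data.frame(ligand_id = ligand_ids[k],
                 atom_index = seq_len(n_ring),
                 f_plus = f_minus + duals,
                 f_minus = f_minus,
                 in_aza_ring = TRUE,
                 is_coordinating_N = seq_len(n_ring) == 1L)
    })
    do.call(rbind, rows)
  })
}
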