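# Pose clustering, Lennard-Jones steric hindrance S(r), and the
# bioactive-conformation selection score.

#' Built-in element-level Lennard-Jones parameter table
#'
#' A compact AMBER-style nonbonded table keyed by element with
#' Lorentz-Berthelot combination (Rmin/2 values add, well depths combine as
#' the geometric mean).  Atom-typing a full force field is out of scope; in
#' the clash regime (pair energies above ~10 kcal/mol) element-level
#' parameters are an adequate proxy.  A user table with the same columns may
#' be supplied anywhere the default is accepted.
#'
#' @return data.frame with columns \code{type}, \code{eps} (kcal/mol) and
#'   \code{rmin2} (Rmin/2, Angstrom); attribute \code{combination} =
#'   \code{"lorentz_berthelot"}.
#' @export
lj_params_default <- function() {
  structure(
    data.frame(
      type = c("H", "C", "N", "O", "S", "F", "Cl", "Fe"),
      eps = c(0.0157, 0.1094, 0.1700, 0.2100, 0.2500, 0.0610, 0.2650, 0.0130),
      # polar-hydrogen Rmin/2 (0.6) so genuine hydrogen bonds (H...A ~ 2 A)
      # do not register as steric clashes
      rmin2 = c(0.60, 1.908, 1.824, 1.6612, 2.000, 1.75, 1.948, 1.30),
      stringsAsFactors = FALSE
    ),
    combination = "lorentz_berthelot"
  )
}

# Combined (eps_ij, rmin_ij) for two element types.
lj_combine <- function(type_i, type_j, table) {
  ii <- match(type_i, table$type)
  jj <- match(type_j, table$type)
  if (anyNA(ii)) stop("unknown Lennard-Jones type: ", paste(unique(type_i[is.na(ii)]), collapse = ", "))
  if (anyNA(jj)) stop("unknown Lennard-Jones type: ", paste(unique(type_j[is.na(jj)]), collapse = ", "))
  list(eps = sqrt(table$eps[ii] * table$eps[jj]),
       rmin = table$rmin2[ii] + table$rmin2[jj])
}

#' 12-6 Lennard-Jones pair energy
#'
#' \eqn{U(r) = \epsilon_{ij} [ (R_{min}/r)^{12} - 2 (R_{min}/r)^6 ]}: diverges
#' as \eqn{r \to 0}, reaches its minimum \eqn{-\epsilon_{ij}} at the combined
#' minimum-energy distance, and decays to zero at long range.
#'
#' @param r interatomic distance (Angstrom), > 0 (vectorised).
#' @param type_i,type_j element types present in \code{table}.
#' @param table parameter table (see \code{\link{lj_params_default}}).
#' @return energy in kcal/mol.
#' @export
lj_energy <- function(r, type_i, type_j, table = lj_params_default()) {
  stopifnot(all(r > 0))
  p <- lj_combine(type_i, type_j, table)
  sr6 <- (p$rmin / r)^6
  p$eps * (sr6^2 - 2 * sr6)
}

#' Heavy-atom RMSD between two poses of the same ligand
#'
#' Computed in the shared binding-site frame without superposition, over
#' heavy atoms, assuming identical atom ordering.
#'
#' @param a,b \code{ligand_pose} objects with matching atom sequences.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(a, b) {
  heavy_a <- a$atoms$element != "H"
  heavy_b <- b$atoms$element != "H"
  if (sum(heavy_a) != sum(heavy_b))
    stop("atom-count mismatch between poses ", a$pose_id, " and ", b$pose_id)
  xa <- atom_coords(a)[heavy_a, , drop = FALSE]
  xb <- atom_coords(b)[heavy_b, , drop = FALSE]
  sqrt(mean(rowSums((xa - xb)^2)))
}

#' Cluster repeated-docking poses by greedy leader clustering
#'
#' Poses are scanned in input order; each pose joins the first existing
#' cluster whose leader is within \code{rmsd_threshold}, otherwise it opens a
#' new cluster.  Only clusters observed at least \code{min_multiplicity}
#' times are returned as candidates for the bioactive conformation.
#' Deterministic given the input order.
#'
#' @param poses list of \code{ligand_pose} objects sharing atom ordering.
#' @param rmsd_threshold leader RMSD threshold (Angstrom, default 0.5).
#' @param min_multiplicity minimum cluster size to qualify as a candidate
#'   (default 3).
#' @return list of \code{pose_cluster} objects: \code{representative} (the
#'   leader pose), \code{members} (pose ids), \code{multiplicity}.
#' @export
cluster_poses <- function(poses, rmsd_threshold = 0.5, min_multiplicity = 3) {
  leaders <- list()
  members <- list()
  for (p in poses) {
    placed <- FALSE
    for (k in seq_along(leaders)) {
      if (pose_rmsd(leaders[[k]], p) < rmsd_threshold) {
        members[[k]] <- c(members[[k]], p$pose_id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders[[length(leaders) + 1]] <- p
      members[[length(members) + 1]] <- p$pose_id
    }
  }
  clusters <- mapply(function(l, m) {
    structure(list(representative = l, members = m, multiplicity = length(m)),
              class = "pose_cluster")
  }, leaders, members, SIMPLIFY = FALSE)
  Filter(function(cl) cl$multiplicity >= min_multiplicity, clusters)
}

# Site atoms as a flat element/coordinate table for clash scoring.
site_atom_table <- function(site) {
  an <- site$anchors
  rows <- list(
    data.frame(element = "Fe", t(an$heme_iron$position)),
    data.frame(element = "S", t(an$Cys437_S$position)),
    data.frame(element = rep("N", 4), an$heme_N)
  )
  for (nm in c("Ala306_carbonyl_O", "Asp309_COOH", "Thr310_OH", "Met374_amide_NH")) {
    a <- an[[nm]]
    rows[[length(rows) + 1]] <- data.frame(element = a$element %||% "O", t(a$position))
    if (!is.null(a$attached))
      rows[[length(rows) + 1]] <- data.frame(element = a$attached_element %||% "C", t(a$attached))
  }
  hp <- site$hydrophobic_atoms
  rows[[length(rows) + 1]] <- data.frame(element = rep("C", nrow(hp)),
                                         hp[, c("x", "y", "z")])
  out <- do.call(rbind, lapply(rows, function(r) {
    names(r) <- c("element", "x", "y", "z"); r
  }))
  rownames(out) <- NULL
  out
}

#' Steric hindrance of a pose with the binding site
#'
#' Sum of Lennard-Jones pair energies over ligand-atom x site-atom pairs,
#' restricted to remarkable clashes, i.e. pairs with \eqn{U(r) \ge u_{min}}
#' (default 10 kcal/mol).  Zero for a clash-free pose.
#'
#' @param pose a \code{ligand_pose}.
#' @param site a \code{binding_site}.
#' @param table Lennard-Jones table.
#' @param u_min clash inclusion threshold (kcal/mol).
#' @return S >= 0 (kcal/mol).
#' @export
steric_hindrance <- function(pose, site, table = lj_params_default(), u_min = 10) {
  sa <- site_atom_table(site)
  lig_xyz <- atom_coords(pose)
  site_xyz <- as.matrix(sa[, c("x", "y", "z")])
  d2 <- outer(rowSums(lig_xyz^2), rowSums(site_xyz^2), "+") -
    2 * lig_xyz %*% t(site_xyz)
  d <- sqrt(pmax(d2, 1e-12))
  u <- matrix(0, nrow(d), ncol(d))
  for (i in seq_len(nrow(d)))
    u[i, ] <- lj_energy(d[i, ], pose$atoms$element[i], sa$element, table)
  sum(u[u >= u_min])
}

#' Bioactive-conformation selection score
#'
#' Combines the model-estimated potency of a candidate pose with its steric
#' hindrance.  In the default \code{"penalty"} mode the clash term opposes
#' the pose: \eqn{\Delta G = pIC_{50}^{cal} - \log_{10} S} for \eqn{S \ge 1}
#' (no clash term when S < 1).  The \code{"literal"} mode adds the clash
#' term with a positive sign (\eqn{\Delta G = pIC_{50}^{cal} + \log_{10} S}),
#' omitting it when S = 0.  Base-10 logarithms keep the term commensurate
#' with pIC50.
#'
#' @param pIC50_cal model-estimated potency of the pose.
#' @param S steric hindrance (>= 0).
#' @param mode \code{"penalty"} (default) or \code{"literal"}.
#' @return the score Delta G.
#' @export
selection_score <- function(pIC50_cal, S, mode = c("penalty", "literal")) {
  mode <- match.arg(mode)
  stopifnot(S >= 0)
  if (mode == "penalty") {
    if (S >= 1) pIC50_cal - log10(S) else pIC50_cal
  } else {
    if (S > 0) pIC50_cal + log10(S) else pIC50_cal
  }
}

#' Select the bioactive conformation among candidate clusters
#'
#' Featurizes each cluster representative, predicts its potency with the
#' QSAR model, scores it with \code{\link{selection_score}}, and returns the
#' argmax.  Ties are broken by larger multiplicity, then input order.
#'
#' @param clusters list of \code{pose_cluster} (from
#'   \code{\link{cluster_poses}}).
#' @param model a \code{qsar_model}.
#' @param site a \code{binding_site}.
#' @param featurize function(pose) -> interaction fingerprint; defaults to
#'   \code{\link{detect_features}} against \code{site} (FP8/FP9 left zero).
#' @param mode score mode, see \code{\link{selection_score}}.
#' @param table,u_min Lennard-Jones settings for the clash term.
#' @return object of class \code{selection_result}: \code{ligand_id},
#'   \code{pose_id}, \code{delta_G}, \code{pIC50_cal}, \code{S},
#'   \code{candidates} (per-candidate scores).  When \code{clusters} is
#'   empty, a result with \code{pose_id = NA} and a \code{reason} field is
#'   returned rather than an error.
#' @export
select_bioactive <- function(clusters, model, site, featurize = NULL,
                             mode = c("penalty", "literal"),
                             table = lj_params_default(), u_min = 10) {
  mode <- match.arg(mode)
  if (length(clusters) == 0)
    return(structure(list(ligand_id = NA_character_, pose_id = NA_character_,
                          delta_G = NA_real_, pIC50_cal = NA_real_, S = NA_real_,
                          candidates = data.frame(),
                          reason = "no bioactive conformation"),
                     class = "selection_result"))
  if (is.null(featurize))
    featurize <- function(pose) detect_features(pose, site)
  rows <- lapply(clusters, function(cl) {
    pose <- cl$representative
    fp <- featurize(pose)
    p <- predict_pic50(model, fp)
    s <- steric_hindrance(pose, site, table, u_min)
    data.frame(pose_id = pose$pose_id, multiplicity = cl$multiplicity,
               pIC50_cal = p, S = s,
               delta_G = selection_score(p, s, mode))
  })
  cand <- do.call(rbind, rows)
  ord <- order(-cand$delta_G, -cand$multiplicity, seq_len(nrow(cand)))
  best <- ord[1]
  structure(list(ligand_id = clusters[[best]]$representative$ligand_id,
                 pose_id = cand$pose_id[best],
                 delta_G = cand$delta_G[best],
                 pIC50_cal = cand$pIC50_cal[best],
                 S = cand$S[best],
                 candidates = cand, reason = NULL),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (is.na(x$pose_id)) {
    cat("<selection_result: no bioactive conformation>\n")
  } else {
    cat(sprintf("<selection_result %s: pose %s, deltaG %.3f (pIC50_cal %.3f, S %.2f)>\n",
                x$ligand_id, x$pose_id, x$delta_G, x$pIC50_cal, x$S))
  }
  invisible(x)
}
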