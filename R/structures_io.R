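# Reading and writing molecular structures, binding-site models and
# fingerprint tables.

KNOWN_ELEMENTS <- c(
  "H", "B", "C", "N", "O", "F", "Na", "Mg", "Si", "P", "S", "Cl",
  "K", "Ca", "Fe", "Zn", "Se", "Br", "I"
)

ATOM_ROLES <- c(
  "hbond_donor_H", "hbond_acceptor", "aromatic_ring_N", "nitrile_N",
  "keto_or_ether_O", "hydroxyl_O", "nitro_O", "C19_carbon", "C19_oxygen",
  "heavy_attached_to_acceptor"
)

SITE_ANCHOR_NAMES <- c(
  "Ala306_carbonyl_O", "Asp309_COOH", "Thr310_OH", "Met374_amide_NH",
  "heme_iron", "Cys437_S", "heme_N"
)

#' Construct a ligand pose
#'
#' A pose is one docked conformation of a ligand: an ordered atom table with
#' Cartesian coordinates (Angstrom), a bond list, and identifiers.  Atom order
#' must be identical across poses of the same ligand so that pose-pose RMSD
#' can be computed without atom remapping.
#'
#' @param ligand_id,pose_id character identifiers.
#' @param atoms data.frame with columns \code{index}, \code{element},
#'   \code{x}, \code{y}, \code{z}, \code{formal_charge} and a list column
#'   \code{roles} of character vectors of role tags.
#' @param bonds data.frame with integer columns \code{i}, \code{j} (atom
#'   indices) and \code{order} (1, 2, 3, or 4 for aromatic).
#' @param source_run integer docking replicate index.
#' @return an object of class \code{ligand_pose}.
#' @export
ligand_pose <- function(ligand_id, pose_id, atoms, bonds = NULL,
                        source_run = 1L) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1)
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0
  if (is.null(atoms$roles)) atoms$roles <- replicate(nrow(atoms), character(0), simplify = FALSE)
  if (is.null(atoms$index)) atoms$index <- seq_len(nrow(atoms))
  if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("atom coordinates must be finite")
  bad <- !(atoms$element %in% KNOWN_ELEMENTS)
  if (any(bad)) stop("unsupported element(s): ", paste(unique(atoms$element[bad]), collapse = ", "))
  if (nrow(bonds) > 0 && (max(bonds$i, bonds$j) > nrow(atoms) || min(bonds$i, bonds$j) < 1))
    stop("bond indices reference non-existent atoms")
  for (k in seq_len(nrow(atoms))) {
    r <- atoms$roles[[k]]
    if ("C19_oxygen" %in% r && atoms$element[k] != "O")
      stop("atom tagged C19_oxygen must be an oxygen (atom ", k, ")")
    if ("aromatic_ring_N" %in% r && atoms$element[k] != "N")
      stop("atom tagged aromatic_ring_N must be a nitrogen (atom ", k, ")")
  }
  structure(
    list(ligand_id = as.character(ligand_id), pose_id = as.character(pose_id),
         atoms = atoms, bonds = bonds, source_run = as.integer(source_run)),
    class = "ligand_pose"
  )
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose %s/%s: %d atoms, %d bonds, run %d>\n",
              x$ligand_id, x$pose_id, nrow(x$atoms), nrow(x$bonds), x$source_run))
  invisible(x)
}

# Atoms (by index) that are members of a ring: vertices of the 2-core of the
# bond graph.
ring_atom_indices <- function(pose) {
  if (nrow(pose$bonds) == 0) return(integer(0))
  g <- igraph::graph_from_data_frame(
    pose$bonds[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(pose$atoms)))
  )
  core <- igraph::coreness(g)
  as.integer(names(core)[core >= 2])
}

#' Assign interaction role tags from connectivity
#'
#' Substructure-based tagging: donor hydrogens are H bonded to N or O;
#' nitrile N is the nitrogen of a C-triple-bond-N group; aromatic ring N is a
#' ring nitrogen with an aromatic (order 4) bond, or a two-connected ring
#' nitrogen without attached hydrogen (pyridine-type); keto/ether O is a
#' carbonyl oxygen or an oxygen bridging two carbons; nitro O belongs to an
#' N(O)O group; hydroxyl O is a singly-connected oxygen on carbon (explicit
#' or implicit H).  C19 identity is a steroid-numbering convention and cannot
#' be derived from connectivity; supply it via \code{c19_carbon} /
#' \code{c19_oxygen}.
#'
#' @param pose a \code{ligand_pose}.
#' @param c19_carbon,c19_oxygen optional atom indices annotating the C19
#'   carbon and a 19-hydroxyl/19-keto oxygen.
#' @return the pose with its \code{roles} column replaced.
#' @export
assign_atom_roles <- function(pose, c19_carbon = NULL, c19_oxygen = NULL) {
  el <- pose$atoms$element
  n <- nrow(pose$atoms)
  b <- pose$bonds
  deg <- integer(n)
  if (nrow(b) > 0) {
    tab <- table(factor(c(b$i, b$j), levels = seq_len(n)))
    deg <- as.integer(tab)
  }
  nb_list <- lapply(seq_len(n), function(i) c(b$j[b$i == i], b$i[b$j == i]))
  ord_to <- function(i, j) {
    o <- b$order[(b$i == i & b$j == j) | (b$i == j & b$j == i)]
    if (length(o)) o[1] else 0L
  }
  ring <- ring_atom_indices(pose)
  roles <- replicate(n, character(0), simplify = FALSE)
  add <- function(i, tag) roles[[i]] <<- union(roles[[i]], tag)

  for (i in seq_len(n)) {
    nbs <- nb_list[[i]]
    heavy_nbs <- nbs[el[nbs] != "H"]
    h_nbs <- nbs[el[nbs] == "H"]
    if (el[i] == "H" && length(nbs) >= 1 && any(el[nbs] %in% c("N", "O")))
      add(i, "hbond_donor_H")
    if (el[i] == "N") {
      if (deg[i] == 1 && length(heavy_nbs) == 1 && el[heavy_nbs] == "C" &&
          ord_to(i, heavy_nbs) == 3)
        add(i, "nitrile_N")
      is_nitro_n <- sum(el[heavy_nbs] == "O") >= 2
      if (i %in% ring) {
        arom_bond <- any(vapply(nbs, function(j) ord_to(i, j) == 4L, logical(1)))
        if (arom_bond || (deg[i] == 2 && length(h_nbs) == 0))
          add(i, "aromatic_ring_N")
      }
      if (!is_nitro_n && deg[i] <= 3) add(i, "hbond_acceptor")
    }
    if (el[i] == "O") {
      add(i, "hbond_acceptor")
      n_nb <- heavy_nbs[el[heavy_nbs] == "N"]
      is_nitro <- length(n_nb) >= 1 &&
        any(vapply(n_nb, function(j) {
          onbs <- nb_list[[j]]
          sum(el[onbs] == "O") >= 2
        }, logical(1)))
      if (is_nitro) {
        add(i, "nitro_O")
      } else {
        c_nbs <- heavy_nbs[el[heavy_nbs] == "C"]
        dbl_c <- any(vapply(c_nbs, function(j) ord_to(i, j) == 2L, logical(1)))
        if (dbl_c || length(c_nbs) == 2) add(i, "keto_or_ether_O")
        if (length(c_nbs) == 1 && !dbl_c &&
            (length(h_nbs) >= 1 || deg[i] == 1))
          add(i, "hydroxyl_O")
      }
    }
  }
  if (!is.null(c19_carbon)) {
    if (any(c19_carbon < 1 | c19_carbon > n))
      stop("c19_carbon annotation out of range for ligand ", pose$ligand_id)
    for (i in c19_carbon) add(i, "C19_carbon")
  }
  if (!is.null(c19_oxygen)) {
    if (any(c19_oxygen < 1 | c19_oxygen > n))
      stop("c19_oxygen annotation out of range for ligand ", pose$ligand_id)
    for (i in c19_oxygen) {
      if (el[i] != "O") stop("c19_oxygen annotation names a non-oxygen atom (", i, ")")
      add(i, "C19_oxygen")
    }
  }
  pose$atoms$roles <- roles
  pose
}

#' Read ligand poses from a structure file
#'
#' SDF files are parsed with \pkg{ChemmineR}; MOL2 and PDB with \pkg{bio3d}.
#' Role tags are assigned from connectivity (see
#' \code{\link{assign_atom_roles}}).  PDB input carries no bond block, so
#' bonds are inferred from interatomic distances against covalent radii.
#'
#' @param path file path.
#' @param format one of \code{"sdf"}, \code{"mol2"}, \code{"pdb"}; guessed
#'   from the extension by default.
#' @param c19_carbon,c19_oxygen optional named lists mapping ligand_id to
#'   annotated atom indices (steroid numbering is a convention, not
#'   connectivity-derivable).
#' @return list of \code{ligand_pose} objects (empty, with a warning, for an
#'   empty file).
#' @export
read_poses <- function(path, format = c("auto", "sdf", "mol2", "pdb"),
                       c19_carbon = NULL, c19_oxygen = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("sdf", "mol2", "pdb"))
    stop("unsupported structure format: ", format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size == 0 ||
      all(!nzchar(trimws(readLines(path, warn = FALSE))))) {
    warning("empty structure file: ", path)
    return(list())
  }
  poses <- switch(format,
    sdf = read_poses_sdf(path),
    mol2 = read_poses_mol2(path),
    pdb = read_poses_pdb(path)
  )
  lapply(poses, function(p) {
    assign_atom_roles(p,
      c19_carbon = c19_carbon[[p$ligand_id]],
      c19_oxygen = c19_oxygen[[p$ligand_id]])
  })
}

read_poses_sdf <- function(path) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop("failed to parse SDF record: ", conditionMessage(e))
  )
  out <- vector("list", length(sdfset))
  for (k in seq_along(sdfset)) {
    sdf <- tryCatch(sdfset[[k]], error = function(e)
      stop("unparseable SDF record at index ", k, ": ", conditionMessage(e)))
    ab <- ChemmineR::atomblock(sdf)
    if (is.null(dim(ab)) || nrow(ab) == 0)
      stop("unparseable SDF record at index ", k, ": empty atom block")
    el <- sub("_.*$", "", rownames(ab))
    atoms <- data.frame(
      index = seq_len(nrow(ab)), element = el,
      x = ab[, 1], y = ab[, 2], z = ab[, 3],
      formal_charge = 0, stringsAsFactors = FALSE
    )
    rownames(atoms) <- NULL
    bb <- ChemmineR::bondblock(sdf)
    bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) NULL else
      data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                 order = as.integer(bb[, 3]))
    hdr <- ChemmineR::header(sdf)
    db <- ChemmineR::datablock(sdf)
    lig <- unname(hdr["Molecule_Name"])
    if (is.na(lig) || !nzchar(lig)) lig <- paste0("mol", k)
    pid <- if ("pose_id" %in% names(db)) unname(db["pose_id"]) else paste0(lig, "_p1")
    run <- if ("source_run" %in% names(db)) as.integer(db["source_run"]) else 1L
    out[[k]] <- ligand_pose(lig, pid, atoms, bonds, run)
  }
  out
}

read_poses_mol2 <- function(path) {
  m <- bio3d::read.mol2(path)
  if (inherits(m, "mol2")) m <- list(m)
  lapply(seq_along(m), function(k) {
    mm <- m[[k]]
    at <- mm$atom
    el <- sub("\\..*$", "", at$atom.type)
    atoms <- data.frame(
      index = seq_len(nrow(at)), element = el,
      x = at$x, y = at$y, z = at$z,
      formal_charge = if (!is.null(at$charge)) at$charge else 0,
      stringsAsFactors = FALSE
    )
    bonds <- NULL
    if (!is.null(mm$bond) && nrow(mm$bond) > 0) {
      ord <- mm$bond$type
      ord[ord == "ar"] <- "4"
      ord[ord == "am"] <- "1"
      bonds <- data.frame(i = as.integer(mm$bond$origin),
                          j = as.integer(mm$bond$target),
                          order = as.integer(ord))
    }
    lig <- if (!is.null(mm$name) && nzchar(mm$name[1])) mm$name[1] else paste0("mol", k)
    ligand_pose(lig, paste0(lig, "_p1"), atoms, bonds)
  })
}

COVALENT_RADII <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
                    Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Fe = 1.32,
                    Zn = 1.22, Se = 1.20, Br = 1.20, I = 1.39)

# Distance-based bond perception for formats without a bond block.
infer_bonds <- function(atoms, tol = 1.25) {
  n <- nrow(atoms)
  if (n < 2) return(data.frame(i = integer(0), j = integer(0), order = integer(0)))
  r <- COVALENT_RADII[atoms$element]
  r[is.na(r)] <- 0.77
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  pairs <- which(upper.tri(d) & d < tol * outer(r, r, "+"), arr.ind = TRUE)
  data.frame(i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
             order = rep(1L, nrow(pairs)))
}

read_poses_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  el <- at$elesy
  if (is.null(el) || all(!nzchar(el))) el <- substr(trimws(at$elety), 1, 1)
  el <- trimws(el)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 10)))
  atoms <- data.frame(index = seq_len(nrow(at)), element = el,
                      x = at$x, y = at$y, z = at$z, formal_charge = 0,
                      stringsAsFactors = FALSE)
  lig <- if (length(unique(at$resid))) unique(at$resid)[1] else "PDBLIG"
  list(ligand_pose(lig, paste0(lig, "_p1"), atoms, infer_bonds(atoms)))
}

#' Construct a binding-site anchor model
#'
#' The model holds the six hydrogen-bond/heme anchor features plus the heme
#' nitrogens, the hydrophobic pocket atoms, a convex access-channel region,
#' and the fixed formal charges (iron +3.0, each heme N -0.5, Cys437 S -1.0).
#'
#' @param anchors named list; entries \code{Ala306_carbonyl_O},
#'   \code{Asp309_COOH}, \code{Thr310_OH}, \code{Met374_amide_NH},
#'   \code{Cys437_S} each a list with \code{position} and \code{attached}
#'   3-vectors and a \code{role} ("donor" or "acceptor"); \code{heme_iron}
#'   a list with \code{position}; \code{heme_N} a 4 x 3 matrix.
#' @param hydrophobic_atoms data.frame with \code{x}, \code{y}, \code{z},
#'   \code{residue}.
#' @param access_channel list with \code{ref} (3-vector), \code{direction}
#'   (3-vector) and \code{radius} (Angstrom).
#' @return object of class \code{binding_site}.
#' @export
binding_site <- function(anchors, hydrophobic_atoms, access_channel) {
  missing <- setdiff(SITE_ANCHOR_NAMES, names(anchors))
  if (length(missing))
    stop("missing anchor: ", paste(missing, collapse = ", "))
  hn <- anchors$heme_N
  if (is.null(dim(hn)) || nrow(as.matrix(hn)) != 4)
    stop("heme_N must provide four nitrogen positions")
  anchors$heme_N <- matrix(as.numeric(as.matrix(hn)), nrow = 4)
  for (nm in setdiff(SITE_ANCHOR_NAMES, "heme_N")) {
    anchors[[nm]]$position <- as.numeric(anchors[[nm]]$position)
    if (!is.null(anchors[[nm]]$attached))
      anchors[[nm]]$attached <- as.numeric(anchors[[nm]]$attached)
  }
  stopifnot(is.data.frame(hydrophobic_atoms),
            all(c("x", "y", "z", "residue") %in% names(hydrophobic_atoms)))
  access_channel$ref <- as.numeric(access_channel$ref)
  access_channel$direction <- vunit(as.numeric(access_channel$direction))
  stopifnot(access_channel$radius > 0)
  structure(
    list(anchors = anchors, hydrophobic_atoms = hydrophobic_atoms,
         access_channel = access_channel,
         charges = list(heme_iron = 3.0, heme_N = -0.5, Cys437_S = -1.0)),
    class = "binding_site"
  )
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("<binding_site: %d anchors, %d hydrophobic atoms>\n",
              length(x$anchors), nrow(x$hydrophobic_atoms)))
  invisible(x)
}

#' Build a binding-site model from a JSON anchor file or a protein PDB
#'
#' The JSON anchor file is the canonical portable format; PDB extraction is a
#' convenience built on top of it (waters and non-heme ligands are removed,
#' anchor atoms are pulled from the named residues, and missing polar
#' hydrogens are placed at idealised positions along the donor heavy-atom
#' directions).
#'
#' @param source path to a \code{.json} anchor file or a \code{.pdb} file.
#' @return a \code{binding_site}.
#' @export
build_site_model <- function(source) {
  ext <- tolower(tools::file_ext(source))
  if (ext == "json") build_site_from_json(source)
  else if (ext == "pdb") build_site_from_pdb(source)
  else stop("unsupported site source (need .json or .pdb): ", source)
}

build_site_from_json <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(j$anchors)) stop("anchor file lacks an 'anchors' entry")
  missing <- setdiff(SITE_ANCHOR_NAMES, names(j$anchors))
  if (length(missing)) stop("missing anchor: ", paste(missing, collapse = ", "))
  hp <- as.data.frame(j$hydrophobic_atoms)
  binding_site(j$anchors, hp, j$access_channel)
}

#' Write a binding-site model to a JSON anchor file
#' @param site a \code{binding_site}.
#' @param path output path.
#' @export
write_site_model <- function(site, path) {
  jsonlite::write_json(
    list(anchors = site$anchors,
         hydrophobic_atoms = site$hydrophobic_atoms,
         access_channel = site$access_channel),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

HYDROPHOBIC_RESIDUES <- c("ILE133", "PHE134", "PHE221", "TRP224", "VAL369",
                          "VAL370", "LEU477", "SER478")

build_site_from_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), ]
  key <- paste0(at$resid, at$resno)
  pick <- function(res, atom_name) {
    row <- at[key == res & trimws(at$elety) == atom_name, , drop = FALSE]
    if (nrow(row) == 0) return(NULL)
    as.numeric(row[1, c("x", "y", "z")])
  }
  need <- list(
    Ala306_O = c("ALA306", "O"), Ala306_C = c("ALA306", "C"),
    Asp309_OD2 = c("ASP309", "OD2"), Asp309_CG = c("ASP309", "CG"),
    Thr310_OG1 = c("THR310", "OG1"), Thr310_CB = c("THR310", "CB"),
    Met374_N = c("MET374", "N"), Met374_CA = c("MET374", "CA"),
    Fe = c("HEM600", "FE"), Cys437_SG = c("CYS437", "SG"), Cys437_CB = c("CYS437", "CB")
  )
  got <- lapply(need, function(sp) pick(sp[1], sp[2]))
  # heme iron may sit on any residue number; fall back to element search
  if (is.null(got$Fe)) {
    fe_row <- at[trimws(at$elety) == "FE" | trimws(at$elesy) == "FE", , drop = FALSE]
    if (nrow(fe_row)) got$Fe <- as.numeric(fe_row[1, c("x", "y", "z")])
  }
  hemeN <- at[at$resid == "HEM" & trimws(at$elety) %in% c("NA", "NB", "NC", "ND"), , drop = FALSE]
  missing <- c(
    names(got)[vapply(got, is.null, logical(1))],
    if (nrow(hemeN) < 4) "heme_N"
  )
  if (length(missing)) stop("missing anchor: ", paste(missing, collapse = ", "))
  place_h <- function(heavy, back, len = 1.0) heavy + len * vunit(heavy - back)
  fe <- got$Fe
  anchors <- list(
    Ala306_carbonyl_O = list(position = got$Ala306_O, attached = got$Ala306_C,
                             role = "acceptor", element = "O", attached_element = "C"),
    Asp309_COOH = list(position = place_h(got$Asp309_OD2, got$Asp309_CG, 0.96),
                       attached = got$Asp309_OD2, role = "donor",
                       element = "H", attached_element = "O"),
    Thr310_OH = list(position = place_h(got$Thr310_OG1, got$Thr310_CB, 0.96),
                     attached = got$Thr310_OG1, role = "donor",
                     element = "H", attached_element = "O"),
    Met374_amide_NH = list(position = place_h(got$Met374_N, got$Met374_CA, 1.01),
                           attached = got$Met374_N, role = "donor",
                           element = "H", attached_element = "N"),
    heme_iron = list(position = fe, role = "iron", element = "Fe"),
    Cys437_S = list(position = got$Cys437_SG, attached = got$Cys437_CB,
                    role = "donor", element = "S", attached_element = "C"),
    heme_N = as.matrix(hemeN[, c("x", "y", "z")])
  )
  hp <- at[key %in% HYDROPHOBIC_RESIDUES &
             !(trimws(at$elety) %in% c("N", "C", "O", "CA")) &
             substr(trimws(at$elety), 1, 1) == "C", , drop = FALSE]
  if (nrow(hp) == 0) stop("no hydrophobic pocket atoms found in PDB source")
  hydrophobic <- data.frame(x = hp$x, y = hp$y, z = hp$z,
                            residue = paste0(hp$resid, hp$resno))
  # channel: flank anchored near Phe221/Thr310, pointing away from the iron
  ref_atoms <- hydrophobic[grepl("PHE221", hydrophobic$residue), c("x", "y", "z")]
  ref <- if (nrow(ref_atoms)) colMeans(ref_atoms) else colMeans(hydrophobic[, c("x", "y", "z")])
  channel <- list(ref = as.numeric(ref),
                  direction = vunit(as.numeric(ref) - fe), radius = 2.5)
  binding_site(anchors, hydrophobic, channel)
}

#' Write / read a fingerprint-activity table
#'
#' One row per ligand: \code{ligand_id}, \code{FP1}..\code{FP9},
#' \code{pIC50}.  Values round-trip losslessly (to 1e-9) through
#' \code{read_fingerprint_table}.
#'
#' @param records data.frame with columns \code{ligand_id}, \code{FP1..FP9},
#'   \code{pIC50}, or a list of \code{list(ligand_id=, fp=, pIC50=)} entries.
#' @param path output CSV path.
#' @export
write_fingerprint_table <- function(records, path) {
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      fp <- as.numeric(r$fp[paste0("FP", 1:9)])
      out <- data.frame(ligand_id = r$ligand_id)
      out[paste0("FP", 1:9)] <- as.list(fp)
      out$pIC50 <- r$pIC50
      out
    }))
  }
  cols <- c("ligand_id", paste0("FP", 1:9), "pIC50")
  stopifnot(all(cols %in% names(records)))
  out <- records[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) formatC(v, digits = 12, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fingerprint_table
#' @export
read_fingerprint_table <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("ligand_id", paste0("FP", 1:9), "pIC50") %in% names(tbl)))
  tbl
}

#' Write ligand poses to an SDF file
#'
#' @param poses list of \code{ligand_pose} objects.
#' @param path output path.
#' @export
write_poses_sdf <- function(poses, path) {
  if (inherits(poses, "ligand_pose")) poses <- list(poses)
  sdfs <- lapply(poses, function(p) {
    n <- nrow(p$atoms)
    ab <- cbind(as.matrix(p$atoms[, c("x", "y", "z")]), matrix(0, n, 13))
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:17))
    rownames(ab) <- paste(p$atoms$element, seq_len(n), sep = "_")
    nb <- nrow(p$bonds)
    bb <- cbind(as.matrix(p$bonds[, c("i", "j", "order")]), matrix(0, nb, 4))
    colnames(bb) <- paste0("C", 1:7)
    rownames(bb) <- as.character(seq_len(max(nb, 0)))
    counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
    methods::new(methods::getClass("SDF", where = asNamespace("ChemmineR")),
      header = c(Molecule_Name = p$ligand_id, Source = "aromprofile",
                 Comment = "", Counts_Line = counts),
      atomblock = ab, bondblock = bb,
      datablock = c(pose_id = p$pose_id, source_run = as.character(p$source_run)))
  })
  sdfset <- methods::new(methods::getClass("SDFset", where = asNamespace("ChemmineR")), ID = vapply(poses, function(p) p$pose_id, character(1)),
                         SDF = sdfs)
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}
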