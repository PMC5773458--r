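# Structure and table I/O: pose parsing, role tagging, site models,
# fingerprint tables.

test_that("SDF reading preserves atom counts, order and identity", {
  site <- toy_site()
  poses <- lapply(1:3, function(k)
    make_pose_with_features(site, c(FP4 = "on"), seed = k,
                            ligand_id = sprintf("lig%d", k)))
  path <- tempfile(fileext = ".sdf")
  write_poses_sdf(poses, path)
  back <- read_poses(path, "sdf")
  expect_length(back, 3)
  expect_equal(nrow(back[[1]]$atoms), nrow(poses[[1]]$atoms))
  expect_equal(back[[2]]$ligand_id, "lig2")
  expect_equal(back[[1]]$atoms$element, poses[[1]]$atoms$element)
  # reading the same file twice yields identical atom sequences
  again <- read_poses(path, "sdf")
  expect_identical(back[[1]]$atoms[, c("element", "x", "y", "z")],
                   again[[1]]$atoms[, c("element", "x", "y", "z")])
})

test_that("substructure tagging identifies a nitrile and donor hydrogens", {
  path <- write_nitrile_sdf(tempfile(fileext = ".sdf"))
  poses <- read_poses(path, "sdf")
  expect_length(poses, 1)
  p <- poses[[1]]
  nitrile <- which(vapply(p$atoms$roles, function(r) "nitrile_N" %in% r, logical(1)))
  expect_equal(p$atoms$element[nitrile], "N")
  expect_length(nitrile, 1)
  # carbons are not acceptors; the nitrile N is
  expect_true("hbond_acceptor" %in% p$atoms$roles[[nitrile]])
})

test_that("tagging covers keto, hydroxyl, nitro, aromatic-ring and C19 roles", {
  # acetone-like: C-C(=O)-C, plus C-OH, plus nitro N(O)(O), plus a
  # pyridine-like aromatic ring nitrogen
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.2, 1.2, 0),     # C C O(keto)
               c(4, 0, 0), c(4.8, 1.1, 0), c(5.4, 1.5, 0.5), # C O(H) H
               c(7, 0, 0), c(7.8, 1, 0), c(7.8, -1, 0),      # N O O (nitro)
               c(10, 0, 0), c(11.4, 0, 0), c(12.1, 1.2, 0),  # ring C C N
               c(11.4, 2.4, 0), c(10, 2.4, 0), c(9.3, 1.2, 0))
  el <- c("C", "C", "O", "C", "O", "H", "N", "O", "O", "C", "C", "N", "C", "C", "C")
  bonds <- data.frame(
    i = c(1, 2, 4, 5, 7, 7, 10, 11, 12, 13, 14, 15, 7),
    j = c(2, 3, 5, 6, 8, 9, 11, 12, 13, 14, 15, 10, 4),
    order = c(1, 2, 1, 1, 2, 1, 4, 4, 4, 4, 4, 4, 1)
  )
  p <- assign_atom_roles(raw_pose(xyz, el, bonds = bonds), c19_carbon = 1)
  role_of <- function(i) p$atoms$roles[[i]]
  expect_true("keto_or_ether_O" %in% role_of(3))
  expect_true("hydroxyl_O" %in% role_of(5))
  expect_true("hbond_donor_H" %in% role_of(6))
  expect_true(all(c("nitro_O") %in% role_of(8)))
  expect_true("nitro_O" %in% role_of(9))
  expect_true("aromatic_ring_N" %in% role_of(12))
  expect_true("C19_carbon" %in% role_of(1))
  expect_error(assign_atom_roles(p, c19_oxygen = 99), "out of range")
})

test_that("an empty structure file yields an empty pose list with a warning", {
  path <- tempfile(fileext = ".sdf")
  writeLines("", path)
  expect_warning(poses <- read_poses(path, "sdf"), "empty")
  expect_length(poses, 0)
})

test_that("unsupported elements are rejected", {
  expect_error(
    raw_pose(rbind(c(0, 0, 0)), "Xx"),
    "unsupported element"
  )
})

test_that("site model JSON round-trips and missing anchors are named", {
  site <- toy_site()
  path <- tempfile(fileext = ".json")
  write_site_model(site, path)
  back <- build_site_model(path)
  expect_s3_class(back, "binding_site")
  expect_equal(back$anchors$heme_iron$position, site$anchors$heme_iron$position)
  expect_equal(back$charges, site$charges)
  # drop the iron and expect a named error
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  j$anchors$heme_iron <- NULL
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(j, path2, auto_unbox = TRUE, digits = NA)
  expect_error(build_site_model(path2), "missing anchor: heme_iron")
})

test_that("site extraction from a toy PDB finds anchors and pocket atoms", {
  # synthetic PDB fixture: backbone/side-chain atoms of the named residues
  # around a heme group (coordinates schematic, not crystallographic)
  fmt <- function(serial, name, res, resno, x, y, z, el)
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, res, resno, x, y, z, el)
  lines <- c(
    fmt(1, "O", "ALA", 306, -3.2, 1.6, 7.0, "O"),
    fmt(2, "C", "ALA", 306, -4.2, 1.8, 7.6, "C"),
    fmt(3, "OD2", "ASP", 309, -1.8, -3.4, 6.4, "O"),
    fmt(4, "CG", "ASP", 309, -2.4, -4.5, 6.9, "C"),
    fmt(5, "OG1", "THR", 310, 2.8, -2.4, 6.8, "O"),
    fmt(6, "CB", "THR", 310, 3.6, -3.3, 7.3, "C"),
    fmt(7, "N", "MET", 374, 3.4, 1.8, 7.2, "N"),
    fmt(8, "CA", "MET", 374, 4.3, 2.5, 7.9, "C"),
    fmt(9, "SG", "CYS", 437, 0.0, 0.0, -2.3, "S"),
    fmt(10, "CB", "CYS", 437, 0.0, 1.0, -3.4, "C"),
    fmt(11, "CD1", "ILE", 133, 5.0, 1.0, 4.5, "C"),
    fmt(12, "CZ", "PHE", 134, -4.8, 2.0, 5.0, "C"),
    fmt(13, "CZ", "PHE", 221, 4.0, -3.0, 5.5, "C"),
    fmt(14, "CH2", "TRP", 224, -3.5, -4.0, 5.0, "C"),
    fmt(15, "CG1", "VAL", 370, 0.5, 5.2, 4.8, "C"),
    fmt(16, "CD1", "LEU", 477, 1.0, -5.2, 6.0, "C"),
    fmt(17, "CG2", "VAL", 369, 5.2, 2.5, 6.2, "C"),
    fmt(18, "O", "HOH", 900, 0, 0, 20, "O"),
    "HETATM   19 FE   HEM A 600       0.000   0.000   0.000          FE",
    "HETATM   20 NA   HEM A 600       2.000   0.000   0.000           N",
    "HETATM   21 NB   HEM A 600      -2.000   0.000   0.000           N",
    "HETATM   22 NC   HEM A 600       0.000   2.000   0.000           N",
    "HETATM   23 ND   HEM A 600       0.000  -2.000   0.000           N",
    "END"
  )
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  site <- build_site_model(path)
  expect_s3_class(site, "binding_site")
  expect_gte(nrow(site$hydrophobic_atoms), 6)
  expect_equal(site$anchors$heme_iron$position, c(0, 0, 0))
  # donor H placed ~1 Angstrom from the Met374 N, away from CA
  h <- site$anchors$Met374_amide_NH$position
  expect_equal(sqrt(sum((h - c(3.4, 1.8, 7.2))^2)), 1.01, tolerance = 1e-6)
})

test_that("fingerprint tables round-trip losslessly", {
  fp <- c(FP1 = 1, FP2 = 0, FP3 = 1, FP4 = 0, FP5 = 0, FP6 = 0, FP7 = 1,
          FP8 = 4.5678912345, FP9 = 1.23456789)
  recs <- list(
    list(ligand_id = "a", fp = fp, pIC50 = 6.125),
    list(ligand_id = "b", fp = fp * 0, pIC50 = 0.755),
    list(ligand_id = "c", fp = fp / 3, pIC50 = 4.5)
  )
  path <- tempfile(fileext = ".csv")
  write_fingerprint_table(recs, path)
  expect_length(readLines(path), 4)  # header + 3 rows
  back <- read_fingerprint_table(path)
  expect_equal(back$FP8[1], 4.5678912345, tolerance = 1e-9)
  expect_equal(back$FP9[3], 1.23456789 / 3, tolerance = 1e-9)
  expect_equal(back$pIC50, c(6.125, 0.755, 4.5), tolerance = 1e-9)
})

test_that("pose invariants are enforced", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0))
  expect_error(
    raw_pose(xyz, c("C", "C"),
             roles = list(character(0), "C19_oxygen")),
    "must be an oxygen"
  )
  expect_error(
    ligand_pose("x", "p", data.frame(index = 1, element = "C",
                                     x = 0, y = 0, z = 0, formal_charge = 0),
                bonds = data.frame(i = 1, j = 5, order = 1)),
    "non-existent"
  )
})
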