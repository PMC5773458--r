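# Shared fixtures and independent oracles, built in code at test time.

toy_site <- function() make_toy_site(seed = 1)

# Minimal pose from raw coordinates; roles optional.
raw_pose <- function(xyz, elements, roles = NULL, bonds = NULL,
                     ligand_id = "fix", pose_id = "fix_p1") {
  atoms <- data.frame(index = seq_len(nrow(xyz)), element = elements,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      formal_charge = 0)
  if (!is.null(roles)) atoms$roles <- roles
  ligand_pose(ligand_id, pose_id, atoms, bonds)
}

# Branch-by-branch oracle for the block function, independent of the
# package's vectorised arithmetic.
block_oracle <- function(x, x_ideal, x_max) {
  vapply(x, function(xi) {
    if (xi <= x_ideal) return(1)
    if (xi > x_max) return(0)
    1 - (xi - x_ideal) / (x_max - x_ideal)
  }, numeric(1))
}

# Brute-force steric hindrance: explicit double loop over every
# ligand-atom x site-atom pair.
steric_oracle <- function(pose, site, table = lj_params_default(), u_min = 10) {
  sa <- aromprofile:::site_atom_table(site)
  total <- 0
  for (i in seq_len(nrow(pose$atoms))) {
    for (j in seq_len(nrow(sa))) {
      r <- sqrt(sum((c(pose$atoms$x[i], pose$atoms$y[i], pose$atoms$z[i]) -
                       c(sa$x[j], sa$y[j], sa$z[j]))^2))
      u <- lj_energy(r, pose$atoms$element[i], sa$element[j], table)
      if (u >= u_min) total <- total + u
    }
  }
  total
}

# Rigid motion (random rotation + translation) applied jointly to a pose
# and a site model; delta_R must be invariant under it.
random_rigid_motion <- function(seed) {
  set.seed(seed)
  ang <- runif(3, 0, 2 * pi)
  rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  list(R = rx %*% ry %*% rz, t = runif(3, -5, 5))
}

apply_motion_pose <- function(pose, m) {
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")]) %*% t(m$R)
  pose$atoms$x <- xyz[, 1] + m$t[1]
  pose$atoms$y <- xyz[, 2] + m$t[2]
  pose$atoms$z <- xyz[, 3] + m$t[3]
  pose
}

apply_motion_site <- function(site, m) {
  mv <- function(p) as.numeric(m$R %*% p + m$t)
  for (nm in setdiff(names(site$anchors), "heme_N")) {
    site$anchors[[nm]]$position <- mv(site$anchors[[nm]]$position)
    if (!is.null(site$anchors[[nm]]$attached))
      site$anchors[[nm]]$attached <- mv(site$anchors[[nm]]$attached)
  }
  site$anchors$heme_N <- t(apply(site$anchors$heme_N, 1, mv))
  xyz <- as.matrix(site$hydrophobic_atoms[, c("x", "y", "z")]) %*% t(m$R)
  site$hydrophobic_atoms$x <- xyz[, 1] + m$t[1]
  site$hydrophobic_atoms$y <- xyz[, 2] + m$t[2]
  site$hydrophobic_atoms$z <- xyz[, 3] + m$t[3]
  site$access_channel$ref <- mv(site$access_channel$ref)
  site$access_channel$direction <- as.numeric(m$R %*% site$access_channel$direction)
  site
}

# A hand-written acetonitrile-like SDF (CH3-C#N with explicit hydrogens).
write_nitrile_sdf <- function(path) {
  lines <- c(
    "acetonitrile", "  test", "",
    "  6  5  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4600    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.6200    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.3600    1.0200    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.3600   -0.5100    0.8800 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.3600   -0.5100   -0.8800 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "  2  3  3  0  0  0  0",
    "  1  4  1  0  0  0  0",
    "  1  5  1  0  0  0  0",
    "  1  6  1  0  0  0  0",
    "M  END",
    "$$$$"
  )
  writeLines(lines, path)
  path
}
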