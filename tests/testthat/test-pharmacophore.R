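# Block-function scoring, fingerprint bits and the feature detector.

test_that("block matches the branch-by-branch oracle on a dense grid", {
  presets <- default_block_presets()
  for (p in presets) {
    for (spec in list(c(p$dr_ideal, p$dr_max), c(p$da_ideal, p$da_max),
                      c(p$db_ideal, p$db_max))) {
      x <- seq(0, spec[2] * 1.5, length.out = 1000)
      expect_equal(block(x, spec[1], spec[2]), block_oracle(x, spec[1], spec[2]))
    }
  }
  # bounded, non-increasing, continuous at the knots
  x <- seq(0, 1, length.out = 1000)
  v <- block(x, 0.5, 0.65)
  expect_true(all(v >= 0 & v <= 1))
  expect_true(all(diff(v) <= 1e-12))
  expect_equal(block(0.5, 0.5, 0.65), 1)
  expect_equal(block(0.65, 0.5, 0.65), 0, tolerance = 1e-12)
  expect_error(block(-0.1, 0.5, 0.65), "non-negative")
  expect_error(block(0.1, 0.7, 0.65), "x_ideal < x_max")
})

test_that("block evaluates its three regimes as specified", {
  expect_equal(block(0.30, 0.50, 0.65), 1.0)
  expect_equal(block(0.575, 0.50, 0.65), 0.5)
  expect_equal(block(0.70, 0.50, 0.65), 0.0)
})

test_that("Table-1 presets carry the published parameter values", {
  hb <- block_params("hydrogen_bond")
  expect_equal(unlist(unclass(hb)), c(r_ideal = 2.00, dr_ideal = 0.50,
    dr_max = 0.65, alpha_ideal = 180, da_ideal = 45, da_max = 80,
    beta_ideal = 180, db_ideal = 80, db_max = 100))
  ox <- block_params("heme_c19_oxygen")
  expect_equal(c(ox$r_ideal, ox$dr_ideal, ox$da_ideal, ox$da_max,
                 ox$db_ideal), c(2.40, 0.25, 10, 40, 80))
  az <- block_params("heme_azaheterocycle")
  expect_equal(c(az$r_ideal, az$dr_ideal, az$da_ideal, az$da_max,
                 az$db_ideal), c(2.25, 0.25, 20, 40, 60))
})

test_that("delta_R multiplies the three block terms", {
  hb <- block_params("hydrogen_bond")
  expect_equal(delta_R(interaction_geometry(2.00, 180, 180), hb), 1.0)
  expect_equal(delta_R(interaction_geometry(2.575, 180, 180), hb), 0.5)
  expect_equal(delta_R(interaction_geometry(2.00, 90, 180), hb), 0.0)
  # all three terms engaged: hand product of oracle blocks
  g <- interaction_geometry(2.575, 120, 90)
  expect_equal(delta_R(g, hb),
               block_oracle(0.575, 0.5, 0.65) *
                 block_oracle(60, 45, 80) *
                 block_oracle(90, 80, 100))
})

test_that("bit thresholds sit exactly at the published boundaries", {
  expect_equal(feature_bit(0.6), 1L)     # inclusive
  expect_equal(feature_bit(0.599), 0L)
  expect_equal(feature_bit(1.0), 1L)
  expect_equal(c19_iron_bit(4.29), 1L)   # strict
  expect_equal(c19_iron_bit(4.30), 0L)
  expect_equal(c19_iron_bit(2.0), 1L)
})

test_that("delta_R is invariant under a joint rigid motion of pose and site", {
  site <- toy_site()
  pose <- make_pose_with_features(site, c(FP4 = "marginal", FP2 = "on"), seed = 6)
  fp0 <- detect_features(pose, site)
  d0 <- attr(fp0, "delta_R")
  for (s in 1:5) {
    m <- random_rigid_motion(s)
    fp1 <- detect_features(apply_motion_pose(pose, m), apply_motion_site(site, m))
    expect_equal(attr(fp1, "delta_R"), d0, tolerance = 1e-9)
  }
})

test_that("the bit is monotone non-increasing in any single deviation", {
  hb <- block_params("hydrogen_bond")
  dist_seq <- seq(2.0, 3.0, length.out = 40)
  bits <- feature_bit(vapply(dist_seq, function(d)
    delta_R(interaction_geometry(d, 180, 180), hb), numeric(1)))
  expect_true(all(diff(bits) <= 0))
  ang_seq <- seq(180, 80, length.out = 40)
  bits <- feature_bit(vapply(ang_seq, function(a)
    delta_R(interaction_geometry(2.0, a, 180), hb), numeric(1)))
  expect_true(all(diff(bits) <= 0))
})

test_that("detector reproduces generated on/off ground truth across features", {
  site <- toy_site()
  wants <- list(
    c(FP1 = "on", FP4 = "off"),
    c(FP2 = "on", FP3 = "on"),
    c(FP4 = "on"),
    c(FP5 = "on", FP6 = "off"),
    c(FP6 = "on", coordination = "on"),
    c(FP7 = "on"),
    c(FP1 = "off", FP2 = "off", FP3 = "off", FP5 = "off", FP7 = "off")
  )
  for (k in seq_along(wants)) {
    pose <- make_pose_with_features(site, wants[[k]], seed = 40 + k)
    fp <- detect_features(pose, site)
    expect_equal(unname(as.numeric(fp)[1:7]), unname(attr(pose, "truth")),
                 info = paste("case", k))
  }
})

test_that("a pose with no polar atoms yields an all-zero fingerprint", {
  xyz <- rbind(c(0, 0, 5.5), c(1.5, 0, 5.5), c(3, 0, 5.5))
  pose <- assign_atom_roles(raw_pose(xyz, c("C", "C", "C"),
                                     bonds = data.frame(i = c(1, 2), j = c(2, 3),
                                                        order = 1)))
  fp <- detect_features(pose, toy_site())
  expect_equal(as.numeric(fp), rep(0, 9))
})

test_that("FP7 fires through the C19-carbon distance rule", {
  site <- toy_site()
  pose <- make_pose_with_features(site, c(FP7 = "on"), seed = 11)
  fp <- detect_features(pose, site)
  expect_equal(as.numeric(fp)[7], 1)
  expect_lt(attr(fp, "c19_iron_distance"), 4.3)
  # same geometry but annotation withheld: the carbon is just a carbon
  pose2 <- pose
  pose2$atoms$roles <- lapply(pose2$atoms$roles, setdiff, "C19_carbon")
  expect_equal(as.numeric(detect_features(pose2, site))[7], 0)
  # re-annotated through the explicit argument
  idx <- attr(pose, "c19_carbon")
  expect_equal(as.numeric(detect_features(pose2, site, c19_carbon = idx))[7], 1)
  expect_error(detect_features(pose2, site, c19_carbon = 99), "out of range")
})

test_that("FP7 via a C19 oxygen needs both geometry and environment", {
  site <- toy_site()
  fe <- site$anchors$heme_iron$position
  # C19 oxygen at the ideal heme-oxygen geometry: O on the S-Fe axis
  # extended, carbon behind it
  o <- fe + c(0, 0, 2.40)
  cc <- o + c(0, 0, 1.43)
  pose <- raw_pose(rbind(o, cc), c("O", "C"),
                   roles = list(c("C19_oxygen", "hbond_acceptor"), character(0)),
                   bonds = data.frame(i = 1, j = 2, order = 1))
  expect_equal(as.numeric(detect_features(pose, site, c19_env_ok = FALSE))[7], 0)
  expect_equal(as.numeric(detect_features(pose, site, c19_env_ok = TRUE))[7], 1)
})

test_that("unselected candidate features are reported but not in the fingerprint", {
  site <- toy_site()
  # hydroxyl O at ideal Met374 geometry
  an <- site$anchors$Met374_amide_NH
  dir <- (an$position - an$attached) / sqrt(sum((an$position - an$attached)^2))
  o <- an$position + 2.0 * dir
  cx <- o + 1.4 * dir
  h <- o + 0.97 * c(dir[2], -dir[1], dir[3])
  pose <- raw_pose(rbind(o, cx, h), c("O", "C", "H"),
                   bonds = data.frame(i = c(1, 1), j = c(2, 3), order = 1))
  pose <- assign_atom_roles(pose)
  fp <- detect_features(pose, site)
  cand <- attr(fp, "candidates")
  expect_equal(cand$hydroxyl_O_Met374$bit, 1L)
  expect_equal(as.numeric(fp)[4], 0)  # hydroxyl O is not a keto/ether O
})

test_that("changing one preset only moves its own feature class", {
  site <- toy_site()
  pose <- make_pose_with_features(site, c(FP4 = "on", FP7 = "on",
                                          coordination = "on"), seed = 9)
  presets <- default_block_presets()
  # squeeze the azaheterocycle window to nothing: coordination dies,
  # hydrogen bonds and C19 rule untouched
  presets$heme_azaheterocycle <- block_params("custom",
    r_ideal = 0.1, dr_ideal = 0.0, dr_max = 0.01,
    alpha_ideal = 180, da_ideal = 0, da_max = 1,
    beta_ideal = 180, db_ideal = 0, db_max = 1)
  fp0 <- detect_features(pose, site)
  fp1 <- detect_features(pose, site, presets = presets)
  expect_equal(as.numeric(fp1)[1:7], as.numeric(fp0)[1:7])
  expect_equal(attr(fp0, "candidates")$coordination$bit, 1L)
  expect_equal(attr(fp1, "candidates")$coordination$bit, 0L)
})
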