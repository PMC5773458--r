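# Configuration handling and end-to-end pipeline orchestration
# (simulate -> featurize -> fit -> report).

#' Default pipeline configuration
#'
#' A single human-editable YAML-serialisable list.  Block-function presets
#' and the two published coefficient tables are fixed reference values;
#' surface sampling, contact cutoff, selection and GA settings are package
#' decisions with sensible defaults.
#'
#' @return nested named list of class \code{pipeline_config}.
#' @export
default_config <- function() {
  strip <- function(bp) unclass(bp)[names(unclass(bp))]
  structure(list(
    block_params = list(
      hydrogen_bond = strip(block_params("hydrogen_bond")),
      heme_c19_oxygen = strip(block_params("heme_c19_oxygen")),
      heme_azaheterocycle = strip(block_params("heme_azaheterocycle"))
    ),
    logpc = list(probe_radius = 1.4, point_density = 4, contact_cutoff = 4.5),
    selection = list(mode = "penalty", rmsd = 0.5, min_count = 3, u_min = 10),
    qsar = list(weights = list(steroid = 1.0, azaheterocycle = 0.1),
                ga = list(pop_size = 50, generations = 100,
                          mutation_rate = 0.02, elitism = 2,
                          parsimony = 0.002),
                split = list(train_fraction = 0.7, seed = 1)),
    synthetic = list(seed = 1, n_steroid = 122, n_aza = 87)
  ), class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#' @param path file path.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(utils::modifyList(unclass(default_config()), cfg),
            class = "pipeline_config")
}

#' @rdname read_config
#' @param config a \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Convert the config's block_params entries back into preset objects.
config_presets <- function(config) {
  mk <- function(v) do.call(block_params, c(list(preset = "custom"), v))
  list(hydrogen_bond = mk(config$block_params$hydrogen_bond),
       heme_c19_oxygen = mk(config$block_params$heme_c19_oxygen),
       heme_azaheterocycle = mk(config$block_params$heme_azaheterocycle))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on synthetic inputs
#'
#' Orchestrates simulate -> featurize -> fit -> report against the toy
#' binding site.  Every artifact is written to \code{out_dir}; a manifest
#' with MD5 content hashes records each stage's outputs, so a rerun with an
#' identical configuration is bit-identical.  Any stage error aborts with
#' the stage name (and ligand id where applicable).
#'
#' @param config a \code{pipeline_config}.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the written paths, the fitted model and
#'   the manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempdir()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  presets <- config_presets(config)
  paths <- list(
    site = file.path(out_dir, "site.json"),
    poses = file.path(out_dir, "poses.sdf"),
    annotations = file.path(out_dir, "annotations.csv"),
    cohort = file.path(out_dir, "cohort.csv"),
    fingerprints = file.path(out_dir, "fingerprints.csv"),
    model = file.path(out_dir, "model.json"),
    manifest = file.path(out_dir, "manifest.json")
  )

  # -- simulate: site, demonstration poses, activity cohort
  seed <- config$synthetic$seed
  sim <- run_stage("simulate", {
    site <- make_toy_site(seed)
    write_site_model(site, paths$site)
    wants <- list(
      c(FP4 = "on"),
      c(FP2 = "on", FP7 = "on"),
      c(FP5 = "on", coordination = "on"),
      c(FP4 = "off", FP7 = "off")
    )
    poses <- lapply(seq_along(wants), function(k)
      make_pose_with_features(site, wants[[k]], seed = seed + k,
                              ligand_id = sprintf("demo%02d", k)))
    write_poses_sdf(poses, paths$poses)
    ann <- data.frame(
      ligand_id = vapply(poses, function(p) p$ligand_id, character(1)),
      c19_carbon = vapply(poses, function(p)
        attr(p, "c19_carbon") %||% NA_integer_, numeric(1)),
      c19_env_ok = FALSE
    )
    utils::write.csv(ann, paths$annotations, row.names = FALSE)
    cohort <- make_cohort(synthetic_spec(seed = seed,
                                         n_steroid = config$synthetic$n_steroid,
                                         n_aza = config$synthetic$n_aza))
    utils::write.csv(cohort, paths$cohort, row.names = FALSE)
    list(site = site, poses = poses, cohort = cohort, annotations = ann)
  })

  # -- featurize: read the poses back from disk and detect features
  fps <- run_stage("featurize", {
    ann <- utils::read.csv(paths$annotations, stringsAsFactors = FALSE)
    c19 <- stats::setNames(
      lapply(ann$c19_carbon, function(v) if (is.na(v)) NULL else as.integer(v)),
      ann$ligand_id)
    poses <- read_poses(paths$poses, "sdf", c19_carbon = c19)
    model0 <- qsar_preset("table2_generalized")
    rows <- lapply(poses, function(p) {
      fp <- tryCatch(
        detect_features(p, sim$site, presets = presets),
        error = function(e) stop("ligand ", p$ligand_id, ": ",
                                 conditionMessage(e), call. = FALSE))
      list(ligand_id = p$ligand_id, fp = fp,
           pIC50 = predict_pic50(model0, fp))
    })
    write_fingerprint_table(rows, paths$fingerprints)
    rows
  })

  # -- fit: weighted MLR on the synthetic cohort
  model <- run_stage("fit", {
    cohort <- sim$cohort
    w <- unname(unlist(config$qsar$weights)[
      ifelse(cohort$class == "steroid", "steroid", "azaheterocycle")])
    m <- fit_weighted_mlr(cohort[, paste0("FP", 1:9)], cohort$pIC50, w,
                          weights_policy = unlist(config$qsar$weights))
    write_qsar_model(m, paths$model)
    m
  })

  # -- report: manifest with content hashes of every artifact
  manifest <- run_stage("report", {
    files <- unlist(paths[c("site", "poses", "annotations", "cohort",
                            "fingerprints", "model")])
    hashes <- as.list(tools::md5sum(files))
    names(hashes) <- basename(names(hashes))
    jsonlite::write_json(list(artifacts = hashes), paths$manifest,
                         auto_unbox = TRUE)
    hashes
  })

  invisible(list(paths = paths, model = model, manifest = manifest,
                 fingerprints = fps))
}
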