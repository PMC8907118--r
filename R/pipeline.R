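# End-to-end reconstruction workflow: normalize -> segment hemispheric white
# matter -> regress the level set -> topology-correct -> extract (optionally
# smooth) an explicit surface per hemisphere, with a JSON run manifest.
# Hemispheres are independent tasks; a failure in one aborts only that
# hemisphere.

#' Reconstruction pipeline configuration
#'
#' @param seg_model_dir,reg_model_dir directories written by [save_model()]
#'   for the segmentation and level-set regression networks.
#' @param connectivity foreground connectivity for [topology_config()].
#' @param truncation level-set truncation (mm) used to unscale regression
#'   outputs (trained targets are signed distances scaled by
#'   `1/truncation`).
#' @param smooth_iters optional Taubin smoothing iterations for the final
#'   surface (0 disables).
#' @param hemispheres `"both"`, `"left"` or `"right"`.
#' @param parallel process hemispheres concurrently (results are identical
#'   to sequential execution).
#' @param out_dir output directory.
#' @param seed recorded in the manifest; the pipeline itself is
#'   deterministic.
#' @return A `cortrec_pipeline_config`.
#' @export
pipeline_config <- function(seg_model_dir, reg_model_dir, connectivity = 6,
                            truncation = 8, smooth_iters = 0,
                            hemispheres = c("both", "left", "right"),
                            parallel = FALSE, out_dir = tempfile("cortrec_run_"),
                            seed = 1) {
  hemispheres <- match.arg(hemispheres)
  for (d in c(seg_model_dir, reg_model_dir)) {
    if (!file.exists(file.path(d, "net_config.yaml"))) {
      stopf("model directory %s does not contain a saved model", d)
    }
  }
  structure(list(seg_model_dir = seg_model_dir, reg_model_dir = reg_model_dir,
                 connectivity = connectivity, truncation = truncation,
                 smooth_iters = smooth_iters, hemispheres = hemispheres,
                 parallel = parallel, out_dir = out_dir, seed = seed),
            class = "cortrec_pipeline_config")
}

#' Run the full surface-reconstruction pipeline
#'
#' Steps per selected hemisphere: intensity normalization; hemispheric
#' white-matter segmentation; level-set regression from the normalized image
#' plus the hemisphere mask; topology correction; topology-preserving
#' isosurface extraction; optional smoothing; and writing of the surface
#' (FreeSurfer binary), the predicted level set (NIfTI + YAML sidecar with
#' sign convention and truncation) and a JSON run manifest. A stage failure
#' aborts only its hemisphere, with a stage-named error recorded in the
#' manifest.
#'
#' @param image_path path to the input NIfTI volume.
#' @param cfg a [pipeline_config()].
#' @return Invisibly, the manifest list; fields `surfaces` and `levelsets`
#'   name the written files, `errors` any per-hemisphere failures.
#' @export
run_pipeline <- function(image_path, cfg) {
  stopifnot(inherits(cfg, "cortrec_pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timing <- list()
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    r <- tryCatch(force(expr), error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
    timing[[name]] <<- round(proc.time()[["elapsed"]] - ts, 3)
    r
  }
  img <- stage("read", read_volume(image_path))
  norm <- stage("normalize", normalize_intensity(img))
  seg_model <- load_model(cfg$seg_model_dir)
  reg_model <- load_model(cfg$reg_model_dir)
  masks <- stage("segment", segment_hemispheres(seg_model, norm))
  hemis <- switch(cfg$hemispheres, both = c("left", "right"),
                  left = "left", right = "right")
  tcfg <- topology_config(cfg$connectivity)
  run_hemi <- function(h) {
    mask <- masks[[h]]
    if (!any(mask$data > 0)) stopf("stage 'segment' failed: empty %s hemisphere mask", h)
    ts <- list()
    tick <- function(name, expr) {
      t1 <- proc.time()[["elapsed"]]
      r <- tryCatch(force(expr), error = function(e) {
        stopf("stage '%s' failed (%s): %s", name, h, conditionMessage(e))
      })
      ts[[name]] <<- round(proc.time()[["elapsed"]] - t1, 3)
      r
    }
    pred <- tick("regress", predict_sliding(reg_model, norm, mask))
    ls <- level_set(volume(pred$data * cfg$truncation, pred$affine), cfg$truncation)
    ls <- tick("correct", correct_topology(ls, tcfg, seed_mask = mask))
    surf <- tick("extract", extract_surface(ls, tcfg, correct = FALSE))
    if (cfg$smooth_iters > 0) {
      surf <- tick("smooth", smooth_surface(surf, cfg$smooth_iters))
    }
    prefix <- file.path(cfg$out_dir, sprintf("%sh", substr(h, 1, 1)))
    tick("write", {
      write_surface(surf, paste0(prefix, ".white"), "freesurfer")
      write_volume(ls$volume, paste0(prefix, ".levelset.nii.gz"), datatype = "float")
      yaml::write_yaml(list(sign = "negative-inside", truncation = cfg$truncation),
                       paste0(prefix, ".levelset.yaml"))
    })
    list(surface = paste0(prefix, ".white"),
         levelset = paste0(prefix, ".levelset.nii.gz"),
         timing = ts)
  }
  results <- if (cfg$parallel && length(hemis) > 1 &&
                 .Platform$OS.type == "unix") {
    parallel::mclapply(hemis, function(h) tryCatch(run_hemi(h), error = identity),
                       mc.cores = 2)
  } else {
    lapply(hemis, function(h) tryCatch(run_hemi(h), error = identity))
  }
  names(results) <- hemis
  errors <- lapply(Filter(function(r) inherits(r, "condition"), results),
                   conditionMessage)
  ok <- Filter(function(r) !inherits(r, "condition"), results)
  cfg_plain <- unclass(cfg)
  cfg_file <- tempfile()
  yaml::write_yaml(cfg_plain, cfg_file)
  manifest <- list(
    image = image_path,
    config = cfg_plain,
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("cortrec")),
    surfaces = lapply(ok, `[[`, "surface"),
    levelsets = lapply(ok, `[[`, "levelset"),
    stage_seconds = c(timing, lapply(ok, `[[`, "timing")),
    errors = errors,
    total_seconds = round(proc.time()[["elapsed"]] - t0, 3))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (length(errors) > 0) {
    warnf("hemisphere(s) failed: %s", paste(names(errors), collapse = ", "))
  }
  invisible(manifest)
}

#' Evaluate reconstructed surfaces against references
#'
#' Pairs predicted and reference surface files by shared file name between
#' two directories and computes, per case: mean triangle quality, mean and
#' max vertex-to-surface displacement, Euler characteristic, and (when
#' `*.pial` companions exist) mean cortical thickness. Unpaired cases are
#' skipped with a warning. Writes one JSON report per case plus an aggregate
#' with across-case mean and sd of each metric.
#'
#' @param pred_dir,truth_dir directories of surface files (FreeSurfer/OFF/
#'   PLY, paired by identical file name).
#' @param out_dir where reports are written (default `pred_dir`).
#' @return Invisibly, the aggregate report list.
#' @export
run_evaluation_suite <- function(pred_dir, truth_dir, out_dir = pred_dir) {
  preds <- list.files(pred_dir, pattern = "\\.(white|pial|off|ply|surf)$")
  refs <- list.files(truth_dir, pattern = "\\.(white|pial|off|ply|surf)$")
  cases <- intersect(preds, refs)
  un <- union(setdiff(preds, refs), setdiff(refs, preds))
  if (length(un)) warnf("unpaired case(s) skipped: %s", paste(un, collapse = ", "))
  if (length(cases) == 0) stopf("no paired cases between %s and %s", pred_dir, truth_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  per_case <- lapply(cases, function(cs) {
    pm <- read_surface(file.path(pred_dir, cs))
    tm <- read_surface(file.path(truth_dir, cs))
    disp <- surface_displacement(pm, tm)
    rep <- list(case = cs,
                q_mean = triangle_quality(pm)$q_mean,
                displacement_mean = mean(disp),
                displacement_max = max(disp),
                euler = mesh_euler(pm))
    jsonlite::write_json(rep, file.path(out_dir, paste0(cs, ".metrics.json")),
                         auto_unbox = TRUE, digits = NA)
    rep
  })
  metrics <- c("q_mean", "displacement_mean", "displacement_max", "euler")
  agg <- lapply(metrics, function(m) {
    v <- vapply(per_case, `[[`, numeric(1), m)
    list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0)
  })
  names(agg) <- metrics
  aggregate <- list(n_cases = length(per_case), metrics = agg)
  jsonlite::write_json(aggregate, file.path(out_dir, "aggregate.metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cases = per_case, aggregate = aggregate))
}
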