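# End-to-end orchestration: simulate a cohort to disk, analyze a cohort of
# images, cross-validate the VA estimator, write reproducible reports.

#' Pipeline run configuration
#'
#' @param cohort_csv Path to the cohort table (see [read_cohort()]).
#' @param out_dir Output directory (created if absent).
#' @param experiment `"scp_dcp"` or `"scp_only"`.
#' @param k Cross-validation folds.
#' @param seed Integer seed driving the fold shuffle.
#' @param svr An [svr_config()].
#' @param grid_outer_mm Outer ETDRS diameter applied to every scan.
#' @param center_6mm `"frame"` or `"faz"` grid centering on 6x6 mm scans.
#' @param faz A [faz_config()].
#' @param group_by_patient Keep each patient's visits in one fold.
#' @param save_intermediates Write vessel masks and skeletons as PNGs.
#' @param verbose Log per-stage progress and timing to stderr.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort_csv, out_dir, experiment = c("scp_dcp", "scp_only"),
                       k = 5, seed = 1, svr = svr_config(),
                       grid_outer_mm = 3.0, center_6mm = c("frame", "faz"),
                       faz = faz_config(), group_by_patient = FALSE,
                       save_intermediates = FALSE, verbose = TRUE) {
  structure(
    list(cohort_csv = cohort_csv, out_dir = out_dir,
         experiment = match.arg(experiment), k = k, seed = seed, svr = svr,
         grid_outer_mm = grid_outer_mm, center_6mm = match.arg(center_6mm),
         faz = faz, group_by_patient = group_by_patient,
         save_intermediates = save_intermediates, verbose = verbose),
    class = "run_config"
  )
}

log_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full analysis pipeline on a cohort
#'
#' Reads the cohort table, extracts the per-visit biomarkers from the four
#' scans of every visit (failures are logged and the visit excluded with its
#' reason — the run only aborts when more than half the visits fail), then
#' cross-validates the VA estimator and writes `biomarkers.csv`,
#' `predictions.csv`, `exclusions.csv` and `metrics.json` into the output
#' directory. With a fixed seed the whole run — including the bytes of
#' `metrics.json` — is reproducible.
#'
#' @param config A [run_config()].
#' @return The run report (cohort sizes, exclusions, `cv_result`, file
#'   paths), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- read_cohort(config$cohort_csv)
  base <- dirname(config$cohort_csv)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  records <- list()
  exclusions <- data.frame(visit_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  scan_cols <- c(scp3 = "path_scp3", scp6 = "path_scp6",
                 dcp3 = "path_dcp3", dcp6 = "path_dcp6")
  extents <- c(scp3 = 3, scp6 = 6, dcp3 = 3, dcp6 = 6)
  plexi <- c(scp3 = "SCP", scp6 = "SCP", dcp3 = "DCP", dcp6 = "DCP")
  wanted <- if (config$experiment == "scp_only") c("scp3", "scp6") else
    names(scan_cols)
  for (i in seq_len(nrow(cohort))) {
    vid <- cohort$visit_id[i]
    res <- tryCatch({
      imgs <- lapply(wanted, function(s) {
        read_octa_image(
          resolve(cohort[[scan_cols[[s]]]][i]),
          extent_mm = extents[[s]], plexus = plexi[[s]],
          laterality = cohort$laterality[i], visit_id = vid
        )
      })
      names(imgs) <- wanted
      rec <- analyze_visit(imgs, experiment = config$experiment,
                           grid_outer_mm = config$grid_outer_mm,
                           center_6mm = config$center_6mm,
                           faz_config = config$faz)
      rec$real_va_decimal <- cohort$va_decimal[i]
      if (!is.null(cohort$patient_id)) rec$patient_id <- cohort$patient_id[i]
      if (!is.null(cohort$subgroup)) rec$subgroup <- cohort$subgroup[i]
      rec
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_msg(config$verbose, "visit %s excluded: %s", vid, conditionMessage(res))
      exclusions <- rbind(exclusions, data.frame(
        visit_id = vid, reason = conditionMessage(res), stringsAsFactors = FALSE
      ))
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  log_msg(config$verbose, "biomarker extraction: %d/%d visits in %.1f s",
          length(records), nrow(cohort), proc.time()[["elapsed"]] - t0)
  if (length(records) < nrow(cohort) / 2) {
    stop_validation(sprintf(
      "more than half the cohort failed (%d of %d visits excluded)",
      nrow(exclusions), nrow(cohort)
    ))
  }
  t1 <- proc.time()[["elapsed"]]
  cv <- cross_validate(records, experiment = config$experiment, k = config$k,
                       seed = config$seed, svr = config$svr,
                       group_by_patient = config$group_by_patient)
  log_msg(config$verbose, "cross-validation (%d-fold): %.1f s",
          config$k, proc.time()[["elapsed"]] - t1)

  biomarkers <- do.call(rbind, lapply(records, function(r) {
    as.data.frame(c(
      list(visit_id = r$visit_id, laterality = r$laterality),
      as.list(assemble_features(r, config$experiment)),
      list(real_va_decimal = r$real_va_decimal)
    ), stringsAsFactors = FALSE)
  }))
  metrics <- list(
    experiment = config$experiment,
    n_input = nrow(cohort),
    n_included = length(records),
    n_excluded = nrow(exclusions),
    k = config$k,
    seed = config$seed,
    pearson_r = cv$pearson_r,
    p_value = cv$p_value,
    mse_decimal = cv$mse_decimal,
    fold_mse = cv$fold_mse,
    train_mse = cv$train_mse
  )
  subgroups <- vapply(records, function(r) r$subgroup %||% NA_character_, "")
  if (any(!is.na(subgroups))) {
    # subgroup breakdown uses the all-data refit predictions (the comparative
    # whole-sample analysis), not the held-out ones
    y <- vapply(records, function(r) r$real_va_decimal, numeric(1))
    metrics$subgroup_mse <- lapply(
      split(seq_along(records), subgroups),
      function(ix) mse(cv$train_predictions[ix], y[ix])
    )
  }
  paths <- list(
    biomarkers = file.path(config$out_dir, "biomarkers.csv"),
    predictions = file.path(config$out_dir, "predictions.csv"),
    exclusions = file.path(config$out_dir, "exclusions.csv"),
    metrics = file.path(config$out_dir, "metrics.json")
  )
  utils::write.csv(biomarkers, paths$biomarkers, row.names = FALSE)
  utils::write.csv(cv$predictions, paths$predictions, row.names = FALSE)
  utils::write.csv(exclusions, paths$exclusions, row.names = FALSE)
  jsonlite::write_json(metrics, paths$metrics, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  log_msg(config$verbose, "total runtime %.1f s; outputs in %s",
          proc.time()[["elapsed"]] - t0, config$out_dir)
  invisible(list(metrics = metrics, cv = cv, exclusions = exclusions,
                 records = records, paths = paths))
}

#' Write a simulated cohort of angiograms to disk
#'
#' Generates `n_visits` synthetic visits, each with four scans (SCP/DCP at
#' 3x3 and 6x6 mm) rendered by [generate_vessel_image()], plus JSON metadata
#' sidecars, a cohort CSV and a ground-truth JSON. Per-visit pathology is
#' emulated by drawing a FAZ radius and per-zone capillary dropout (the deep
#' plexus is hit harder, as in retinal vein occlusion), and decimal VA is
#' computed from the *ground-truth* biomarkers through the linear law of
#' [cohort_spec()] plus Gaussian noise — so the pipeline's ability to recover
#' VA from re-measured images can be tested end to end.
#'
#' @param out_dir Destination directory.
#' @param n_visits Number of visits.
#' @param size_px Image side in pixels (one size for all scans).
#' @param seed Integer seed.
#' @param noise_sd Intensity noise (gray levels).
#' @param va_noise_sd VA noise (decimal scale).
#' @return Path to the written cohort CSV, invisibly.
#' @export
simulate_cohort <- function(out_dir, n_visits = 20, size_px = 160, seed = 1,
                            noise_sd = 10, va_noise_sd = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  weights <- default_cohort_weights()
  mean_x <- c(0.8, rep(0.135, 20))
  intercept <- 0.5 - sum(weights * mean_x)
  rows <- list()
  truths <- list()
  with_seed(seed, {
    for (i in seq_len(n_visits)) {
      vid <- sprintf("visit%03d", i)
      lat <- sample(c("OD", "OS"), 1)
      faz_r <- stats::runif(1, 0.15, 0.45)
      drop_scp <- stats::setNames(stats::runif(5, 0, 0.3), ZONES)
      drop_dcp <- pmin(drop_scp + stats::runif(5, 0, 0.3), 0.9)
      scan_seeds <- sample.int(.Machine$integer.max, 4)
      scans <- list(
        scp3 = list(plexus = "SCP", extent = 3, drop = drop_scp),
        scp6 = list(plexus = "SCP", extent = 6, drop = drop_scp),
        dcp3 = list(plexus = "DCP", extent = 3, drop = drop_dcp),
        dcp6 = list(plexus = "DCP", extent = 6, drop = drop_dcp)
      )
      x <- stats::setNames(numeric(21), feature_names("scp_dcp"))
      paths <- character(0)
      for (si in seq_along(scans)) {
        s <- scans[[si]]
        nm <- names(scans)[si]
        spec <- vessel_fixture_spec(
          size_px = size_px, extent_mm = s$extent,
          faz_radius_mm = if (s$extent == 3) faz_r else 0,
          dropout = s$drop, noise_sd = noise_sd, plexus = s$plexus,
          laterality = lat, visit_id = vid, seed = scan_seeds[si]
        )
        gen <- generate_vessel_image(spec)
        img_path <- file.path(out_dir, sprintf("%s_%s.png", vid, nm))
        write_octa_image(gen$image, img_path)
        jsonlite::write_json(
          list(extent_mm = s$extent, plexus = s$plexus, laterality = lat,
               visit_id = vid),
          paste0(img_path, ".json"), auto_unbox = TRUE
        )
        paths[nm] <- basename(img_path)
        dens <- gen$truth$zone_counts / gen$truth$zone_sizes
        x[paste0("vd_", tolower(s$plexus), s$extent, "_", ZONES)] <- dens
        if (nm == "scp3") x["faz_area_scp3_mm2"] <- gen$truth$faz_area_mm2
      }
      va <- intercept + sum(weights * x) + stats::rnorm(1, 0, va_noise_sd)
      va <- min(max(va, 0), 1)
      rows[[i]] <- data.frame(
        visit_id = vid, va_decimal = va, laterality = lat,
        path_scp3 = paths["scp3"], path_scp6 = paths["scp6"],
        path_dcp3 = paths["dcp3"], path_dcp6 = paths["dcp6"],
        stringsAsFactors = FALSE
      )
      truths[[vid]] <- list(true_biomarkers = as.list(x), va_decimal = va,
                            faz_radius_mm = faz_r)
    }
  })
  cohort <- do.call(rbind, rows)
  csv <- file.path(out_dir, "cohort.csv")
  utils::write.csv(cohort, csv, row.names = FALSE)
  jsonlite::write_json(
    list(weights = as.list(weights), intercept = intercept, seed = seed,
         visits = truths),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(csv)
}
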