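# Seeded synthetic angiograms with known vascular ground truth, and synthetic
# cohorts with a known biomarker -> VA law. These are first-class test
# instruments: every pipeline stage is validated against their geometry.

#' Specification of a synthetic vessel-network angiogram
#'
#' The generator renders a bright quasi-regular capillary lattice (jittered
#' horizontal and vertical vessels) on a dark background. A FAZ is emulated by
#' erasing all vessels inside a central disk and drawing a circumferential
#' capillary ring whose inner edge sits exactly at the FAZ radius — as in the
#' retina, where a continuous perifoveal arcade bounds the avascular zone —
#' so the true avascular area is well defined. Per-zone dropout erases a
#' fraction of inter-junction vessel segments (capillary non-perfusion);
#' Gaussian noise is added last. Intensities are clearly bimodal by design
#' (vessels 180–255, background 0–60) so thresholding behavior is predictable.
#'
#' @param size_px Image side in pixels.
#' @param extent_mm Physical side length, mm.
#' @param faz_radius_mm FAZ radius (0 = no FAZ); must be < `extent_mm / 2`.
#' @param vessel_spacing_px,vessel_width_px Lattice geometry, pixels.
#' @param dropout Named fractions in `[0, 1]` of vessel segments erased per
#'   ETDRS zone (`foveal`, `upper`, `nasal`, `temporal`, `lower`).
#' @param noise_sd Additive Gaussian intensity noise (gray levels), clipped
#'   to `[0, 255]`.
#' @param plexus,laterality,visit_id Metadata stamped on the image.
#' @param seed Integer seed; the fixture is bit-reproducible per seed.
#' @return A `vessel_fixture_spec` list.
#' @export
vessel_fixture_spec <- function(size_px = 320, extent_mm = 3.0,
                                faz_radius_mm = 0.30,
                                vessel_spacing_px = 12, vessel_width_px = 3,
                                dropout = c(foveal = 0, upper = 0, nasal = 0,
                                            temporal = 0, lower = 0),
                                noise_sd = 10,
                                plexus = "SCP", laterality = "OD",
                                visit_id = "synthetic", seed = 1) {
  full <- stats::setNames(rep(0, 5), ZONES)
  if (is.null(names(dropout))) {
    if (length(dropout) == 1) dropout <- rep(dropout, 5)
    if (length(dropout) != 5) {
      stop_validation("unnamed dropout must have length 1 or 5")
    }
    names(dropout) <- ZONES
  }
  full[names(dropout)] <- dropout
  if (any(full < 0 | full > 1)) {
    stop_validation("dropout fractions must lie in [0, 1]")
  }
  if (faz_radius_mm < 0 || noise_sd < 0 || size_px < 16 || extent_mm <= 0 ||
      vessel_spacing_px < vessel_width_px + 2) {
    stop_validation("invalid fixture geometry")
  }
  if (faz_radius_mm >= extent_mm / 2) {
    stop_validation("faz_radius_mm must be smaller than half the extent")
  }
  structure(
    list(size_px = as.integer(size_px), extent_mm = extent_mm,
         faz_radius_mm = faz_radius_mm,
         vessel_spacing_px = vessel_spacing_px,
         vessel_width_px = vessel_width_px, dropout = full,
         noise_sd = noise_sd, plexus = plexus, laterality = laterality,
         visit_id = visit_id, seed = as.integer(seed)),
    class = "vessel_fixture_spec"
  )
}

#' Render a synthetic angiogram with ground truth
#'
#' @param spec A [vessel_fixture_spec()].
#' @return List with `image` (an [octa_image]), and `truth`: `vessel_mask`
#'   and `skeleton` (pre-noise geometry), `faz_mask` and `faz_area_mm2`
#'   (the true avascular disk), `zone_counts` and `zone_sizes` (per-ETDRS-zone
#'   skeleton pixel counts and zone pixel counts for a grid at the frame
#'   center), and `zones` (the grid itself).
#' @export
generate_vessel_image <- function(spec) {
  stopifnot(inherits(spec, "vessel_fixture_spec"))
  n <- spec$size_px
  w <- spec$vessel_width_px
  sp <- spec$vessel_spacing_px
  scale <- spec$extent_mm / n
  center <- c(n / 2, n / 2)
  with_seed(spec$seed, {
    line_starts <- function() {
      pos <- seq(sp %/% 2, n - w, by = sp)
      pmin(pmax(pos + round(stats::runif(length(pos), -2, 2)), 1L), n - w + 1L)
    }
    vx <- line_starts() # vertical vessel start columns
    hy <- line_starts() # horizontal vessel start rows
    mask <- matrix(0L, n, n)
    for (c0 in vx) mask[, c0:(c0 + w - 1L)] <- 1L
    for (r0 in hy) mask[r0:(r0 + w - 1L), ] <- 1L

    zones <- build_etdrs_masks(c(n, n), center, scale, spec$laterality)
    zone_label <- matrix(0L, n, n)
    for (zi in seq_along(ZONES)) zone_label[zones[[ZONES[zi]]] == 1L] <- zi

    # per-zone dropout of inter-junction segments
    if (any(spec$dropout > 0)) {
      erase_segments <- function(along_rows) {
        lines <- if (along_rows) hy else vx
        crossers <- if (along_rows) vx else hy
        for (l0 in lines) {
          brk <- sort(unique(c(0L, as.integer(outer(crossers, 0:(w - 1L), "+")), n + 1L)))
          runs <- split(seq_len(n), cumsum(seq_len(n) %in% brk))
          for (run in runs) {
            run <- setdiff(run, brk)
            if (length(run) < 2) next
            mid <- run[ceiling(length(run) / 2)]
            z <- if (along_rows) zone_label[l0, mid] else zone_label[mid, l0]
            if (z == 0L) next
            if (stats::runif(1) < spec$dropout[ZONES[z]]) {
              if (along_rows) {
                mask[l0:(l0 + w - 1L), run] <<- 0L
              } else {
                mask[run, l0:(l0 + w - 1L)] <<- 0L
              }
            }
          }
        }
      }
      erase_segments(TRUE)
      erase_segments(FALSE)
    }

    d <- pixel_center_dist(n, n, center)
    faz_mask <- matrix(0L, n, n)
    if (spec$faz_radius_mm > 0) {
      r_px <- spec$faz_radius_mm / scale
      faz_mask[d < r_px] <- 1L
      mask[faz_mask == 1L] <- 0L
      mask[d >= r_px & d < r_px + w] <- 1L # perifoveal capillary ring
    }

    skeleton <- skeletonize(mask)
    zone_counts <- vapply(ZONES, function(z) sum(skeleton[zones[[z]] == 1L]),
                          numeric(1))
    zone_sizes <- vapply(ZONES, function(z) sum(zones[[z]]), numeric(1))

    intens <- matrix(stats::runif(n * n, 0, 60), n, n)
    intens[mask == 1L] <- stats::runif(sum(mask), 180, 255)
    if (spec$noise_sd > 0) {
      intens <- intens + stats::rnorm(n * n, 0, spec$noise_sd)
    }
    pix <- round(pmin(pmax(intens, 0), 255))
    image <- octa_image(pix, spec$extent_mm, spec$plexus, spec$laterality,
                        spec$visit_id)
    list(
      image = image,
      truth = list(
        vessel_mask = mask, skeleton = skeleton,
        faz_mask = faz_mask,
        faz_area_mm2 = sum(faz_mask) * scale^2,
        zone_counts = zone_counts, zone_sizes = zone_sizes,
        zones = zones
      )
    )
  })
}

#' Specification of a synthetic biomarker cohort
#'
#' Biomarkers are drawn independently from plausible clinical ranges (FAZ area
#' 0.1–1.5 mm^2, zone densities 0.02–0.25) and decimal VA follows a known
#' linear law `VA = intercept + w . x + N(0, va_noise_sd)`, clipped to
#' `[0, 1]`. Default weights encode the expected clinical signs — VA falls
#' with FAZ enlargement and rises with perfusion in every plexus — and are
#' scaled so the noiseless VA signal has a standard deviation of about 0.16
#' around a mean of 0.5, i.e. clipping is negligible and the vascular signal
#' clearly dominates measurement noise.
#'
#' @param n_visits Number of visits (>= 15).
#' @param weights Named length-21 weight vector over [feature_names()].
#' @param intercept Intercept of the linear law; `NULL` centers mean VA at 0.5.
#' @param va_noise_sd Gaussian VA noise, decimal scale.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_visits = 150, weights = default_cohort_weights(),
                        intercept = NULL, va_noise_sd = 0.05, seed = 1) {
  if (n_visits < 15) stop_validation("n_visits must be at least 15")
  if (va_noise_sd < 0) stop_validation("va_noise_sd must be nonnegative")
  nm <- feature_names("scp_dcp")
  if (!all(nm %in% names(weights))) {
    stop_validation("weights must cover all 21 biomarker names")
  }
  weights <- weights[nm]
  if (is.null(intercept)) {
    mean_x <- c(0.8, rep((0.02 + 0.25) / 2, 20)) # midpoints of the draw ranges
    intercept <- 0.5 - sum(weights * mean_x)
  }
  structure(
    list(n_visits = as.integer(n_visits), weights = weights,
         intercept = intercept, va_noise_sd = va_noise_sd,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_cohort_weights <- function() {
  c(stats::setNames(-0.22, "faz_area_scp3_mm2"),
    stats::setNames(rep(0.52, 5), paste0("vd_scp3_", ZONES)),
    stats::setNames(rep(0.43, 5), paste0("vd_scp6_", ZONES)),
    stats::setNames(rep(0.48, 5), paste0("vd_dcp3_", ZONES)),
    stats::setNames(rep(0.37, 5), paste0("vd_dcp6_", ZONES)))
}

#' Draw a synthetic cohort with a known biomarker -> VA law
#'
#' @param spec A [cohort_spec()].
#' @return List with `records` (list of `visit_record`s, each carrying
#'   `real_va_decimal`), `weights`, `intercept`, and `va_linear` (the
#'   pre-noise, pre-clip linear predictor, for oracle checks).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  nm <- feature_names("scp_dcp")
  with_seed(spec$seed, {
    n <- spec$n_visits
    x <- cbind(
      stats::runif(n, 0.1, 1.5),
      matrix(stats::runif(n * 20, 0.02, 0.25), n, 20)
    )
    colnames(x) <- nm
    lin <- drop(x %*% spec$weights) + spec$intercept
    va <- lin
    if (spec$va_noise_sd > 0) va <- va + stats::rnorm(n, 0, spec$va_noise_sd)
    va <- pmin(pmax(va, 0), 1)
    records <- lapply(seq_len(n), function(i) {
      vd <- list()
      for (plex in c("SCP", "DCP")) {
        for (ext in c("3", "6")) {
          key <- paste0("vd_", tolower(plex), ext, "_")
          vd[[plex]][[ext]] <- stats::setNames(
            as.list(x[i, paste0(key, ZONES)]), ZONES
          )
        }
      }
      structure(
        list(visit_id = sprintf("sim%03d", i), laterality = "OD",
             faz_area_scp3_mm2 = x[i, 1], faz_centroid_px = NULL,
             vd = vd, real_va_decimal = va[i]),
        class = "visit_record"
      )
    })
    list(records = records, weights = spec$weights,
         intercept = spec$intercept, va_linear = lin)
  })
}
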