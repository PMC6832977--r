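# ETDRS grid construction and skeleton-based vascular density.

ZONES <- c("foveal", "upper", "nasal", "temporal", "lower")

#' Build the five ETDRS zone masks
#'
#' The grid has a 1 mm diameter central (foveal) disk and a 3 mm diameter
#' outer ring; the parafoveal annulus between them is split into four
#' quadrants by the two diagonals through the grid center. Pixel membership
#' is decided by the pixel-center distance to the grid center, and quadrant
#' boundaries are half-open angular intervals so the five masks always
#' partition the outer disk exactly. With angles measured from image-right,
#' counterclockwise: upper = \[45°, 135°), lower = \[225°, 315°); for a right
#' eye (OD) the nasal quadrant is image-right \[-45°, 45°) and temporal is
#' image-left \[135°, 225°); the two swap for a left eye (OS).
#'
#' @param shape `c(H, W)` of the target image in pixels.
#' @param center_px Grid center `(row, col)` in continuous image coordinates
#'   (top-left corner = `(0, 0)`; pixel `(i, j)` centers at `(i-0.5, j-0.5)`).
#' @param scale Millimetres per pixel.
#' @param laterality `"OD"` or `"OS"`.
#' @param inner_diameter_mm,outer_diameter_mm Grid ring diameters (defaults:
#'   the standard 1 mm / 3 mm macular grid).
#' @return A `zone_masks` object: list of five 0/1 matrices named `foveal`,
#'   `upper`, `nasal`, `temporal`, `lower`, plus the grid metadata.
#' @export
build_etdrs_masks <- function(shape, center_px, scale, laterality,
                              inner_diameter_mm = 1.0,
                              outer_diameter_mm = 3.0) {
  h <- shape[1]
  w <- shape[2]
  if (!laterality %in% c("OD", "OS")) {
    stop_validation("`laterality` must be \"OD\" or \"OS\"")
  }
  if (center_px[1] < 0 || center_px[1] > h || center_px[2] < 0 ||
      center_px[2] > w) {
    stop_validation(sprintf(
      "grid center (%.1f, %.1f) lies outside the %d x %d image",
      center_px[1], center_px[2], h, w
    ))
  }
  r_inner <- inner_diameter_mm / 2
  r_outer <- outer_diameter_mm / 2
  d_mm <- pixel_center_dist(h, w, center_px) * scale
  rows <- matrix(seq_len(h) - 0.5, h, w)
  cols <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  # polar angle from image-right, counterclockwise (rows grow downward)
  theta <- atan2(-(rows - center_px[1]), cols - center_px[2]) * 180 / pi
  theta <- (theta + 360) %% 360
  annulus <- d_mm > r_inner & d_mm <= r_outer
  quad <- function(lo, hi) {
    sect <- if (lo < hi) theta >= lo & theta < hi else theta >= lo | theta < hi
    as_binary((annulus & sect) * 1L)
  }
  right <- quad(315, 45)
  left <- quad(135, 225)
  masks <- list(
    foveal = as_binary((d_mm <= r_inner) * 1L),
    upper = quad(45, 135),
    nasal = if (laterality == "OD") right else left,
    temporal = if (laterality == "OD") left else right,
    lower = quad(225, 315)
  )
  structure(
    c(masks, list(
      center_px = as.numeric(center_px),
      inner_diameter_mm = inner_diameter_mm,
      outer_diameter_mm = outer_diameter_mm,
      scale = scale, laterality = laterality
    )),
    class = "zone_masks"
  )
}

#' Skeleton vascular density per ETDRS zone
#'
#' The density of a region is the number of skeleton pixels inside it divided
#' by the region's own pixel count — the restriction, to each zone, of the
#' whole-frame definition (skeleton pixel count over height x width), which is
#' also reported as `dens_global`.
#'
#' @param skeleton 0/1 skeleton matrix (from [skeletonize()]).
#' @param zones A `zone_masks` object sharing the skeleton's shape.
#' @param plexus,extent_mm Optional metadata carried into the profile.
#' @return A `density_profile`: `dens_foveal`, `dens_upper`, `dens_nasal`,
#'   `dens_temporal`, `dens_lower`, `dens_global`, all fractions in `[0, 1]`.
#' @export
zonal_density <- function(skeleton, zones, plexus = NA_character_,
                          extent_mm = NA_real_) {
  if (!inherits(zones, "zone_masks")) {
    stop_validation("`zones` must come from build_etdrs_masks()")
  }
  if (!all(dim(skeleton) == dim(zones$foveal))) {
    stop_validation("skeleton and zone masks have different shapes")
  }
  dens <- vapply(ZONES, function(z) {
    m <- zones[[z]]
    npx <- sum(m)
    if (npx == 0) {
      stop_validation(sprintf(
        "ETDRS zone \"%s\" contains no pixels (grid center too close to the border)", z
      ))
    }
    sum(skeleton[m == 1L]) / npx
  }, numeric(1))
  structure(
    c(as.list(stats::setNames(dens, paste0("dens_", ZONES))),
      list(dens_global = sum(skeleton) / length(skeleton),
           plexus = plexus, extent_mm = extent_mm)),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("<density_profile> %s %s mm\n", x$plexus, format(x$extent_mm)))
  for (z in ZONES) cat(sprintf("  %-9s %.4f\n", z, x[[paste0("dens_", z)]]))
  cat(sprintf("  %-9s %.4f\n", "global", x$dens_global))
  invisible(x)
}

#' Extract all per-visit vascular biomarkers from a visit's scans
#'
#' Runs the full image chain on each available scan: FAZ detection on the
#' 3x3 mm superficial scan, then Otsu thresholding, thinning and zonal density
#' on every scan. The ETDRS grid is centered on the detected FAZ centroid for
#' the 3x3 mm scans; 6x6 mm scans use the frame center by default (all
#' captures are fovea-centered at acquisition), or the propagated FAZ
#' centroid with `center_6mm = "faz"`.
#'
#' @param images Named list of [octa_image]s: `scp3`, `scp6` and, unless
#'   `experiment = "scp_only"`, `dcp3`, `dcp6`. Lateralities must agree.
#' @param experiment `"scp_dcp"` (all four scans) or `"scp_only"`.
#' @param grid_outer_mm Outer grid diameter applied to every scan (the same
#'   physical 1/3 mm grid is used on both scan sizes by default).
#' @param center_6mm `"frame"` or `"faz"`.
#' @param faz_config FAZ detection settings, see [faz_config()].
#' @return A `visit_record`: `visit_id`, `laterality`,
#'   `faz_area_scp3_mm2`, `faz_centroid_px`, nested densities
#'   `vd[[plexus]][[extent]][[zone]]`, and `real_va_decimal` (`NA` until
#'   attached from a cohort table).
#' @export
analyze_visit <- function(images, experiment = c("scp_dcp", "scp_only"),
                          grid_outer_mm = 3.0,
                          center_6mm = c("frame", "faz"),
                          faz_config = octava::faz_config()) {
  experiment <- match.arg(experiment)
  center_6mm <- match.arg(center_6mm)
  wanted <- if (experiment == "scp_only") c("scp3", "scp6") else
    c("scp3", "scp6", "dcp3", "dcp6")
  missing_scans <- setdiff(wanted, names(images))
  if (length(missing_scans)) {
    stop_validation(sprintf(
      "missing scan(s): %s", paste(missing_scans, collapse = ", ")
    ))
  }
  images <- images[wanted]
  lats <- vapply(images, function(im) im$laterality, "")
  if (length(unique(lats)) != 1) {
    stop_validation("scans of one visit must share laterality")
  }
  visit_id <- images$scp3$visit_id
  faz <- tryCatch(
    detect_faz(images$scp3, config = faz_config),
    octava_detection_failure = function(e) {
      stop_detection(sprintf("visit %s: %s", visit_id, conditionMessage(e)))
    }
  )
  vd <- list()
  for (nm in wanted) {
    im <- images[[nm]]
    center <- if (im$extent_mm <= 4.5 || center_6mm == "faz") {
      # propagate the FAZ centroid: all captures share the foveal frame center,
      # so carry its mm offset from the SCP3 frame center into this scan
      off_mm <- faz$centroid_px * scale_mm_per_px(images$scp3) -
        images$scp3$extent_mm / 2
      (im$extent_mm / 2 + off_mm) / scale_mm_per_px(im)
    } else {
      c(nrow(im$pixels) / 2, ncol(im$pixels) / 2)
    }
    zones <- build_etdrs_masks(
      dim(im$pixels), center, scale_mm_per_px(im), im$laterality,
      outer_diameter_mm = grid_outer_mm
    )
    skel <- skeletonize(binarize(im, otsu_threshold(im)$threshold))
    prof <- zonal_density(skel, zones, plexus = im$plexus,
                          extent_mm = im$extent_mm)
    plex <- im$plexus
    ext <- as.character(round(im$extent_mm))
    vd[[plex]][[ext]] <- stats::setNames(
      lapply(ZONES, function(z) prof[[paste0("dens_", z)]]), ZONES
    )
  }
  structure(
    list(
      visit_id = visit_id,
      laterality = lats[[1]],
      faz_area_scp3_mm2 = faz$area_mm2,
      faz_centroid_px = faz$centroid_px,
      vd = vd,
      real_va_decimal = NA_real_
    ),
    class = "visit_record"
  )
}

#' @export
print.visit_record <- function(x, ...) {
  cat(sprintf("<visit_record> %s (%s): FAZ %.4f mm2\n",
              x$visit_id, x$laterality, x$faz_area_scp3_mm2))
  for (p in names(x$vd)) {
    for (e in names(x$vd[[p]])) {
      cat(sprintf("  %s %s mm: %s\n", p, e,
                  paste(sprintf("%s %.3f", ZONES,
                                unlist(x$vd[[p]][[e]])), collapse = ", ")))
    }
  }
  if (!is.na(x$real_va_decimal)) {
    cat(sprintf("  real VA %.2f\n", x$real_va_decimal))
  }
  invisible(x)
}
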