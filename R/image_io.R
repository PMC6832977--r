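# Angiogram containers and file I/O.

#' Construct an en-face OCTA angiogram object
#'
#' An `octa_image` couples a square grid of 8-bit gray intensities with the
#' physical metadata needed downstream: the scan's side length in millimetres,
#' the capillary plexus the slab was projected from, and the eye's laterality
#' (which decides the nasal/temporal labeling of the ETDRS grid).
#'
#' The coordinate convention is fixed package-wide: matrix row 1 is the top
#' (superior) edge of the image, column 1 the left edge, and the center of
#' pixel `(i, j)` sits at continuous coordinates `(i - 0.5, j - 0.5)`.
#'
#' @param pixels Square numeric matrix of whole-number intensities in
#'   `[0, 255]`.
#' @param extent_mm Physical side length in mm (3 and 6 are the usual macular
#'   scan sizes, but any positive value is accepted).
#' @param plexus `"SCP"` (superficial) or `"DCP"` (deep capillary plexus).
#' @param laterality `"OD"` (right eye) or `"OS"` (left eye).
#' @param visit_id Opaque visit identifier.
#' @return An object of class `octa_image` with fields `pixels`, `extent_mm`,
#'   `plexus`, `laterality`, `visit_id`.
#' @examples
#' img <- octa_image(matrix(0L, 8, 8), extent_mm = 3, plexus = "SCP",
#'                   laterality = "OD", visit_id = "v1")
#' scale_mm_per_px(img)
#' @export
octa_image <- function(pixels, extent_mm, plexus, laterality, visit_id) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || nrow(pixels) == 0) {
    stop_validation("`pixels` must be a non-empty numeric matrix")
  }
  if (nrow(pixels) != ncol(pixels)) {
    stop_validation(sprintf(
      "angiogram must be square; got %d x %d", nrow(pixels), ncol(pixels)
    ))
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255 ||
      any(pixels != round(pixels))) {
    stop_validation("intensities must be whole numbers in [0, 255]")
  }
  if (!is.numeric(extent_mm) || length(extent_mm) != 1 || extent_mm <= 0) {
    stop_validation("`extent_mm` must be a single positive number")
  }
  if (!is.character(plexus) || length(plexus) != 1 ||
      !plexus %in% c("SCP", "DCP")) {
    stop_validation("`plexus` must be \"SCP\" or \"DCP\"")
  }
  if (!is.character(laterality) || length(laterality) != 1 ||
      !laterality %in% c("OD", "OS")) {
    stop_validation("`laterality` must be \"OD\" or \"OS\"")
  }
  if (!is.character(visit_id) || length(visit_id) != 1 || !nzchar(visit_id)) {
    stop_validation("`visit_id` must be a non-empty string")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, extent_mm = as.numeric(extent_mm), plexus = plexus,
         laterality = laterality, visit_id = visit_id),
    class = "octa_image"
  )
}

#' Physical pixel pitch of an angiogram
#'
#' @param image An [octa_image].
#' @return Millimetres per pixel (`extent_mm / width`).
#' @export
scale_mm_per_px <- function(image) {
  stopifnot(inherits(image, "octa_image"))
  image$extent_mm / ncol(image$pixels)
}

#' @export
print.octa_image <- function(x, ...) {
  cat(sprintf(
    "<octa_image> %s %s %s: %d x %d px, %.1f mm (%.6f mm/px)\n",
    x$visit_id, x$plexus, x$laterality, nrow(x$pixels), ncol(x$pixels),
    x$extent_mm, scale_mm_per_px(x)
  ))
  invisible(x)
}

#' Read an en-face angiogram from PNG or TIFF
#'
#' Accepts 8-bit grayscale images (PNG via the \pkg{png} package, TIFF via an
#' in-package reader for uncompressed baseline grayscale TIFF). RGB images
#' whose three channels are identical — common for exported screenshots — are
#' collapsed to one channel; truly colored images are rejected. Metadata can
#' be given as arguments or through a JSON sidecar (`<path>.json` is picked up
#' automatically) with fields `extent_mm`, `plexus`, `laterality`, `visit_id`.
#'
#' @param path Image file path (`.png`, `.tif`, `.tiff`).
#' @param extent_mm,plexus,laterality,visit_id Metadata; any left `NULL` must
#'   be supplied by the sidecar.
#' @param sidecar Optional path to a JSON sidecar (overrides the automatic
#'   `<path>.json` lookup).
#' @return An [octa_image]; intensities are preserved bit-exactly.
#' @export
read_octa_image <- function(path, extent_mm = NULL, plexus = NULL,
                            laterality = NULL, visit_id = NULL,
                            sidecar = NULL) {
  if (!file.exists(path)) {
    stop_io(sprintf("image file not found: %s", path))
  }
  if (is.null(sidecar) && file.exists(paste0(path, ".json"))) {
    sidecar <- paste0(path, ".json")
  }
  if (!is.null(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    extent_mm <- extent_mm %||% meta$extent_mm
    plexus <- plexus %||% meta$plexus
    laterality <- laterality %||% meta$laterality
    visit_id <- visit_id %||% meta$visit_id
  }
  if (is.null(extent_mm) || is.null(plexus) || is.null(laterality) ||
      is.null(visit_id)) {
    stop_validation(sprintf(
      "missing metadata for %s: extent_mm, plexus, laterality and visit_id are required",
      path
    ))
  }
  ext <- tolower(tools::file_ext(path))
  pix <- switch(ext,
    png = read_png_gray(path),
    tif = ,
    tiff = read_tiff_gray(path),
    stop_io(sprintf("unsupported image format: .%s", ext))
  )
  octa_image(pix, extent_mm, plexus, laterality, visit_id)
}

#' Write an angiogram (or a 0/1 mask) as an 8-bit grayscale image
#'
#' @param image An [octa_image] or a numeric matrix in `[0, 255]`.
#' @param path Destination (`.png` or `.tif`/`.tiff` decides the format).
#' @return `path`, invisibly.
#' @export
write_octa_image <- function(image, path) {
  pix <- if (inherits(image, "octa_image")) image$pixels else image
  if (!is.matrix(pix) || min(pix) < 0 || max(pix) > 255) {
    stop_validation("pixel matrix must lie in [0, 255]")
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(pix / 255, target = path),
    tif = ,
    tiff = write_tiff_gray(pix, path),
    stop_io(sprintf("unsupported image format: .%s", ext))
  )
  invisible(path)
}

read_png_gray <- function(path) {
  arr <- tryCatch(png::readPNG(path), error = function(e) {
    stop_io(sprintf("cannot decode PNG %s: %s", path, conditionMessage(e)))
  })
  round(collapse_channels(arr, path) * 255)
}

# Collapse HxWxC arrays with identical color channels; error on real color.
# Returns the single [0, 1] channel.
collapse_channels <- function(arr, path) {
  if (length(dim(arr)) == 2) {
    return(arr)
  }
  nc <- dim(arr)[3]
  if (nc >= 3) {
    if (max(abs(arr[, , 1] - arr[, , 2])) > 0 ||
        max(abs(arr[, , 1] - arr[, , 3])) > 0) {
      stop_validation(sprintf(
        "%s is a colored image; only grayscale (or equal-channel RGB) is supported",
        path
      ))
    }
  }
  if (nc == 4 && min(arr[, , 4]) < 1) {
    stop_validation(sprintf("%s has a non-trivial alpha channel", path))
  }
  arr[, , 1]
}

# --- Minimal baseline TIFF codec (uncompressed 8-bit grayscale, 1 sample) ---

write_tiff_gray <- function(pix, path) {
  h <- nrow(pix)
  w <- ncol(pix)
  con <- file(path, "wb")
  on.exit(close(con))
  nbytes <- h * w
  ifd_off <- 8L + nbytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  writeBin(as.raw(as.integer(t(pix))), con) # scanlines top to bottom
  entries <- list(
    c(256L, 3L, 1L, w), # ImageWidth
    c(257L, 3L, 1L, h), # ImageLength
    c(258L, 3L, 1L, 8L), # BitsPerSample
    c(259L, 3L, 1L, 1L), # Compression: none
    c(262L, 3L, 1L, 1L), # Photometric: BlackIsZero
    c(273L, 4L, 1L, 8L), # StripOffsets
    c(277L, 3L, 1L, 1L), # SamplesPerPixel
    c(278L, 4L, 1L, h), # RowsPerStrip
    c(279L, 4L, 1L, nbytes) # StripByteCounts
  )
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(e[1], con, size = 2, endian = "little")
    writeBin(e[2], con, size = 2, endian = "little")
    writeBin(e[3], con, size = 4, endian = "little")
    if (e[2] == 3L) {
      writeBin(e[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(e[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")
  invisible(path)
}

read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8) stop_io(sprintf("not a TIFF file: %s", path))
  endian <- if (rawToChar(raw[1:2]) == "II") "little" else if (
    rawToChar(raw[1:2]) == "MM") "big" else stop_io(
    sprintf("not a TIFF file: %s", path)
  )
  int_at <- function(off, size) {
    # size-4 reads are signed; fine for any realistic file offset (< 2^31)
    readBin(raw[(off + 1):(off + size)], "integer",
            size = size, endian = endian, signed = size == 4L)
  }
  if (int_at(2, 2) != 42L) stop_io(sprintf("not a TIFF file: %s", path))
  ifd <- int_at(4, 4)
  n_entries <- int_at(ifd, 2)
  tags <- list()
  for (i in seq_len(n_entries)) {
    base <- ifd + 2 + (i - 1) * 12
    tag <- int_at(base, 2)
    type <- int_at(base + 2, 2)
    count <- int_at(base + 4, 4)
    tsize <- if (type == 3L) 2L else 4L
    vals <- if (count * tsize <= 4) {
      vapply(seq_len(count), function(j) int_at(base + 8 + (j - 1) * tsize, tsize), 0L)
    } else {
      ptr <- int_at(base + 8, 4)
      vapply(seq_len(count), function(j) int_at(ptr + (j - 1) * tsize, tsize), 0L)
    }
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop_io(sprintf("TIFF tag %d missing in %s", tag, path))
      default
    } else {
      v
    }
  }
  w <- need(256)
  h <- need(257)
  if (any(need(258, 8L) != 8L)) stop_io("only 8-bit TIFF is supported")
  if (need(259, 1L) != 1L) stop_io("only uncompressed TIFF is supported")
  if (need(277, 1L) != 1L) stop_io("only single-sample grayscale TIFF is supported")
  offs <- need(273)
  counts <- need(279, h * w)
  bytes <- unlist(lapply(seq_along(offs), function(i) {
    as.integer(raw[(offs[i] + 1):(offs[i] + counts[i])])
  }))
  if (length(bytes) != h * w) stop_io(sprintf("truncated TIFF data in %s", path))
  matrix(bytes, nrow = h, ncol = w, byrow = TRUE)
}

# --- Cohort table ---

#' Read and validate a cohort table
#'
#' The cohort CSV links each clinical visit to its measured decimal
#' best-corrected visual acuity and the four en-face scans analysed by the
#' pipeline. Required columns: `visit_id`, `va_decimal`, `laterality`,
#' `path_scp3`, `path_scp6`, `path_dcp3`, `path_dcp6` (DCP paths may be empty
#' for SCP-only cohorts). Extra columns (e.g. `subgroup`, `patient_id`) are
#' carried through untouched.
#'
#' @param path CSV file path.
#' @return A `cohort_table` (a validated data frame, row order preserved).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("cohort file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop_validation(sprintf(
      "cannot parse cohort CSV %s: %s", path, conditionMessage(e)
    ))
  )
  as_cohort_table(df)
}

#' @rdname read_cohort
#' @param df A data frame already in memory.
#' @export
as_cohort_table <- function(df) {
  required <- c("visit_id", "va_decimal", "laterality",
                "path_scp3", "path_scp6", "path_dcp3", "path_dcp6")
  if (nrow(df) == 0) stop_validation("cohort table has no rows")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_validation(sprintf(
      "cohort table lacks required columns: %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  dup <- df$visit_id[duplicated(df$visit_id)]
  if (length(dup)) {
    stop_validation(sprintf(
      "duplicate visit_id in cohort: %s", paste(unique(dup), collapse = ", ")
    ))
  }
  bad <- which(!is.finite(df$va_decimal) | df$va_decimal < 0 | df$va_decimal > 1)
  if (length(bad)) {
    stop_validation(sprintf(
      "va_decimal outside [0, 1] in row %d (visit_id %s)",
      bad[1], df$visit_id[bad[1]]
    ))
  }
  if (!all(df$laterality %in% c("OD", "OS"))) {
    stop_validation("laterality must be \"OD\" or \"OS\" for every row")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}
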