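# Vessel segmentation: histogram thresholding and parallel thinning.

#' Otsu's automatic threshold for an angiogram
#'
#' Selects, from the 256-bin gray-level histogram, the threshold that best
#' separates background from flow signal in the discriminant-analysis sense:
#' the between-class variance \eqn{\sigma^2_b(t)} is maximized, which is
#' equivalent to maximizing the ratio criterion
#' \eqn{Q(t) = \sigma^2_b(t) / \sigma^2_w(t)} because the two always sum to
#' the (fixed) total image variance. Working with \eqn{\sigma^2_b} avoids a
#' division by zero when a candidate class is internally constant. Ties are
#' broken toward the smallest threshold, matching common reference
#' implementations.
#'
#' @param image An [octa_image], or a plain numeric matrix of whole-number
#'   intensities in `[0, 255]`.
#' @return An `otsu_result`: list with `threshold` (integer gray level; pixels
#'   strictly above it are foreground), `between_var`, `within_var`, and
#'   `criterion_q` (`Inf` when both classes are internally constant).
#' @seealso [binarize()]
#' @export
otsu_threshold <- function(image) {
  pix <- if (inherits(image, "octa_image")) image$pixels else image
  counts <- tabulate(as.integer(pix) + 1L, nbins = 256L)
  n <- sum(counts)
  levels <- 0:255
  if (sum(counts > 0L) < 2L) {
    stop_degenerate("image has fewer than 2 distinct gray levels; no threshold can partition it")
  }
  w0 <- cumsum(counts) / n
  mu_cum <- cumsum(counts * levels) / n
  mu_total <- mu_cum[256]
  w1 <- 1 - w0
  # between-class variance at every candidate t = 0..255 (class split <= t / > t)
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 256)
  sigma_b[valid] <- (mu_total * w0[valid] - mu_cum[valid])^2 /
    (w0[valid] * w1[valid])
  t_idx <- which.max(sigma_b) # first maximum = smallest threshold
  total_var <- sum(counts * (levels - mu_total)^2) / n
  between <- sigma_b[t_idx]
  structure(
    list(
      threshold = levels[t_idx],
      between_var = between,
      within_var = total_var - between,
      criterion_q = if (total_var - between > 0) between / (total_var - between) else Inf,
      total_var = total_var
    ),
    class = "otsu_result"
  )
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf(
    "<otsu_result> t = %d  (between %.3f / within %.3f, Q = %.4g)\n",
    x$threshold, x$between_var, x$within_var, x$criterion_q
  ))
  invisible(x)
}

#' Binarize an angiogram at a gray-level threshold
#'
#' OCTA flow signal is bright, so foreground (vessel) pixels are those with
#' intensity strictly greater than `t`.
#'
#' @param image An [octa_image] or numeric matrix.
#' @param t Gray level in `[0, 255]`; typically `otsu_threshold(image)$threshold`.
#' @return An integer 0/1 matrix of the same shape.
#' @export
binarize <- function(image, t) {
  if (!is.numeric(t) || length(t) != 1 || t < 0 || t > 255) {
    stop_validation("threshold `t` must be a single gray level in [0, 255]")
  }
  pix <- if (inherits(image, "octa_image")) image$pixels else image
  as_binary((pix > t) * 1L)
}

#' Reduce a binary vessel mask to a one-pixel-wide skeleton
#'
#' Classic two-subiteration parallel thinning (Zhang–Suen): contour pixels are
#' deleted simultaneously in alternating south-east / north-west passes, each
#' pass keeping pixels whose removal would break 8-connectivity (transition
#' count != 1) or shorten a line end (neighbor count outside 2..6), until the
#' image stops changing. The result is idempotent and contained in the input
#' mask; 8-connected components of three or more pixels survive as components.
#'
#' @param mask Integer/numeric 0/1 matrix.
#' @return An integer 0/1 matrix: the skeleton.
#' @export
skeletonize <- function(mask) {
  if (!is_binary_matrix(mask)) {
    stop_validation("`mask` must be a binary 0/1 matrix")
  }
  m <- as_binary(mask * 1L)
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- nb_shift(m, -1L, 0L)
      p3 <- nb_shift(m, -1L, 1L)
      p4 <- nb_shift(m, 0L, 1L)
      p5 <- nb_shift(m, 1L, 1L)
      p6 <- nb_shift(m, 1L, 0L)
      p7 <- nb_shift(m, 1L, -1L)
      p8 <- nb_shift(m, 0L, -1L)
      p9 <- nb_shift(m, -1L, -1L)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0L & p3 == 1L) + (p3 == 0L & p4 == 1L) +
        (p4 == 0L & p5 == 1L) + (p5 == 0L & p6 == 1L) +
        (p6 == 0L & p7 == 1L) + (p7 == 0L & p8 == 1L) +
        (p8 == 0L & p9 == 1L) + (p9 == 0L & p2 == 1L)
      del <- m == 1L & b >= 2L & b <= 6L & a == 1L
      if (pass == 1L) {
        del <- del & p2 * p4 * p6 == 0L & p4 * p6 * p8 == 0L
      } else {
        del <- del & p2 * p4 * p8 == 0L & p2 * p6 * p8 == 0L
      }
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}
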