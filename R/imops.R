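# Low-level raster operations. No image-processing dependency is assumed:
# everything works on plain 0/1 or grayscale matrices (row 1 = top of image).
# These are deliberately small, vectorized building blocks for the
# segmentation pipeline; they are internal but unit-tested through it.

# Value of the neighbor at offset (dr, dc) for every pixel; out-of-image
# neighbors read as `fill`.
nb_shift <- function(m, dr, dc, fill = 0) {
  h <- nrow(m)
  w <- ncol(m)
  out <- matrix(fill, h, w)
  r1 <- max(1L, 1L - dr)
  r2 <- min(h, h - dr)
  c1 <- max(1L, 1L - dc)
  c2 <- min(w, w - dc)
  if (r1 <= r2 && c1 <= c2) {
    out[r1:r2, c1:c2] <- m[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc)]
  }
  out
}

# Offsets (dr, dc) of a digital disk of radius r (Euclidean, <= r).
disk_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
}

binary_dilate <- function(mask, radius = 1) {
  off <- disk_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(off))) {
    if (off$dr[i] == 0 && off$dc[i] == 0) next
    out <- pmax(out, nb_shift(mask, off$dr[i], off$dc[i], fill = 0))
  }
  out
}

binary_erode <- function(mask, radius = 1, pad = 1) {
  off <- disk_offsets(radius)
  out <- mask
  for (i in seq_len(nrow(off))) {
    if (off$dr[i] == 0 && off$dc[i] == 0) next
    out <- pmin(out, nb_shift(mask, off$dr[i], off$dc[i], fill = pad))
  }
  out
}

# Closing seals gaps narrower than the structuring element. Erosion pads with
# foreground so that closing never eats the image border.
binary_close <- function(mask, radius = 2) {
  binary_erode(binary_dilate(mask, radius), radius, pad = 1)
}

# Separable Gaussian smoothing with edge renormalization (truncated kernel
# weights are rescaled near the borders, so flat regions stay flat).
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) {
    return(m)
  }
  r <- as.integer(ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  band <- function(n) {
    b <- matrix(0, n, n)
    for (i in seq_len(2L * r + 1L)) {
      off <- i - r - 1L
      idx <- seq_len(n)
      src <- idx + off
      ok <- src >= 1L & src <= n
      b[cbind(idx[ok], src[ok])] <- b[cbind(idx[ok], src[ok])] + k[i]
    }
    b / rowSums(b)
  }
  br <- band(nrow(m))
  bc <- band(ncol(m))
  br %*% m %*% t(bc)
}

# Connected-component labeling via the pixel-adjacency graph. Returns an
# integer matrix: 0 = background, 1..n = component id.
label_components <- function(mask, connectivity = 8) {
  h <- nrow(mask)
  idx <- which(mask == 1)
  lab <- matrix(0L, h, ncol(mask))
  if (length(idx) == 0L) {
    return(lab)
  }
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) {
    offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  }
  rank <- match(seq_len(h * ncol(mask)), idx, nomatch = 0L)
  from <- integer(0)
  to <- integer(0)
  for (o in offs) {
    ok <- r + o[1] >= 1L & r + o[1] <= h & cc + o[2] >= 1L & cc + o[2] <= ncol(mask)
    nidx <- idx[ok] + o[1] + o[2] * h
    hit <- mask[nidx] == 1
    from <- c(from, rank[idx[ok][hit]])
    to <- c(to, rank[nidx[hit]])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

count_components <- function(mask, connectivity = 8, min_size = 1) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) {
    return(0L)
  }
  sizes <- tabulate(lab[lab > 0L])
  sum(sizes >= min_size)
}

# Fill interior holes: background components (4-connected) that do not touch
# the image border become foreground.
fill_holes <- function(mask) {
  bg <- 1L - mask
  lab <- label_components(bg, connectivity = 4)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0L]
  hole <- bg == 1L & !(lab %in% border)
  out <- mask
  out[hole] <- 1L
  out
}

# Pixel-center distance (in pixels) of every pixel to a point given in
# continuous image coordinates (row 0 = top edge; pixel (i, j) of the matrix
# has its center at (i - 0.5, j - 0.5)).
pixel_center_dist <- function(h, w, center) {
  rows <- matrix(seq_len(h) - 0.5, h, w)
  cols <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  sqrt((rows - center[1])^2 + (cols - center[2])^2)
}

# Perimeter estimate of a binary region: number of exposed pixel edges
# (foreground/background 4-adjacent pairs, image border counts as exposed).
region_perimeter <- function(mask) {
  p <- 0
  for (o in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    p <- p + sum(mask == 1 & nb_shift(mask, o[1], o[2], fill = 0) == 0)
  }
  p
}
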