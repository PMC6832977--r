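# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths wherever they are used to check one.

# Brute-force Otsu: try all 256 candidate thresholds, compute the
# between-class variance from first principles, take the smallest argmax.
oracle_otsu <- function(pix) {
  v <- as.numeric(pix)
  best_t <- NA_integer_
  best_b <- -Inf
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    w1 <- 1 - w0
    b <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (b > best_b + 1e-12) {
      best_b <- b
      best_t <- t
    }
  }
  list(threshold = best_t, between_var = best_b)
}

pop_var <- function(v) mean((v - mean(v))^2)

# Stack-based flood fill component counter (independent of igraph).
oracle_count_components <- function(mask, min_size = 1) {
  h <- nrow(mask)
  w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (start in which(mask == 1)) {
    if (seen[start]) next
    stack <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1L
      pr <- ((p - 1L) %% h) + 1L
      pc <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- pr + dr
        c2 <- pc + dc
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
          q <- (c2 - 1L) * h + r2
          if (mask[q] == 1 && !seen[q]) {
            seen[q] <- TRUE
            stack <- c(stack, q)
          }
        }
      }
    }
    if (size >= min_size) count <- count + 1L
  }
  count
}

has_2x2_block <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  any(m[-h, -w] & m[-1, -w] & m[-h, -1] & m[-1, -1])
}

make_image <- function(pix, extent_mm = 3, plexus = "SCP", laterality = "OD",
                       visit_id = "t") {
  octa_image(pix, extent_mm, plexus, laterality, visit_id)
}

# A quick bimodal random image.
random_bimodal <- function(n, seed) {
  set.seed(seed)
  pix <- matrix(sample(0:60, n * n, replace = TRUE), n, n)
  vessel <- matrix(runif(n * n) < 0.3, n, n)
  pix[vessel] <- sample(180:255, sum(vessel), replace = TRUE)
  pix
}

# Build a full synthetic visit (four scans) and its ground-truth densities.
make_synthetic_visit <- function(seed, size_px = 96, noise_sd = 0,
                                 laterality = "OD", visit_id = "v1") {
  scans <- list(
    scp3 = list(plexus = "SCP", extent = 3, faz = 0.3),
    scp6 = list(plexus = "SCP", extent = 6, faz = 0),
    dcp3 = list(plexus = "DCP", extent = 3, faz = 0),
    dcp6 = list(plexus = "DCP", extent = 6, faz = 0)
  )
  out <- list(images = list(), truth = list())
  for (nm in names(scans)) {
    s <- scans[[nm]]
    gen <- generate_vessel_image(vessel_fixture_spec(
      size_px = size_px, extent_mm = s$extent, faz_radius_mm = s$faz,
      noise_sd = noise_sd, plexus = s$plexus, laterality = laterality,
      visit_id = visit_id, seed = seed + match(nm, names(scans))
    ))
    out$images[[nm]] <- gen$image
    out$truth[[nm]] <- gen$truth
  }
  out
}
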