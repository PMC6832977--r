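# Biomarker feature assembly, epsilon support-vector regression, and the
# cross-validated visual-acuity evaluation harness.

#' Canonical feature names for an experiment
#'
#' @param experiment `"scp_only"` (11 features: FAZ area + 5 superficial zone
#'   densities at each scan size) or `"scp_dcp"` (21: adds the 10 deep-plexus
#'   densities).
#' @return Character vector of feature names, in the fixed model order.
#' @export
feature_names <- function(experiment = c("scp_dcp", "scp_only")) {
  experiment <- match.arg(experiment)
  nm <- c("faz_area_scp3_mm2",
          paste0("vd_scp3_", ZONES), paste0("vd_scp6_", ZONES))
  if (experiment == "scp_dcp") {
    nm <- c(nm, paste0("vd_dcp3_", ZONES), paste0("vd_dcp6_", ZONES))
  }
  nm
}

#' Flatten a visit record into an ordered feature vector
#'
#' Order is fixed and documented: FAZ area, then the five zone densities
#' (foveal, upper, nasal, temporal, lower) of the superficial 3 mm then 6 mm
#' scans and, for `"scp_dcp"`, the deep 3 mm then 6 mm scans.
#'
#' @param record A `visit_record` (see [analyze_visit()]).
#' @param experiment `"scp_dcp"` or `"scp_only"`.
#' @return Named numeric vector of length 21 or 11.
#' @export
assemble_features <- function(record, experiment = c("scp_dcp", "scp_only")) {
  experiment <- match.arg(experiment)
  get_vd <- function(plex, ext) {
    v <- record$vd[[plex]][[ext]]
    if (is.null(v)) {
      stop_validation(sprintf(
        "record %s lacks %s %s mm densities required by experiment \"%s\"",
        record$visit_id, plex, ext, experiment
      ))
    }
    unlist(v[ZONES])
  }
  x <- c(record$faz_area_scp3_mm2, get_vd("SCP", "3"), get_vd("SCP", "6"))
  if (experiment == "scp_dcp") {
    x <- c(x, get_vd("DCP", "3"), get_vd("DCP", "6"))
  }
  names(x) <- feature_names(experiment)
  if (anyNA(x) || !all(is.finite(x))) {
    stop_validation(sprintf(
      "record %s has missing or non-finite biomarkers", record$visit_id
    ))
  }
  x
}

#' Epsilon-SVR settings
#'
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost Box constraint C.
#' @param epsilon Half-width of the insensitive tube, on the decimal VA scale
#'   (0.05 is half a decimal acuity line).
#' @param gamma RBF kernel width; default `1/p`.
#' @param clip Range predictions are clipped to (decimal VA lives in `[0, 1]`).
#' @return An `svr_config` list.
#' @export
svr_config <- function(kernel = c("linear", "rbf"), cost = 1.0,
                       epsilon = 0.05, gamma = NULL, clip = c(0, 1)) {
  kernel <- match.arg(kernel)
  structure(
    list(kernel = kernel, cost = cost, epsilon = epsilon, gamma = gamma,
         clip = clip),
    class = "svr_config"
  )
}

kernel_matrix <- function(a, b, config) {
  if (config$kernel == "linear") {
    return(a %*% t(b))
  }
  gamma <- config$gamma %||% (1 / ncol(a))
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  exp(-gamma * pmax(d2, 0))
}

#' Fit epsilon support-vector regression on standardized biomarkers
#'
#' Features are z-scored with training-set statistics (constant features get
#' unit scale) and the standard epsilon-SVR dual is solved exactly as a
#' quadratic program. Predictions are clipped to the decimal VA range.
#'
#' @param x Numeric matrix (visits x features) or list of feature vectors.
#' @param y Decimal VA targets in `[0, 1]`.
#' @param config An [svr_config()].
#' @return An `svr_model` with a [predict][predict.svr_model] method.
#' @export
fit_svr <- function(x, y, config = svr_config()) {
  if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  n <- nrow(x)
  if (n != length(y)) stop_validation("nrow(x) must equal length(y)")
  if (n < 10) {
    stop_insufficient(sprintf("need at least 10 samples to fit SVR, got %d", n))
  }
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  z <- sweep(sweep(x, 2, mu), 2, sd, "/")
  k <- kernel_matrix(z, z, config)
  eps <- config$epsilon
  cc <- config$cost
  dmat <- rbind(cbind(k, -k), cbind(-k, k))
  ridge <- 1e-8 * max(1, mean(diag(k)))
  diag(dmat) <- diag(dmat) + ridge
  dvec <- c(y - eps, -y - eps)
  m2 <- 2L * n
  amat <- cbind(c(rep(1, n), rep(-1, n)), diag(m2), -diag(m2))
  bvec <- c(0, rep(0, m2), rep(-cc, m2))
  sol <- quadprog::solve.QP(dmat, dvec, amat, bvec, meq = 1)$solution
  alpha <- pmin(pmax(sol[1:n], 0), cc)
  alpha_star <- pmin(pmax(sol[(n + 1):m2], 0), cc)
  coef <- alpha - alpha_star
  g <- drop(k %*% coef)
  tol <- 1e-7 * cc
  up <- alpha > tol & alpha < cc - tol
  lo <- alpha_star > tol & alpha_star < cc - tol
  b <- if (any(up) || any(lo)) {
    mean(c(y[up] - eps - g[up], y[lo] + eps - g[lo]))
  } else {
    mean(y - g)
  }
  structure(
    list(z = z, coef = coef, b = b, mu = mu, sd = sd, config = config,
         feature_names = colnames(x)),
    class = "svr_model"
  )
}

#' Predict decimal VA for new feature vectors
#'
#' @param object An `svr_model`.
#' @param newdata Matrix or list of feature vectors in the training order.
#' @param ... Unused.
#' @return Numeric predictions, clipped to the configured VA range.
#' @export
predict.svr_model <- function(object, newdata, ...) {
  if (is.list(newdata) && !is.matrix(newdata)) newdata <- do.call(rbind, newdata)
  newdata <- as.matrix(newdata)
  z <- sweep(sweep(newdata, 2, object$mu), 2, object$sd, "/")
  f <- drop(kernel_matrix(z, object$z, object$config) %*% object$coef) + object$b
  pmin(pmax(f, object$config$clip[1]), object$config$clip[2])
}

#' Pearson correlation with the t-transform p-value
#'
#' @param a,b Equal-length numeric vectors (length >= 3, neither constant).
#' @return List with `r` and two-sided `p`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop_validation("vectors differ in length")
  n <- length(a)
  if (n < 3) stop_validation("need at least 3 paired observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop_validation("correlation is undefined for a constant vector")
  }
  r <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p)
}

#' Mean squared error on the decimal VA scale
#'
#' @param est,real Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse <- function(est, real) {
  if (length(est) != length(real) || length(est) < 1) {
    stop_validation("`est` and `real` must be non-empty and of equal length")
  }
  mean((est - real)^2)
}

#' Convert decimal visual acuity to logMAR
#'
#' @param va Decimal VA in `(0, 1]`.
#' @return `-log10(va)`.
#' @export
decimal_to_logmar <- function(va) {
  if (any(va <= 0)) stop_validation("decimal VA must be > 0 to convert to logMAR")
  -log10(va)
}

# Fold assignment: seeded uniform shuffle into k near-equal folds (sizes
# differ by at most one; the first n %% k folds take the extra sample).
# With grouping, whole groups are assigned greedily to the smallest fold.
make_folds <- function(n, k, seed, groups = NULL) {
  with_seed(seed, {
    fold <- integer(n)
    if (is.null(groups)) {
      sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
      fold[sample.int(n)] <- rep(seq_len(k), times = sizes)
    } else {
      gs <- unique(groups)
      gs <- gs[sample.int(length(gs))]
      load <- numeric(k)
      for (g in gs) {
        j <- which.min(load)
        fold[groups == g] <- j
        load[j] <- load[j] + sum(groups == g)
      }
    }
    fold
  })
}

#' K-fold cross-validated VA estimation
#'
#' Shuffles the visits with the given seed into `k` near-equal folds, fits
#' the SVR on each training split (standardization statistics are recomputed
#' on the training folds only), pools the held-out predictions, and reports
#' the Pearson correlation, its p-value, and the MSE on the decimal scale.
#' The model is also refit on all visits and its in-sample MSE reported
#' (`train_mse`), mirroring the optimistic whole-sample analysis that a
#' train/test split is meant to guard against.
#'
#' @param records List of `visit_record`s carrying `real_va_decimal`.
#' @param experiment `"scp_dcp"` or `"scp_only"`.
#' @param k Number of folds.
#' @param seed Integer seed for the fold shuffle.
#' @param svr An [svr_config()].
#' @param group_by_patient If `TRUE` and records carry a `patient_id` field,
#'   all visits of a patient land in the same fold (leakage-safe variant).
#' @return A `cv_result`: `predictions` data frame (visit_id, real_va,
#'   estimated_va, fold), `pearson_r`, `p_value`, `mse_decimal`, `fold_mse`,
#'   `train_mse`, `train_predictions`, `fold` assignment vector.
#' @export
cross_validate <- function(records, experiment = c("scp_dcp", "scp_only"),
                           k = 5, seed = 1, svr = svr_config(),
                           group_by_patient = FALSE) {
  experiment <- match.arg(experiment)
  n <- length(records)
  if (n < k * 3) {
    stop_insufficient(sprintf(
      "need at least %d records for %d-fold cross-validation, got %d", k * 3, k, n
    ))
  }
  x <- do.call(rbind, lapply(records, assemble_features, experiment = experiment))
  y <- vapply(records, function(r) r$real_va_decimal, numeric(1))
  if (anyNA(y) || any(y < 0 | y > 1)) {
    stop_validation("every record needs real_va_decimal in [0, 1]")
  }
  groups <- NULL
  if (group_by_patient) {
    groups <- vapply(records, function(r) r$patient_id %||% r$visit_id, "")
  }
  fold <- make_folds(n, k, seed, groups)
  est <- numeric(n)
  for (j in seq_len(k)) {
    test <- fold == j
    model <- fit_svr(x[!test, , drop = FALSE], y[!test], svr)
    est[test] <- predict(model, x[test, , drop = FALSE])
  }
  pr <- pearson_r(est, y)
  full <- fit_svr(x, y, svr)
  train_est <- predict(full, x)
  structure(
    list(
      predictions = data.frame(
        visit_id = vapply(records, function(r) r$visit_id, ""),
        real_va = y, estimated_va = est, fold = fold,
        stringsAsFactors = FALSE
      ),
      fold = fold,
      pearson_r = pr$r,
      p_value = pr$p,
      mse_decimal = mse(est, y),
      fold_mse = vapply(seq_len(k), function(j) mse(est[fold == j], y[fold == j]),
                        numeric(1)),
      train_mse = mse(train_est, y),
      train_predictions = train_est,
      experiment = experiment, k = k, seed = seed
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s, %d-fold (seed %d): r = %.3f (p = %.3g), MSE = %.4f (train %.4f)\n",
    x$experiment, x$k, x$seed, x$pearson_r, x$p_value, x$mse_decimal, x$train_mse
  ))
  invisible(x)
}
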