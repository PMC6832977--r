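# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random stream set to `seed`, then restores the
#' caller's stream, so library calls never perturb user-level reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

abort_octava <- function(msg, class) {
  stop(structure(
    class = c(class, "octava_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) abort_octava(msg, "octava_validation_error")
stop_io <- function(msg) abort_octava(msg, "octava_io_error")
stop_degenerate <- function(msg) abort_octava(msg, "octava_degenerate_input_error")
stop_detection <- function(msg) abort_octava(msg, "octava_detection_failure")
stop_insufficient <- function(msg) abort_octava(msg, "octava_insufficient_data_error")

is_binary_matrix <- function(m) {
  is.matrix(m) && is.numeric(m) && all(m %in% c(0, 1))
}

as_binary <- function(m) {
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
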