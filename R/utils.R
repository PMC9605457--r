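# internal helpers shared across modules

#' @keywords internal
abort_pv <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "pulsevar_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# wrap angles in degrees to (-180, 180]
#' @keywords internal
wrap_deg <- function(x) {
  y <- x %% 360
  y[y > 180] <- y[y > 180] - 360
  y
}

# run expr with a locally-seeded RNG, restoring the caller's stream
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# sample SD (n - 1 denominator); beat counts are small so the correction matters
#' @keywords internal
cv_pct <- function(x) {
  m <- mean(x)
  if (m == 0) return(0)
  100 * stats::sd(x) / m
}
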