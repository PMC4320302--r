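# Classed error conditions so callers (and the CLI) can map failures to
# meaningful exit codes instead of string-matching messages.

msi_abort <- function(message, class, call = sys.call(-1), ...) {
  cnd <- structure(
    class = c(class, "msi_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cnd)
}

#' @noRd
domain_error <- function(message, ...) {
  msi_abort(message, "msi_domain_error", call = sys.call(-1), ...)
}

#' @noRd
io_error <- function(message, ...) {
  msi_abort(message, "msi_io_error", call = sys.call(-1), ...)
}

#' @noRd
config_error <- function(message, ...) {
  msi_abort(message, "msi_config_error", call = sys.call(-1), ...)
}

#' @noRd
numerical_error <- function(message, ...) {
  msi_abort(message, "msi_numerical_error", call = sys.call(-1), ...)
}

# Evaluate `expr` under a temporary, fully specified RNG state and restore
# whatever state the caller had. All randomness in the package goes through
# this helper so results are reproducible bit-for-bit from recorded seeds.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    domain_error("`seed` must be a single non-missing number")
  }
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Map an arbitrary integer-ish seed plus a stream index onto [0, 2^31 - 2]
# with a fixed multiplier (48271, the MINSTD constant). Used to derive
# independent, reproducible sub-seeds (basis rows, restarts, repeats).
derive_seed <- function(seed, index) {
  base <- ((as.numeric(seed) %% 2147483647) + 2147483647) %% 2147483647
  as.integer((base + as.numeric(index) * 48271) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
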