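# internal helpers

# Run `code` with the RNG seeded to `seed`, restoring any pre-existing
# global RNG state afterwards so simulation never perturbs the caller's stream.
with_preserved_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed) ||
      seed != trunc(seed)) {
    abort("`seed` must be a single integer.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero (the convention of the printed trial tables;
# base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(paste0("`", name, "` must be finite and numeric."))
  }
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  check_finite(x, name)
  bad <- if (strict) any(x <= 0) else any(x < 0)
  if (bad) {
    abort(paste0("`", name, "` must be ", if (strict) "> 0" else ">= 0", "."))
  }
  invisible(x)
}
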