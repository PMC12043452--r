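`%||%` <- function(x, y) if (is.null(x)) y else x

# Run downstream code with a reproducible, isolated RNG state: the global
# .Random.seed is restored on exit so package functions never perturb the
# caller's stream.
local_seed <- function(seed, env = parent.frame()) {
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  defer <- function() {
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
  do.call(on.exit, list(substitute(defer(), list(defer = defer)), add = TRUE),
          envir = env)
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

# Deterministic per-unit substream seed below 2^31, derived from a master
# seed and an index (used for virtual patients and spatial tie-breaks).
substream_seed <- function(master, index) {
  as.integer((as.double(master) * 48271 + as.double(index) * 16807 + 1) %%
               2147483647)
}
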