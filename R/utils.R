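# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_("`%s` must be a single finite number", name)
  if (strict && x <= lower) stop_("`%s` must be > %g", name, lower)
  if (!strict && x < lower) stop_("`%s` must be >= %g", name, lower)
  as.numeric(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic derivation of per-subject / per-stage seeds from a global
# seed; stays below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + 7919 * k) %% 2147483629 + 1)
}

# voxel index matrix (n x 3) -> linear index for a given grid
vox_linear <- function(ijk, dims) {
  (ijk[, 3L] - 1L) * dims[1L] * dims[2L] + (ijk[, 2L] - 1L) * dims[1L] + ijk[, 1L]
}

in_grid <- function(ijk, dims) {
  ijk[, 1L] >= 1L & ijk[, 1L] <= dims[1L] &
  ijk[, 2L] >= 1L & ijk[, 2L] <= dims[2L] &
  ijk[, 3L] >= 1L & ijk[, 3L] <= dims[3L]
}
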