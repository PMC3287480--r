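# Internal helpers shared across the pipeline.

# Fluxes with magnitude below this are treated as zero everywhere downstream
# (activity calls, flux-pattern ties).
FMB_ZERO_TOL <- 1e-6

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed from a master seed and a stream label, kept below
# 2^31 so it is always a valid R integer.
derive_seed <- function(master_seed, ...) {
  label <- paste(c(master_seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  as.integer(h + 1L)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_fmb <- function(...) stop(sprintf(...), call. = FALSE)
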