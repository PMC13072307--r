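# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic child seed i of a parent seed, kept below 2^31.
derive_seed <- function(seed, i) {
  (as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483647
}

stop_ovm <- function(...) stop(sprintf(...), call. = FALSE)

warn_ovm <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# largest connected component (6-connectivity) of a 3D logical array
largest_component <- function(mask) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  labels <- .label_components_3d(as.logical(mask), as.integer(dim(mask)))
  out <- labels == 1L
  dim(out) <- dim(mask)
  out
}
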