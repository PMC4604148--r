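# internal helpers shared across modules

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. Keeps simulation functions referentially
# transparent: the same (config, seed) always yields the same arrays.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific 31-bit seed from a master seed (R seeds are 32-bit
# signed integers, so keep everything below 2^31).
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream) * 16807) %% 2147483647)
}

stopifnot_image <- function(x, name = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(name, " must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(x)))
    stop(name, " contains non-finite pixels", call. = FALSE)
  invisible(x)
}

check_roi <- function(roi, dim_img) {
  if (!is.matrix(roi) || !is.logical(roi))
    stop("roi must be a logical matrix", call. = FALSE)
  if (!identical(dim(roi), dim_img))
    stop("roi dimensions do not match the image", call. = FALSE)
  if (!any(roi))
    stop("roi is empty", call. = FALSE)
  invisible(roi)
}
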