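# Internal helpers: classed conditions, seeded evaluation, small hash.

`%||%` <- function(a, b) if (is.null(a)) b else a

# All user-facing failures carry a class so callers (and the pipeline driver)
# can distinguish configuration mistakes from computation failures.
.fail <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("dimergate_", class, "_error"), "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards. Guarantees bitwise reproducibility without side effects.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used to stamp outputs with a fingerprint of the run configuration.
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256                      # xor only touches the low byte
    h <- (h - lo) + bitwXor(as.integer(lo), b)
    # 32-bit modular multiply by 16777619, split to stay within double precision
    hi <- h %/% 65536
    lo2 <- h %% 65536
    h <- (lo2 * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.is_coord_matrix <- function(x) is.matrix(x) && is.numeric(x) && ncol(x) == 3

.assert_coords <- function(x, what = "coordinates") {
  if (!.is_coord_matrix(x))
    .fail(sprintf("%s must be an n x 3 numeric matrix", what), "shape")
  if (!all(is.finite(x)))
    .fail(sprintf("%s contain non-finite values", what), "consistency")
  invisible(x)
}

.vnorm <- function(v) sqrt(sum(v * v))

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rotation matrix about unit axis by angle (radians), Rodrigues form.
.rot_about <- function(axis, theta) {
  u <- axis / .vnorm(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}
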