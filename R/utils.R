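# Internal helpers shared across modules.

is_power_of_two <- function(x) {
  x == round(x) && x >= 1 && bitwAnd(as.integer(x), as.integer(x) - 1L) == 0L
}

#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# Deterministic 32-bit seed derivation. All multipliers are small enough that
# the arithmetic stays exact in doubles (< 2^53) before the modulus.
derive_seed <- function(seed, stream, index = 0) {
  stream_id <- sum(utf8ToInt(as.character(stream))) %% 1009
  v <- (as.numeric(seed) %% 2147483647) * 69069 +
    stream_id * 99991 + as.numeric(index) * 7919 + 12345
  as.integer(v %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# FNV-1a 32-bit hash of a character scalar; used for lightweight provenance
# tags in manifests (not cryptographic).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  # 32-bit modular multiply, exact in doubles via 16-bit split
  mul32 <- function(h, m) {
    ((h %% 65536) * m + (((h %/% 65536) * m) %% 65536) * 65536) %% 4294967296
  }
  h <- 2166136261
  for (b in bytes) {
    # xor with the byte affects only the low 8 bits; keep h in [0, 2^32)
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- mul32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(x) {
  fnv1a32(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
}

# image (H x W matrix) <-> column-major vector conventions
vec_image <- function(img) as.vector(img)
unvec_image <- function(v, n) matrix(v, n, n)

assert_square_image <- function(f, what = "image") {
  if (!is.matrix(f) || nrow(f) != ncol(f)) {
    stop(sprintf("%s must be a square matrix", what), call. = FALSE)
  }
  if (!all(is.finite(f))) stop(sprintf("%s contains non-finite values", what), call. = FALSE)
  invisible(f)
}
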