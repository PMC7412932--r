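# Internal helpers: seed derivation, hashing, small assertions.

#' Derive a deterministic sub-seed from a master seed
#'
#' Mixes a master seed with stage labels (strings or integers) into a new
#' seed below 2^31, so pipeline stages can be re-run in isolation while the
#' whole run stays reproducible from one number.
#'
#' @param seed Master seed (single integer).
#' @param ... Stage labels: character strings and/or integers.
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "cohort", 3L)
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  mod <- 2147483647 # 2^31 - 1, keeps arithmetic exact in doubles
  h <- as.double(abs(as.integer(seed))) %% mod
  for (p in list(...)) {
    vals <- if (is.character(p)) utf8ToInt(p) else as.double(p)
    for (v in vals) h <- (h * 69069 + v + 1) %% mod
  }
  as.integer(h)
}

# Polynomial rolling hash of a string (two lanes -> 16 hex digits); used to
# stamp outputs with a config hash. Not cryptographic, just a stable fingerprint.
text_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  m <- 2147483647
  h1 <- 17; h2 <- 9176
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% m
    h2 <- (h2 * 131 + b) %% m
  }
  sprintf("%08x%08x", h1, h2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a numeric vector/matrix losslessly for text output.
num_chr <- function(x) sprintf("%.17g", x)

stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop2(sprintf("`%s` must be a single finite number in [%s, %s]",
                  name, format(lower), format(upper)))
  invisible(x)
}
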