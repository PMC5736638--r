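#' @keywords internal
"_PACKAGE"

# Deterministic derivation of stream seeds from one root seed plus a string
# tag (stage name, dataset id, set size ...). Plain polynomial hash kept
# below 2^31 so the result is a valid R integer seed.
derive_seed <- function(root, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- as.double(root %% 2147483647L)
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147483647
  as.integer(h)
}

# local RNG scope: run expr under a given seed without disturbing the
# caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
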