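# Deterministic seed derivation so that every stochastic operation can run on
# its own reproducible stream derived from one user-facing seed.

# modular product with m < 2^31; exact in double arithmetic
.mulmod <- function(a, b, m) {
  lo <- b %% 65536L
  hi <- (b - lo) / 65536L
  (((a * hi) %% m) * 65536 + a * lo) %% m
}

.MOD <- 2147483629 # prime below 2^31

.hash_one <- function(h, x, m) {
  if (is.character(x)) {
    for (v in utf8ToInt(paste(x, collapse = "\u1f"))) {
      h <- (.mulmod(h, 65599, m) + v) %% m
    }
  } else {
    for (v in as.numeric(x)) {
      v <- abs(v) %% m
      h <- (.mulmod(h, 65599, m) + v) %% m
    }
  }
  h
}

#' Derive a reproducible child seed
#'
#' Combines a master seed with arbitrary tags (strings, integers) into a new
#' seed in `[1, 2^31 - 2]`. Used throughout the package so that independent
#' operations draw from independent, order-insensitive streams.
#'
#' @param seed Integer master seed.
#' @param ... Tags (character or numeric scalars/vectors) naming the stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  h <- (as.numeric(seed) %% .MOD)
  for (x in list(...)) h <- .hash_one(h, x, .MOD)
  as.integer(h %% (.MOD - 2) + 1)
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# vectorised counter-based uniform hash on (seed, i, j) -> [0, 1); used where a
# per-(individual, site) draw must not depend on site insertion order
hash_unit <- function(seed, i, j) {
  m <- .MOD
  h <- (as.numeric(seed) + .mulmod((i %% m), 2654435761 %% m, m)) %% m
  h <- (.mulmod(h, 65599, m) + (j %% m)) %% m
  h <- .mulmod(h, 48271, m)
  h <- .mulmod(h, 69621, m)
  h / m
}
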