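# Internal helpers: classed error conditions and scoped RNG.

e2d_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "e2d_error")))
}

#' @useDynLib e2dseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Every deterministic contract in the package
# (phantoms, cohorts, splits, weight init, training) goes through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Fan a master seed out into named substreams so that components (split,
# sampler, init, ...) are independently reproducible. Polynomial rolling
# hash over the substream name, kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, ...) {
  key <- utf8ToInt(paste(c(...), collapse = "/"))
  h <- as.numeric(seed) %% 2147483647
  for (b in key) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
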