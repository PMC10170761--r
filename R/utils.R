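#' @importFrom stats cor median pnorm pwilcox rlnorm rnorm rpois runif sd
#'   setNames t.test var
#' @importFrom utils read.delim write.table packageVersion
NULL

# Derive a reproducible 31-bit seed for a named generator stream from a
# global seed, so that adding a generator never perturbs the others.
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded from (seed, name),
# restoring the caller's RNG state afterwards.
with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, name))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
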