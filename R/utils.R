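# Internal helpers shared across modules.

# Chromosome labels in karyotype order.
CHROMOSOMES <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                 "IX", "X", "XI", "XII", "XIII", "XIV", "XV", "XVI")

ORIGIN_LEVELS <- c("BY", "3S")

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# origin codes: 0 = BY, 1 = 3S
origin_label <- function(x) ORIGIN_LEVELS[x + 1L]

origin_code <- function(x) {
  m <- match(x, ORIGIN_LEVELS)
  if (anyNA(m)) stopf("origins must be 'BY' or '3S'")
  m - 1L
}
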