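# Shared small helpers: deterministic hashing, rounding, seeded evaluation,
# lightweight logging.

# Proton mass used for [M+H]+ / neutral-mass arithmetic (Da).
PROTON_MASS <- 1.007276466

#' Round half away from zero
#'
#' Unit-resolution rounding used to index biotransformation rules by their
#' mass delta: `round_half_away(-2.5)` is `-3`, `round_half_away(2.5)` is `3`,
#' so +/- 0.5 Da boundary cases are deterministic (base R `round()` rounds
#' half to even).
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @export
#' @examples
#' round_half_away(c(-15.02, -2.4, 2.5, -2.5))
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Deterministic, platform-stable hash of a string into (0, 1].  Used for
# pseudo-fragment peak intensities; a polynomial rolling hash mod a prime
# keeps every intermediate exactly representable in doubles.
str_hash01 <- function(s) {
  vapply(s, function(one) {
    h <- 0
    for (b in utf8ToInt(one)) h <- (h * 31 + b) %% 1000003
    (h + 1) / 1000004
  }, numeric(1), USE.NAMES = FALSE)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards.
with_seed_local <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

bam_log <- function(stage, fmt, ...) {
  message(sprintf("[bamanno:%s] %s", stage, sprintf(fmt, ...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ..., class = NULL) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "bam_error"),
                      call = sys.call(-1)))
}
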