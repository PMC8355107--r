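# Internal helpers shared across stages.

# Deterministic sub-seed for a named substream of a master seed. Keeps every
# stage's randomness tied to one user-visible integer while letting stages be
# re-run independently. Result is kept inside the 32-bit signed range.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- sum(as.integer(charToRaw(name)) * (31L^(seq_along(charToRaw(name)) %% 7L)))
  as.integer((abs(seed) * 48271 + h) %% .Machine$integer.max)
}

with_substream <- function(seed, name, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    set.seed(substream_seed(seed, name))
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    }, add = TRUE)
  }
  force(expr)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# Two-sided normal-theory p-value from an estimate and its standard error.
wald_p <- function(estimate, se) 2 * pnorm(-abs(estimate / se))

# Standardize a numeric vector to mean 0, sd 1 (sample sd).
standardize <- function(x) {
  s <- sd(x)
  assert_that(is.finite(s) && s > 0, "cannot standardize a constant vector")
  (x - mean(x)) / s
}

# canonical threshold label, element-wise (format() on a vector pads to a
# common width, which would silently desynchronize column names)
thr_label <- function(x) {
  vapply(x, function(t) format(t, scientific = FALSE, trim = TRUE),
         character(1))
}

# logistic link and its standard-normal-metric conversion constant
logistic_D <- 1.702

item_link <- function(link = c("logistic", "probit")) {
  link <- match.arg(link)
  if (link == "logistic") plogis else pnorm
}
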