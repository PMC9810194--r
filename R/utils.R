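#' @keywords internal
"_PACKAGE"

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive independent sub-seeds from a master seed
#'
#' Splits one experiment seed into deterministic per-component seeds
#' (weight initialization, task generation, voltage initialization, ...) so
#' that a single component can be re-randomized by changing one field.
#' All sub-seeds stay below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n = 4L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  m <- 2147483647  # 2^31 - 1, Mersenne prime; simple LCG-style mixing
  s <- (abs(as.numeric(seed)) %% m)
  out <- integer(n)
  for (i in seq_len(n)) {
    s <- (s * 48271 + 11 + i) %% m
    out[i] <- as.integer(s)
  }
  out
}

# argument check helper: stop with the caller's message if cond is FALSE
check_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# coerce a vector/1-col structure to plain numeric vector
as_num <- function(x) as.numeric(x)

# Resolve an activation function by name. tanh is the conventional choice
# for FORCE reservoirs; alternatives are provided for experimentation.
resolve_activation <- function(name) {
  check_that(is.character(name) && length(name) == 1L,
             "activation must be a single function name")
  switch(name,
    tanh     = list(fn = tanh, inverse = atanh, range = c(-1, 1)),
    identity = list(fn = identity, inverse = identity, range = c(-Inf, Inf)),
    relu     = list(fn = function(x) pmax(x, 0), inverse = NULL, range = c(0, Inf)),
    sigmoid  = list(fn = stats::plogis, inverse = stats::qlogis, range = c(0, 1)),
    stop(sprintf("unknown activation '%s' (supported: tanh, identity, relu, sigmoid)",
                 name), call. = FALSE)
  )
}

#' Mean absolute error between output and target series
#'
#' @param z Numeric matrix (T x M) or vector of outputs.
#' @param target Numeric matrix or vector of the same shape.
#' @return Scalar mean absolute error over all steps and output dimensions.
#' @export
mae <- function(z, target) {
  z <- as.matrix(z); target <- as.matrix(target)
  check_that(all(dim(z) == dim(target)),
             sprintf("output is %dx%d but target is %dx%d",
                     nrow(z), ncol(z), nrow(target), ncol(target)))
  mean(abs(z - target))
}
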