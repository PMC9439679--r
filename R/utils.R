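# Internal helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @return value of `expr`
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific seed from a master seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629L)
}

# Half-open interval overlap: [s1,e1) intersects [s2,e2)?
intervals_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

# Mean of each diagonal d = 0..(n-1) of a square matrix, NA cells ignored.
# Returns a numeric vector indexed by d + 1; diagonals with no defined cell
# are NA.
diagonal_means <- function(mat) {
  n <- nrow(mat)
  d <- abs(row(mat) - col(mat))
  v <- as.vector(mat)
  ok <- !is.na(v)
  sums <- rep(NA_real_, n)
  cnts <- tapply(v[ok], d[ok], length)
  mns <- tapply(v[ok], d[ok], mean)
  out <- rep(NA_real_, n)
  out[as.integer(names(mns)) + 1L] <- as.numeric(mns)
  out
}

# sample() without the length-1 surprise
resample <- function(x, size = length(x), ...) x[sample.int(length(x), size, ...)]

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Require columns in a data.frame, with a schema error naming the missing ones.
check_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  invisible(df)
}
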