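# internal helpers shared across modules

# 2D linear convolution with zero padding (FFT path via EBImage).
convZero <- function(x, kernel) {
  if (nrow(kernel) == 1L && ncol(kernel) == 1L) return(x * kernel[1, 1])
  y <- EBImage::filter2(x, kernel, boundary = 0)
  # FFT roundoff can leave values like -1e-17 on zero background
  y[y < 0 & y > -1e-9] <- 0
  as.matrix(y)
}

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
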