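# misc numeric helpers shared across modules

#' Round half away from zero
#'
#' `base::round()` rounds half to even; reported percentages follow the
#' conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# population standard deviation (divide by N, not N-1)
sd_pop <- function(x) {
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

# weighted mean/sd with the same weights
wmean <- function(x, w) sum(w * x) / sum(w)
wsd_pop <- function(x, w) {
  mu <- wmean(x, w)
  sqrt(sum(w * (x - mu)^2) / sum(w))
}

# evaluate expr with a local RNG seeded at `seed`, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
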