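## Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## wrap degrees to [0, 360); floating-point x %% 360 can yield exactly 360
wrap360 <- function(x) {
  y <- x %% 360
  y[y >= 360] <- 0
  y
}

## Derive a stream-specific 32-bit sub-seed from a root seed.
subSeed <- function(seed, stream) {
  (as.integer(seed) * 7919L + as.integer(stream) * 104729L) %% 2147483563L
}

## Centers of the trial-aligned time grid covering [window[1], window[2]).
gridCenters <- function(window, dt) {
  nb <- round((window[2] - window[1]) / dt)
  window[1] + (seq_len(nb) - 0.5) * dt
}

## Linear interpolation over NA runs; ends carried from nearest value.
fillGapsLinear <- function(x) {
  ok <- which(!is.na(x))
  if (!length(ok)) return(x)
  if (length(ok) == length(x)) return(x)
  stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
}

## mean of values whose bin centers fall inside [window[1], window[2])
windowMean <- function(values, centers, window) {
  sel <- centers >= window[1] & centers < window[2]
  mean(values[sel])
}
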