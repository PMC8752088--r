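# Run code with a fixed RNG seed, restoring the caller's RNG state after.
# Keeps every generator a pure function of (config, seed).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Index range of a [t0, t1] second window on a time grid, inclusive.
window_index <- function(times, window, what = "window") {
  if (window[1] < times[1] - 1e-9 || window[2] > times[length(times)] + 1e-9)
    abort(sprintf("%s [%g, %g] s lies outside the recording", what,
                  window[1], window[2]))
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (length(idx) == 0)
    abort(sprintf("%s [%g, %g] s contains no samples", what,
                  window[1], window[2]))
  idx
}
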