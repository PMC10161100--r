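# Shared fixtures and independent oracles. Everything here is built in code
# at test time; no binary fixtures.

# coarse phantom label grid (built once per session)
coarsePhantom <- local({
  cache <- NULL
  function(spacing = 2) {
    if (is.null(cache)) cache <<- buildPhantom(phantomSpec(spacing = spacing))
    cache
  }
})

# Exhaustive brute-force gamma oracle (independent of the package's
# expanding-shell search): minimises over EVERY point of the linearly
# resampled evaluated raster. 2D maps on a unit-pitch raster by default.
bruteGamma2d <- function(refm, evalm, dd = 3, dta = 1, step = 0.1,
                         cutoff = 1, pitch = 1) {
  ev <- resampleMap(list(values = evalm, org = c(0, 0),
                         step = c(pitch, pitch)), step)
  ax <- lapply(1:2, function(a) ev$org[a] + (seq_len(ev$dims[a]) - 1) * step)
  eg <- as.matrix(expand.grid(ax[[1]], ax[[2]]))
  evv <- as.vector(ev$values)
  n <- dim(refm)
  g <- matrix(NA_real_, n[1], n[2])
  for (i in seq_len(n[1])) {
    for (j in seq_len(n[2])) {
      Dr <- refm[i, j]
      if (Dr <= cutoff) next
      d2 <- (eg[, 1] - (i - 1) * pitch)^2 + (eg[, 2] - (j - 1) * pitch)^2
      g[i, j] <- sqrt(min(d2 / dta^2 + (evv - Dr)^2 / ((dd / 100) * Dr)^2))
    }
  }
  g
}

# 1D brute-force gamma oracle
bruteGamma1d <- function(refp, evalp, dd = 3, dta = 1, step = 0.1,
                         cutoff = 1, pitch = 1) {
  ev <- resampleMap(list(values = evalp, org = 0, step = pitch), step)
  ex <- ev$org + (seq_along(ev$values) - 1) * step
  vapply(seq_along(refp), function(i) {
    Dr <- refp[i]
    if (Dr <= cutoff) return(NA_real_)
    sqrt(min((ex - (i - 1) * pitch)^2 / dta^2 +
               (ev$values - Dr)^2 / ((dd / 100) * Dr)^2))
  }, numeric(1))
}

# small water-equivalent density maps for fast engine tests
coarseWaterMaps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- waterSphereMaps(2)
    cache
  }
})

# fast engine settings: 2 mm dose grid / 2 mm tracing
coarseGridSpec <- function(plan, spacing = 2, margin = 20) {
  ctr <- do.call(rbind, lapply(plan@shots, function(s) s@center))
  lo <- apply(ctr, 2, min) - margin
  n <- as.integer(ceiling((apply(ctr, 2, max) + margin - lo) / spacing)) + 1L
  list(origin = lo, spacing = rep(spacing, 3), dims = n)
}
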