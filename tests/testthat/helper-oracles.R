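# Independent oracles and small fixture builders used across the suite.

# Textbook Cox-de Boor recursion, written independently of the package's
# splineDesign-based basis: value of the i-th B-spline of given degree on
# the knot vector at point x.
cox_de_boor <- function(x, knots, i, degree) {
  if (degree == 0) {
    return(as.numeric(x >= knots[i] & x < knots[i + 1]))
  }
  d1 <- knots[i + degree] - knots[i]
  d2 <- knots[i + degree + 1] - knots[i + 1]
  t1 <- if (d1 > 0) (x - knots[i]) / d1 * cox_de_boor(x, knots, i, degree - 1)
        else 0
  t2 <- if (d2 > 0) (knots[i + degree + 1] - x) / d2 *
          cox_de_boor(x, knots, i + 1, degree - 1) else 0
  t1 + t2
}

# Brute-force O(n * nx * ny) binning: loop over every point and every bin,
# half-open bins with the last bin closed.
brute_bin <- function(strength, contrast, x_edges, y_edges) {
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  counts <- matrix(0L, nx, ny)
  in_bin <- function(v, lo, hi, last) v >= lo & (if (last) v <= hi else v < hi)
  for (k in seq_along(strength)) {
    for (i in seq_len(nx)) {
      if (!in_bin(strength[k], x_edges[i], x_edges[i + 1], i == nx)) next
      for (j in seq_len(ny)) {
        if (in_bin(contrast[k], y_edges[j], y_edges[j + 1], j == ny)) {
          counts[i, j] <- counts[i, j] + 1L
        }
      }
    }
  }
  counts
}

# Unimodal 1-D histogram fixture: counts of n Gaussian draws on nbins equal
# bins, plus the matching basis at bin midpoints.
gaussian_hist_1d <- function(n = 1e4, nbins = 100, seed = 1, nseg = 10) {
  set.seed(seed)
  x <- rnorm(n)
  lo <- min(x) - 0.1
  hi <- max(x) + 0.1
  edges <- seq(lo, hi, length.out = nbins + 1)
  y <- as.numeric(table(cut(x, edges, include.lowest = TRUE)))
  mids <- (edges[-1] + edges[-(nbins + 1)]) / 2
  list(y = y, mids = mids, basis = bspline_basis(mids, lo, hi, nseg = nseg))
}

# Small well-separated synthetic array plus its transform/grid/histogram,
# for mixture and calling tests.
small_separated_run <- function(n = 5000, seed = 7, separation = 8,
                                nx = 50, ny = 50, nseg = 8) {
  sim <- simulate_array(platform_preset("affymetrix_like", n_snps = n,
                                        seed = seed,
                                        separation = separation))
  tt <- transform_signals(sim$signals)
  grid <- make_grid(tt, nx = nx, ny = ny)
  h <- build_histogram(tt, grid)
  list(sim = sim, tt = tt, grid = grid, h = h, nseg = nseg)
}
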