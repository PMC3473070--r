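test_that("initial pseudo-counts hard-split the histogram by sector", {
  r <- small_separated_run(n = 2000, seed = 5)
  pc <- initialize_pseudocounts(r$h)
  # bins in the low-contrast sector carry their full count in AA
  ym <- r$grid$y_mid
  aa_cols <- which(ym < -0.2)
  expect_equal(pc$counts$AA[, aa_cols], r$h$counts[, aa_cols],
               ignore_attr = TRUE)
  expect_true(all(pc$counts$AA[, ym >= -0.2] == 0))
  # the three matrices sum to the histogram exactly
  expect_identical(pc$counts$AA + pc$counts$AB + pc$counts$BB + 0,
                   r$h$counts + 0)
  expect_length(pc$empty_sectors, 0L)
})

test_that("degenerate splits are detected and floored", {
  r <- small_separated_run(n = 500, seed = 6)
  expect_warning(pc <- initialize_pseudocounts(r$h, split_lo = 9.8,
                                               split_hi = 10),
                 "empty seed sector")
  expect_setequal(pc$empty_sectors, c("AB", "BB"))
  expect_equal(sum(pc$counts$AA), sum(r$h$counts))
  expect_gt(sum(pc$counts$BB), 0)   # uniform floor, fittable
  expect_error(initialize_pseudocounts(r$h, 0.2, -0.2), "config error")
})

test_that("EM recovers well-separated clusters with near-certain memberships", {
  # three clusters with essentially zero overlap
  cfg <- sim_config(4000, maf = 0.4,
                    centers = rbind(c(2, -1.5), c(2, 0), c(2, 1.5)),
                    spreads = rep(list(diag(c(0.2, 0.1)^2)), 3),
                    seed = 99)
  sim <- simulate_array(cfg)
  tt <- transform_signals(sim$signals)
  g <- make_grid(tt, nx = 50, ny = 50)
  h <- build_histogram(tt, g)
  fit <- em_fit(h, nseg = 8)
  expect_true(fit$converged)
  expect_lte(fit$em_iterations, 50)
  expect_gt(min(fit$pstar[h$counts > 0]), 0.999)
  calls <- call_genotypes(tt, fit, h)
  expect_equal(mean(calls$call == sim$truth$genotype), 1)
})

test_that("memberships are probabilities and pstar respects the 1/3 floor", {
  r <- small_separated_run(n = 3000, seed = 8)
  fit <- em_fit(r$h, nseg = r$nseg)
  s <- fit$membership$AA + fit$membership$AB + fit$membership$BB
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-12)
  expect_true(all(fit$membership$AA >= 0))
  expect_gte(min(fit$pstar), 1 / 3)
})

test_that("penalized log-likelihood trace is non-decreasing", {
  r <- small_separated_run(n = 3000, seed = 10, separation = 5)
  fit <- em_fit(r$h, nseg = r$nseg)
  tr <- fit$loglik_trace
  expect_gte(length(tr), 2L)
  slack <- 1e-8 * (1 + abs(tr[-length(tr)]))
  expect_true(all(diff(tr) >= -slack))
})

test_that("a mirror-symmetric histogram yields mirror-symmetric component fits", {
  set.seed(14)
  n <- 1500
  base <- data.frame(strength = rnorm(n, 2, 0.3),
                     contrast = c(rnorm(n / 3, -1, 0.15), rnorm(n / 3, 0, 0.15),
                                  rnorm(n / 3, 1, 0.15)))
  sym <- rbind(base, transform(base, contrast = -contrast))
  sym$snp_id <- sprintf("s%d", seq_len(nrow(sym)))
  g <- make_grid(sym, nx = 40, ny = 40, ylim = c(-1.8, 1.8))
  h <- build_histogram(sym, g)
  fit <- em_fit(h, nseg = 6)
  mirror <- function(m) m[, ncol(m):1]
  expect_equal(fit$components$AA$mu, mirror(fit$components$BB$mu),
               tolerance = 1e-6)
  expect_equal(fit$pstar, mirror(fit$pstar), tolerance = 1e-6)
})

test_that("calls are robust to perturbing the seed split thresholds", {
  r <- small_separated_run(n = 4000, seed = 15)
  fit1 <- em_fit(r$h, nseg = r$nseg, split_lo = -0.2, split_hi = 0.2)
  fit2 <- em_fit(r$h, nseg = r$nseg, split_lo = -0.3, split_hi = 0.1)
  c1 <- call_genotypes(r$tt, fit1, r$h)
  c2 <- call_genotypes(r$tt, fit2, r$h)
  expect_identical(c1$call, c2$call)
})

test_that("EM is deterministic: identical refits bit for bit", {
  r <- small_separated_run(n = 1000, seed = 16)
  f1 <- em_fit(r$h, nseg = 6)
  f2 <- em_fit(r$h, nseg = 6)
  expect_identical(f1$membership, f2$membership)
  expect_identical(f1$loglik_trace, f2$loglik_trace)
})

test_that("an extinct component is frozen at a flat floor and flagged", {
  # single cluster at contrast 0: AA and BB sectors receive (almost) nothing
  cfg <- sim_config(2000, maf = 0,
                    centers = rbind(c(2, 0), c(2, 0), c(2, 0)),
                    spreads = rep(list(diag(c(0.2, 0.08)^2)), 3),
                    seed = 21)
  sim <- simulate_array(cfg)   # truth all AA, but geometry has one blob at 0
  tt <- transform_signals(sim$signals)
  h <- build_histogram(tt, make_grid(tt, nx = 40, ny = 40,
                                     ylim = c(-1.5, 1.5)))
  w <- capture_warnings(fit <- em_fit(h, nseg = 6))
  expect_true(any(grepl("extinct|empty seed", w)))
  expect_true(length(fit$extinct) >= 1)
  expect_true(fit$converged || fit$em_iterations == fit$em_maxit)
  # extinct components are flat
  for (k in fit$extinct) {
    expect_equal(diff(range(fit$components[[k]]$mu)), 0)
  }
  # memberships still normalized
  s <- fit$membership$AA + fit$membership$AB + fit$membership$BB
  expect_equal(max(abs(s - 1)), 0, tolerance = 1e-12)
})

test_that("membership_at returns the stored triple and checks the index", {
  r <- small_separated_run(n = 1000, seed = 18)
  fit <- em_fit(r$h, nseg = 6)
  m <- membership_at(fit, 10, 10)
  expect_named(m$p, c("AA", "AB", "BB"))
  expect_equal(sum(m$p), 1, tolerance = 1e-12)
  expect_equal(m$pstar, max(m$p))
  expect_gte(m$pstar, 1 / 3)
  expect_error(membership_at(fit, 0, 1), "range error")
  expect_error(membership_at(fit, 1, 51), "range error")
})

test_that("equal component densities give the uniform triple with pstar 1/3", {
  # by construction of the E-step: mu triple (2, 2, 2) normalizes to 1/3 each
  p <- c(2, 2, 2) / sum(c(2, 2, 2))
  expect_equal(p, rep(1 / 3, 3))
  expect_equal(max(p), 1 / 3)
  p2 <- c(9, 1, 0) / 10
  expect_equal(max(p2), 0.9)
})

test_that("a fitted mixture serializes to a JSON sidecar", {
  r <- small_separated_run(n = 1000, seed = 19)
  fit <- em_fit(r$h, nseg = 6)
  path <- tempfile(fileext = ".json")
  write_mixture_json(fit, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$grid$nx, 50)
  expect_equal(obj$lambda, c(300, 300))
  expect_equal(dim(obj$coef$AA), c(9L, 9L))   # nseg 6 + degree 3 per side
  unlink(path)
})
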