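#' Initial pseudo-counts from the three-sector seed split
#'
#' Seeds the EM algorithm by hard-splitting the histogram along the contrast
#' axis: each bin's full count goes to the single genotype component of its
#' sector, decided by the bin's contrast midpoint against the two split
#' thresholds (below `split_lo` AA, the closed middle band AB, above
#' `split_hi` BB).  The three matrices sum to the observed histogram exactly.
#'
#' A sector with zero total count (possible at extreme minor allele
#' frequency) gets a uniform floor of total mass 1e-6 of the data so its
#' component can be fitted at all; this is flagged.
#'
#' @param h a `histogram2d`.
#' @param split_lo,split_hi contrast thresholds, as in [seed_labels()].
#' @return object of class `pseudo_counts`: list with `counts` (list of
#'   three `nx` by `ny` matrices named AA, AB, BB), `empty_sectors`
#'   (character vector of sectors that received the floor).
#' @export
initialize_pseudocounts <- function(h, split_lo = -0.2, split_hi = 0.2) {
  stopifnot(inherits(h, "histogram2d"))
  if (!(split_lo < split_hi))
    stop("config error: need split_lo < split_hi", call. = FALSE)
  ym <- h$grid$y_mid
  sector <- ifelse(ym < split_lo, "AA", ifelse(ym > split_hi, "BB", "AB"))
  counts <- lapply(c(AA = "AA", AB = "AB", BB = "BB"), function(g) {
    m <- h$counts
    m[, sector != g] <- 0
    m
  })
  empty <- names(counts)[vapply(counts, sum, 0) == 0]
  if (length(empty)) {
    warning("empty seed sector(s): ", paste(empty, collapse = ", "),
            "; applying uniform floor", call. = FALSE)
    floor_mass <- 1e-6 * sum(h$counts)
    for (g in empty)
      counts[[g]] <- matrix(floor_mass / length(h$counts),
                            nrow(h$counts), ncol(h$counts))
  }
  structure(list(counts = counts, empty_sectors = empty,
                 split_lo = split_lo, split_hi = split_hi),
            class = "pseudo_counts")
}

#' Fit the three-component log-concave mixture by EM
#'
#' Alternates two steps on the histogram until the per-bin membership
#' probabilities stabilize: the M-step smooths each component's pseudo-counts
#' with the penalized Poisson tensor-product fitter
#' ([fit_pspline_poisson_2d()]), and the E-step recomputes memberships as
#' `mu_k / (mu_1 + mu_2 + mu_3)` per bin and splits the observed counts into
#' new pseudo-counts proportional to them.  The pseudo-counts therefore sum
#' to the observed histogram exactly at every iteration, and the mixing
#' proportions are implicit in the pseudo-count totals — there are no
#' separate mixing parameters.
#'
#' Convergence is declared when the count-weighted mean absolute membership
#' change — the average amount by which an individual SNP's membership
#' probabilities still move per iteration — drops below `em_tol`.  Weighting
#' by bin counts ties the criterion to the SNPs actually being called:
#' a lone outlier point in a far tail bin, whose membership can keep
#' drifting for many iterations without any call changing, does not hold
#' the whole fit hostage.  Component fits are warm-started from the
#' previous EM iteration, so later M-steps take very few IRLS iterations.
#' The observed-data penalized log-likelihood is recorded per iteration; EM
#' theory makes it non-decreasing up to the inner-solver tolerance.
#'
#' A component whose pseudo-count total falls below 1 is declared extinct:
#' it is frozen at a flat density of total mass 1e-6 of the data, flagged,
#' and EM continues with the remaining components.
#'
#' @param h a `histogram2d`.
#' @param nseg,degree B-spline basis size per direction (default 10 + 3
#'   cubic splines).
#' @param lambda smoothing parameter, shared by both penalty directions
#'   (or `c(lambda_r, lambda_c)`), passed to the component fitter.  Calls
#'   are insensitive to `lambda` over a wide plateau (two orders of
#'   magnitude around the default); the default 300 keeps each component
#'   close to its unimodal log-concave limit on histograms of 1e5-1e6 SNPs.
#'   Much weaker smoothing lets mis-seeded mass linger as secondary bumps
#'   in the component densities and slows the EM mass transfer without
#'   changing the final calls.
#' @param split_lo,split_hi seed split thresholds for the initial
#'   pseudo-counts.
#' @param em_tol convergence tolerance on the count-weighted mean absolute
#'   membership change per iteration.
#' @param em_maxit maximum EM iterations; non-convergence is flagged.
#' @param irls_tol,irls_maxit control for the inner penalized Poisson fits.
#' @return object of class `mixture_fit`: `components` (list of three
#'   `smooth_fit_2d`, named AA/AB/BB), `membership` (list of three `nx` by
#'   `ny` probability matrices), `pstar` (per-bin maximum membership),
#'   `em_iterations`, `converged`, `loglik_trace`, `extinct` (character
#'   vector), plus the grid, bases and control settings.
#' @export
em_fit <- function(h, nseg = 10, degree = 3, lambda = 300,
                   split_lo = -0.2, split_hi = 0.2,
                   em_tol = 1e-6, em_maxit = 50,
                   irls_tol = 1e-6, irls_maxit = 50) {
  stopifnot(inherits(h, "histogram2d"))
  g <- h$grid
  basis_r <- bspline_basis(g$x_mid, g$x_edges[1], g$x_edges[g$nx + 1L],
                           nseg = nseg, degree = degree)
  basis_c <- bspline_basis(g$y_mid, g$y_edges[1], g$y_edges[g$ny + 1L],
                           nseg = nseg, degree = degree)
  pc <- initialize_pseudocounts(h, split_lo, split_hi)
  cache <- glam_cache(basis_r, basis_c, lambda)
  Y <- h$counts
  n_total <- sum(Y)
  floor_mu <- matrix(1e-6 * n_total / length(Y), nrow(Y), ncol(Y))
  comp_names <- c("AA", "AB", "BB")

  fits <- stats::setNames(vector("list", 3L), comp_names)
  extinct <- character(0)
  membership <- NULL
  loglik_trace <- numeric(0)
  converged <- FALSE
  it <- 0L

  for (it in seq_len(em_maxit)) {
    # M-step: smooth each component's pseudo-counts
    for (k in comp_names) {
      Yk <- pc$counts[[k]]
      if (sum(Yk) < 1) {
        if (!(k %in% extinct)) {
          warning("component ", k, " extinct (pseudo-count total < 1); ",
                  "frozen at flat floor density", call. = FALSE)
          extinct <- c(extinct, k)
        }
        fits[[k]] <- structure(list(coef = NULL, eta = log(floor_mu),
                                    mu = floor_mu, iterations = 0L,
                                    converged = TRUE, penalized_loglik = NA_real_,
                                    lambda = rep_len(lambda, 2L),
                                    pen_order = 3),
                               class = "smooth_fit_2d")
        next
      }
      fits[[k]] <- fit_pspline_poisson_2d(
        Yk, basis_r, basis_c, lambda = lambda,
        tol = irls_tol, maxit = irls_maxit,
        alpha0 = if (!is.null(fits[[k]])) fits[[k]]$coef else NULL,
        cache = cache)
    }

    # E-step: memberships from the component densities
    mu_tot <- fits$AA$mu + fits$AB$mu + fits$BB$mu
    memb_new <- lapply(fits, function(f) f$mu / mu_tot)
    pc$counts <- lapply(memb_new, function(m) Y * m)

    # observed-data penalized log-likelihood
    pen <- sum(vapply(comp_names, function(k) {
      f <- fits[[k]]
      if (is.null(f$coef)) return(0)
      Dr <- difference_matrix(nrow(f$coef), f$pen_order)
      Dc <- difference_matrix(ncol(f$coef), f$pen_order)
      (f$lambda[1] / 2) * sum((Dr %*% f$coef)^2) +
        (f$lambda[2] / 2) * sum((f$coef %*% t(Dc))^2)
    }, 0))
    loglik_trace <- c(loglik_trace, sum(Y * log(mu_tot)) - sum(mu_tot) - pen)

    if (!is.null(membership)) {
      chg <- pmax(abs(memb_new$AA - membership$AA),
                  abs(memb_new$AB - membership$AB),
                  abs(memb_new$BB - membership$BB))
      delta <- sum(Y * chg) / n_total
      membership <- memb_new
      if (delta < em_tol) { converged <- TRUE; break }
    } else {
      membership <- memb_new
    }
  }

  pstar <- pmax(membership$AA, membership$AB, membership$BB)
  structure(list(components = fits, membership = membership, pstar = pstar,
                 em_iterations = it, converged = converged,
                 loglik_trace = loglik_trace, extinct = extinct,
                 grid = g, basis_r = basis_r, basis_c = basis_c,
                 lambda = rep_len(lambda, 2L),
                 split_lo = split_lo, split_hi = split_hi,
                 em_tol = em_tol, em_maxit = em_maxit),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "Three-component log-concave mixture on a %d x %d histogram\n",
    x$grid$nx, x$grid$ny))
  cat(sprintf("  EM iterations: %d (%s)%s\n", x$em_iterations,
              if (x$converged) "converged" else "NOT converged",
              if (length(x$extinct))
                paste0("; extinct: ", paste(x$extinct, collapse = ", "))
              else ""))
  cat(sprintf("  penalized log-likelihood: %.4f\n",
              utils::tail(x$loglik_trace, 1)))
  invisible(x)
}

#' Membership probabilities of one histogram bin
#'
#' Returns the stored normalized membership triple of bin `(i, j)` and its
#' maximum `pstar`.  With three components `pstar` can never fall below 1/3,
#' the value attained when all three densities are equal in the bin.
#'
#' @param fit a `mixture_fit`.
#' @param i,j bin indices (strength, contrast), 1-based.
#' @return list with `p` (named numeric triple AA/AB/BB) and `pstar`.
#' @export
membership_at <- function(fit, i, j) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (i < 1 || i > fit$grid$nx || j < 1 || j > fit$grid$ny)
    stop("range error: bin index out of grid", call. = FALSE)
  p <- c(AA = fit$membership$AA[i, j],
         AB = fit$membership$AB[i, j],
         BB = fit$membership$BB[i, j])
  list(p = p, pstar = max(p))
}

#' Serialize a fitted mixture to JSON
#'
#' Writes the grid, basis definition, smoothing parameters and the three
#' coefficient matrices to a JSON sidecar for later inspection or reuse.
#'
#' @param fit a `mixture_fit`.
#' @param path output file.
#' @export
write_mixture_json <- function(fit, path) {
  obj <- list(
    grid = list(nx = fit$grid$nx, ny = fit$grid$ny,
                x_edges = fit$grid$x_edges, y_edges = fit$grid$y_edges),
    basis = list(nseg = fit$basis_r$nseg, degree = fit$basis_r$degree),
    lambda = fit$lambda,
    split = c(fit$split_lo, fit$split_hi),
    em_iterations = fit$em_iterations,
    converged = fit$converged,
    extinct = fit$extinct,
    coef = lapply(fit$components, function(f) f$coef))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
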