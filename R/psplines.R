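#' Equally spaced B-spline basis on a domain
#'
#' Builds the B-spline design matrix used for log-density smoothing: the
#' domain `[lo, hi]` is divided into `nseg` equal segments, the knot grid is
#' extended by `degree` knots on each side, giving `nseg + degree` basis
#' functions (the extras are boundary splines).  The default, 10 segments of
#' cubic splines, gives 10+3 = 13 bases per direction.  On equally spaced
#' knots the bases form a partition of unity over the whole domain.
#'
#' @param eval_points points (histogram bin midpoints) where the basis is
#'   evaluated; must lie within `[lo, hi]`.
#' @param lo,hi domain limits, `lo < hi`.
#' @param nseg number of equal segments (>= 4).
#' @param degree spline degree (default 3, cubic).
#' @return object of class `bspline_basis`: list with `B` (length(eval_points)
#'   by `nseg + degree` matrix), `lo`, `hi`, `nseg`, `degree`, `n_bases`,
#'   `eval_points`, `knots`.
#' @export
bspline_basis <- function(eval_points, lo, hi, nseg = 10, degree = 3) {
  if (!(lo < hi)) stop("config error: need lo < hi", call. = FALSE)
  if (nseg < 4) stop("config error: nseg must be >= 4", call. = FALSE)
  if (any(eval_points < lo | eval_points > hi))
    stop("range error: eval points outside [lo, hi]", call. = FALSE)
  h <- (hi - lo) / nseg
  knots <- seq(lo - degree * h, hi + degree * h, by = h)
  B <- splines::splineDesign(knots, eval_points, ord = degree + 1L)
  structure(list(B = B, lo = lo, hi = hi, nseg = as.integer(nseg),
                 degree = as.integer(degree),
                 n_bases = as.integer(nseg + degree),
                 eval_points = eval_points, knots = knots),
            class = "bspline_basis")
}

#' Difference (contrast) matrix of a given order
#'
#' Returns the `(n - order)` by `n` matrix applying order-th differences to a
#' coefficient vector.  With `order = 3` its null space is the quadratic
#' sequences, which is what makes the penalized log-density tend to a
#' parabola (a Gaussian density) as the penalty grows, and what yields
#' conservation of the first two moments of the fit.
#'
#' @param n length of the coefficient vector (`n > order`).
#' @param order difference order (>= 1).
#' @export
difference_matrix <- function(n, order = 3) {
  if (order < 1) stop("config error: order must be >= 1", call. = FALSE)
  if (n <= order)
    stop("config error: need n > order", call. = FALSE)
  diff(diag(n), differences = order)
}

# Penalized least-squares initialization of the linear predictor: fit
# log(y + 1) on the basis with the difference penalty plus a small ridge
# (heavier on this first step for stability in empty regions).
init_eta_1d <- function(y, B, P) {
  z0 <- log(y + 1)
  a0 <- solve(crossprod(B) + P + 1e-4 * diag(ncol(B)), crossprod(B, z0))
  drop(B %*% a0)
}

#' Penalized Poisson density smoothing in one dimension
#'
#' Fits the P-spline Poisson model for histogram counts: the log expected
#' count is a B-spline expansion, `eta = B alpha`, and the penalized
#' log-likelihood `sum(y * eta - mu) - (lambda / 2) * ||D alpha||^2` is
#' maximized, with `D` the order-`pen_order` difference matrix.  The solver
#' is iteratively reweighted least squares (IRLS): each step solves
#' `(B' W B + lambda D'D) alpha = B' W z` with working weights `W = diag(mu)`
#' and working variable `z = eta + (y - mu) / mu`, until the maximum absolute
#' coefficient change drops below `tol`.  On unimodal histograms this
#' typically converges in fewer than ten iterations.
#'
#' With the default third-order penalty the fit conserves the total count and
#' the first two moments of the histogram for every `lambda`, so the smooth
#' density never drifts away from the mean and variance of the data — the
#' property that makes these fits usable as mixture components.
#'
#' Counts may be fractional (EM pseudo-counts); the Poisson log-likelihood is
#' then read as a quasi-likelihood in `y`.
#'
#' @param y non-negative count vector (one entry per bin), at least one
#'   positive entry.
#' @param basis a `bspline_basis` evaluated at the bin midpoints.
#' @param lambda smoothing parameter, >= 0.
#' @param pen_order difference order of the penalty (default 3).
#' @param tol convergence tolerance on the max abs coefficient change.
#' @param maxit maximum IRLS iterations; non-convergence is flagged in the
#'   result, not an error.
#' @param eta0 optional starting linear predictor (warm start).
#' @return object of class `smooth_fit_1d`: `alpha`, `eta`, `mu`,
#'   `iterations`, `converged`, `penalized_loglik`, `lambda`, `pen_order`.
#' @export
fit_pspline_poisson_1d <- function(y, basis, lambda = 10, pen_order = 3,
                                   tol = 1e-6, maxit = 50, eta0 = NULL) {
  stopifnot(inherits(basis, "bspline_basis"))
  if (any(y < 0)) stop("input error: negative counts", call. = FALSE)
  if (all(y == 0))
    stop("input error: all-zero counts (extinct component)", call. = FALSE)
  if (length(y) != nrow(basis$B))
    stop("config error: length(y) must match basis eval points", call. = FALSE)

  B <- basis$B
  D <- difference_matrix(ncol(B), pen_order)
  P <- lambda * crossprod(D)

  pll_of <- function(a) {
    eta <- drop(B %*% a)
    sum(y * eta - exp(pmin(eta, 300))) - (lambda / 2) * sum((D %*% a)^2)
  }
  eta <- if (is.null(eta0)) init_eta_1d(y, B, P) else eta0
  alpha <- drop(solve(crossprod(B) + P + 1e-4 * diag(ncol(B)),
                      crossprod(B, eta)))
  pll <- pll_of(alpha)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    mu <- pmax(exp(pmin(eta, 300)), 1e-10)
    # B' W z = B' (mu * eta + y - mu)
    rhs <- crossprod(B, mu * eta + y - mu)
    lhs <- crossprod(B, B * mu) + P
    alpha_new <- drop(solve(lhs, rhs))
    # step-halving: never let an IRLS step decrease the penalized likelihood
    pll_new <- pll_of(alpha_new)
    half <- 0L
    ftol <- 1e-9 * (1 + abs(pll))
    while (pll_new < pll - ftol && half < 20L) {
      alpha_new <- (alpha_new + alpha) / 2
      pll_new <- pll_of(alpha_new)
      half <- half + 1L
    }
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    pll <- pll_new
    eta <- drop(B %*% alpha)
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- pmax(exp(pmin(eta, 300)), 1e-10)
  pll <- sum(y * eta - mu) - (lambda / 2) * sum((D %*% alpha)^2)
  structure(list(alpha = alpha, eta = eta, mu = mu, iterations = it,
                 converged = converged, penalized_loglik = pll,
                 lambda = lambda, pen_order = pen_order),
            class = "smooth_fit_1d")
}

# Row-wise tensor (box) product: column (a-1)*c + b holds B[, a] * B[, b].
row_tensor <- function(B) {
  c <- ncol(B)
  B[, rep(seq_len(c), each = c), drop = FALSE] *
    B[, rep(seq_len(c), times = c), drop = FALSE]
}

# GLAM weighted inner product: the (nr*nc) x (nr*nc) matrix
# (Bc %x% Br)' diag(vec(W)) (Bc %x% Br) computed without forming the
# Kronecker design, via row tensors of the two marginal bases (which are
# constant across IRLS iterations and can be passed in precomputed).
glam_xwx <- function(Br, Bc, W, Rr = row_tensor(Br), Rc = row_tensor(Bc),
                     perm = glam_perm(ncol(Br), ncol(Bc))) {
  nr <- ncol(Br); nc <- ncol(Bc)
  Fm <- crossprod(Rr, W %*% Rc)         # (nr^2) x (nc^2), index [b, a, d, c]
  G <- Fm[perm]                         # reorder to [(b, d), (a, c)]
  dim(G) <- c(nr * nc, nr * nc)
  G
}

# Index permutation reordering the row-tensor cross product into the
# Kronecker coefficient order (row index of the coefficient matrix fastest);
# equals aperm(array(Fm, c(nr, nr, nc, nc)), c(1, 3, 2, 4)) but reusable.
glam_perm <- function(nr, nc) {
  a <- array(seq_len((nr * nc)^2), c(nr, nr, nc, nc))
  as.vector(aperm(a, c(1, 3, 2, 4)))
}

# Penalty matrix for the tensor-product coefficients, vec(A) with the row
# index of A running fastest: lambda_r ||Dr A||_F^2 + lambda_c ||A Dc'||_F^2.
penalty_2d <- function(nr, nc, lambda_r, lambda_c, pen_order) {
  DtDr <- crossprod(difference_matrix(nr, pen_order))
  DtDc <- crossprod(difference_matrix(nc, pen_order))
  lambda_r * (diag(nc) %x% DtDr) + lambda_c * (DtDc %x% diag(nr))
}

# Precomputed constants for repeated GLAM fits on the same bases: penalty
# matrix, difference matrices, row tensors and the reordering permutation.
# The EM loop builds this once and reuses it for every component and
# iteration.
glam_cache <- function(basis_r, basis_c, lambda, pen_order = 3) {
  lambda <- rep_len(lambda, 2L)
  nr <- ncol(basis_r$B); nc <- ncol(basis_c$B)
  list(P = penalty_2d(nr, nc, lambda[1], lambda[2], pen_order),
       Dr = difference_matrix(nr, pen_order),
       Dc = difference_matrix(nc, pen_order),
       Rr = row_tensor(basis_r$B),
       Rc = row_tensor(basis_c$B),
       perm = glam_perm(nr, nc))
}

#' Penalized Poisson density smoothing on a 2-D histogram (GLAM)
#'
#' Tensor-product extension of [fit_pspline_poisson_1d()]: the matrix of log
#' expected counts is `eta = Br A Bc'` with marginal B-spline bases `Br`
#' (strength direction) and `Bc` (contrast direction) and a coefficient
#' matrix `A`, penalized by third-order differences along both rows and
#' columns of `A` (Frobenius norms, one `lambda` per direction).  The IRLS
#' normal equations are assembled with the generalized linear array model
#' (GLAM) identities — row tensors of the two marginal bases — so the full
#' Kronecker design matrix is never materialized; the result is identical to
#' the explicit Kronecker formulation (see [naive_fit_2d_kron()]).
#'
#' @param Y non-negative count matrix (`nx` by `ny`), fractional allowed.
#' @param basis_r,basis_c `bspline_basis` objects for the row (strength) and
#'   column (contrast) directions; their eval points must match `nrow(Y)`
#'   and `ncol(Y)`.
#' @param lambda smoothing parameter(s): a single value shared by both
#'   directions or `c(lambda_r, lambda_c)`.
#' @param pen_order penalty difference order (default 3).
#' @param tol,maxit IRLS control, as in the 1-D fitter.
#' @param alpha0 optional starting coefficient matrix (warm start, used by
#'   the EM loop).
#' @param cache optional precomputed constants (internal; the EM loop
#'   builds one set of penalty matrices and row tensors and reuses it for
#'   every component fit).
#' @return object of class `smooth_fit_2d`: `coef` (`n_r` by `n_c` matrix),
#'   `eta`, `mu` (both `nx` by `ny`), `iterations`, `converged`,
#'   `penalized_loglik`, `lambda`, `pen_order`.
#' @export
fit_pspline_poisson_2d <- function(Y, basis_r, basis_c, lambda = 10,
                                   pen_order = 3, tol = 1e-6, maxit = 50,
                                   alpha0 = NULL, cache = NULL) {
  stopifnot(inherits(basis_r, "bspline_basis"),
            inherits(basis_c, "bspline_basis"))
  if (any(Y < 0)) stop("input error: negative counts", call. = FALSE)
  if (all(Y == 0))
    stop("input error: all-zero counts (extinct component)", call. = FALSE)
  Br <- basis_r$B; Bc <- basis_c$B
  if (nrow(Y) != nrow(Br) || ncol(Y) != nrow(Bc))
    stop("config error: histogram dimensions do not match the bases",
         call. = FALSE)
  lambda <- rep_len(lambda, 2L)
  nr <- ncol(Br); nc <- ncol(Bc)
  if (is.null(cache)) cache <- glam_cache(basis_r, basis_c, lambda, pen_order)
  P <- cache$P
  Dr <- cache$Dr
  Dc <- cache$Dc
  pll_of <- function(A) {
    eta <- Br %*% A %*% t(Bc)
    sum(Y * eta - exp(pmin(eta, 300))) -
      (lambda[1] / 2) * sum((Dr %*% A)^2) -
      (lambda[2] / 2) * sum((A %*% t(Dc))^2)
  }
  if (is.null(alpha0)) {
    Z0 <- log(Y + 1)
    G0 <- glam_xwx(Br, Bc, matrix(1, nrow(Y), ncol(Y)),
                   cache$Rr, cache$Rc, cache$perm)
    a <- solve(G0 + P + 1e-4 * diag(nr * nc),
               as.vector(crossprod(Br, Z0 %*% Bc)))
    A <- matrix(a, nr, nc)
  } else {
    A <- alpha0
  }
  eta <- Br %*% A %*% t(Bc)
  # objective and linear predictor of a candidate, computed together so the
  # accepted eta is reused rather than recomputed
  eval_cand <- function(A) {
    eta <- Br %*% A %*% t(Bc)
    list(pll = sum(Y * eta - exp(pmin(eta, 300))) -
           (lambda[1] / 2) * sum((Dr %*% A)^2) -
           (lambda[2] / 2) * sum((A %*% t(Dc))^2),
         eta = eta)
  }
  pll <- pll_of(A)
  Rr <- cache$Rr
  Rc <- cache$Rc
  perm <- cache$perm
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    mu <- pmax(exp(pmin(eta, 300)), 1e-10)
    M <- mu * eta + Y - mu                      # W z, elementwise
    rhs <- as.vector(crossprod(Br, M %*% Bc))   # (Bc %x% Br)' vec(W z)
    H <- glam_xwx(Br, Bc, mu, Rr, Rc, perm)
    # tiny scaled ridge: the penalty null space (quadratic surfaces) is not
    # identified where a component carries almost no mass
    ridge <- 1e-9 * (1 + max(diag(H)))
    H <- H + P
    diag(H) <- diag(H) + ridge
    A_new <- matrix(solve(H, rhs), nr, nc)
    # step-halving guards against transient divergence of the linearization
    cand <- eval_cand(A_new)
    half <- 0L
    ftol <- 1e-9 * (1 + abs(pll))
    while (cand$pll < pll - ftol && half < 20L) {
      A_new <- (A_new + A) / 2
      cand <- eval_cand(A_new)
      half <- half + 1L
    }
    delta <- max(abs(A_new - A))
    A <- A_new
    pll <- cand$pll
    eta <- cand$eta
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- pmax(exp(pmin(eta, 300)), 1e-10)
  pll <- sum(Y * eta - mu) -
    (lambda[1] / 2) * sum((Dr %*% A)^2) -
    (lambda[2] / 2) * sum((A %*% t(Dc))^2)
  structure(list(coef = A, eta = eta, mu = mu, iterations = it,
                 converged = converged, penalized_loglik = pll,
                 lambda = lambda, pen_order = pen_order),
            class = "smooth_fit_2d")
}

#' Naive Kronecker-product 2-D fit (reference implementation)
#'
#' Solves the same penalized Poisson tensor-product problem as
#' [fit_pspline_poisson_2d()] by vectorizing the count matrix and forming
#' the explicit Kronecker design `Bc %x% Br`.  This is deliberately the
#' slow, memory-hungry formulation; it exists as the independent correctness
#' oracle for the GLAM solver and refuses problems with more than 400 total
#' basis functions.
#'
#' @inheritParams fit_pspline_poisson_2d
#' @return a `smooth_fit_2d`, identical (to solver tolerance) to the GLAM
#'   fit on the same inputs.
#' @export
naive_fit_2d_kron <- function(Y, basis_r, basis_c, lambda = 10,
                              pen_order = 3, tol = 1e-6, maxit = 50,
                              alpha0 = NULL) {
  stopifnot(inherits(basis_r, "bspline_basis"),
            inherits(basis_c, "bspline_basis"))
  Br <- basis_r$B; Bc <- basis_c$B
  nr <- ncol(Br); nc <- ncol(Bc)
  if (nr * nc > 400)
    stop("problem too large for the naive Kronecker path (limit 400 bases); ",
         "use fit_pspline_poisson_2d", call. = FALSE)
  if (all(Y == 0))
    stop("input error: all-zero counts (extinct component)", call. = FALSE)
  lambda <- rep_len(lambda, 2L)
  Bfull <- Bc %x% Br                        # vec(Br A Bc') = Bfull vec(A)
  y <- as.vector(Y)
  P <- penalty_2d(nr, nc, lambda[1], lambda[2], pen_order)
  Dr <- difference_matrix(nr, pen_order)
  Dc <- difference_matrix(nc, pen_order)
  pll_of <- function(a) {
    eta <- drop(Bfull %*% a)
    A <- matrix(a, nr, nc)
    sum(y * eta - exp(pmin(eta, 300))) -
      (lambda[1] / 2) * sum((Dr %*% A)^2) -
      (lambda[2] / 2) * sum((A %*% t(Dc))^2)
  }

  if (is.null(alpha0)) {
    a <- drop(solve(crossprod(Bfull) + P + 1e-4 * diag(nr * nc),
                    crossprod(Bfull, log(y + 1))))
  } else {
    a <- as.vector(alpha0)
  }
  eta <- drop(Bfull %*% a)
  pll <- pll_of(a)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    mu <- pmax(exp(pmin(eta, 300)), 1e-10)
    rhs <- crossprod(Bfull, mu * eta + y - mu)
    G <- crossprod(Bfull, Bfull * mu)
    ridge <- 1e-9 * (1 + max(diag(G)))  # same stabilizer as the GLAM path
    a_new <- drop(solve(G + P + ridge * diag(nr * nc), rhs))
    pll_new <- pll_of(a_new)
    half <- 0L
    ftol <- 1e-9 * (1 + abs(pll))
    while (pll_new < pll - ftol && half < 20L) {
      a_new <- (a_new + a) / 2
      pll_new <- pll_of(a_new)
      half <- half + 1L
    }
    delta <- max(abs(a_new - a))
    a <- a_new
    pll <- pll_new
    eta <- drop(Bfull %*% a)
    if (delta < tol) { converged <- TRUE; break }
  }
  mu <- pmax(exp(pmin(eta, 300)), 1e-10)
  A <- matrix(a, nr, nc)
  pll <- sum(y * eta - mu) -
    (lambda[1] / 2) * sum((Dr %*% A)^2) -
    (lambda[2] / 2) * sum((A %*% t(Dc))^2)
  structure(list(coef = A, eta = matrix(eta, nrow(Y), ncol(Y)),
                 mu = matrix(mu, nrow(Y), ncol(Y)), iterations = it,
                 converged = converged, penalized_loglik = pll,
                 lambda = lambda, pen_order = pen_order),
            class = "smooth_fit_2d")
}
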