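#' Simulation configuration for a synthetic single array
#'
#' Describes a synthetic array in the (strength, contrast) plane: three
#' genotype clusters (AA, AB, BB) with Gaussian noise, a per-SNP minor
#' allele frequency sampler, and an optional quadratic bend (shear of
#' strength as a function of contrast) that mimics the asymmetric, curved
#' clusters of two-dye platforms.
#'
#' @param n_snps number of SNPs (>= 1).
#' @param maf minor-allele-frequency sampler: a single value in `[0, 0.5]`,
#'   a numeric vector of values sampled with equal probability, or a list
#'   `list(type = "uniform", min=, max=)` or `list(type = "beta", shape1=,
#'   shape2=)` (beta draws are rescaled to `[0, 0.5]`).
#' @param centers 3 x 2 matrix of cluster centers, rows AA/AB/BB, columns
#'   (strength, contrast).
#' @param spreads list of three 2 x 2 positive-definite covariance matrices
#'   (strength, contrast), order AA/AB/BB.
#' @param skew numeric length 3: per-cluster quadratic bend coefficients;
#'   strength is shifted by `skew * (contrast - center_contrast)^2`.
#' @param seed integer RNG seed; recorded in the output so a run is
#'   reproducible.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_snps, maf = list(type = "uniform", min = 0.05,
                                          max = 0.5),
                       centers, spreads, skew = c(0, 0, 0), seed = 1L) {
  if (n_snps < 1) stop("config error: n_snps must be >= 1", call. = FALSE)
  centers <- as.matrix(centers)
  stopifnot(identical(dim(centers), c(3L, 2L)), length(spreads) == 3L,
            length(skew) == 3L)
  for (S in spreads) {
    S <- as.matrix(S)
    if (!all(dim(S) == 2L) || any(eigen(S, symmetric = TRUE,
                                        only.values = TRUE)$values <= 0))
      stop("config error: cluster covariances must be 2x2 positive definite",
           call. = FALSE)
  }
  structure(list(n_snps = as.integer(n_snps), maf = maf,
                 centers = centers, spreads = lapply(spreads, as.matrix),
                 skew = as.numeric(skew), seed = as.integer(seed)),
            class = "sim_config")
}

draw_maf <- function(maf, n) {
  if (is.numeric(maf)) {
    p <- if (length(maf) == 1L) rep(maf, n) else sample(maf, n, replace = TRUE)
  } else if (is.list(maf) && identical(maf$type, "uniform")) {
    p <- stats::runif(n, maf$min, maf$max)
  } else if (is.list(maf) && identical(maf$type, "beta")) {
    p <- 0.5 * stats::rbeta(n, maf$shape1, maf$shape2)
  } else {
    stop("config error: unrecognized maf sampler", call. = FALSE)
  }
  if (any(p < 0 | p > 0.5))
    stop("config error: MAF values must lie in [0, 0.5]", call. = FALSE)
  p
}

#' Simulate one synthetic array with known genotypes
#'
#' Per SNP: draw a minor allele frequency `p` from the configured sampler,
#' draw the genotype from Hardy-Weinberg proportions `((1-p)^2, 2p(1-p),
#' p^2)` (B is the minor allele), draw `(strength, contrast)` from the
#' genotype's Gaussian cluster with the optional quadratic bend, then invert
#' the log transform to produce linear-scale channel intensities
#' `signal_A = 10^(strength - contrast/2)`, `signal_B = 10^(strength +
#' contrast/2)`.  Running [transform_signals()] on the output recovers the
#' sampled coordinates exactly (up to floating point), so every downstream
#' stage can be tested against known truth.  Deterministic given the seed.
#'
#' @param cfg a `sim_config`, e.g. from [platform_preset()].
#' @return list with `signals` (data frame `snp_id`, `signal_A`,
#'   `signal_B`), `truth` (data frame `snp_id`, `genotype`, `maf`), and
#'   `config`.
#' @export
simulate_array <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  n <- cfg$n_snps
  p <- draw_maf(cfg$maf, n)
  u <- stats::runif(n)
  p_aa <- (1 - p)^2
  p_ab <- 2 * p * (1 - p)
  geno_idx <- ifelse(u < p_aa, 1L, ifelse(u < p_aa + p_ab, 2L, 3L))

  xy <- matrix(0, n, 2)
  for (k in 1:3) {
    sel <- geno_idx == k
    nk <- sum(sel)
    if (nk == 0L) next
    L <- chol(cfg$spreads[[k]])
    z <- matrix(stats::rnorm(2 * nk), nk, 2) %*% L
    xy[sel, 1] <- cfg$centers[k, 1] + z[, 1] +
      cfg$skew[k] * (z[, 2])^2
    xy[sel, 2] <- cfg$centers[k, 2] + z[, 2]
  }
  strength <- xy[, 1]
  contrast <- xy[, 2]
  ids <- sprintf("snp%06d", seq_len(n))
  signals <- data.frame(snp_id = ids,
                        signal_A = 10^(strength - contrast / 2),
                        signal_B = 10^(strength + contrast / 2),
                        stringsAsFactors = FALSE)
  truth <- data.frame(snp_id = ids,
                      genotype = c("AA", "AB", "BB")[geno_idx],
                      maf = p, stringsAsFactors = FALSE)
  list(signals = signals, truth = truth, config = cfg)
}

#' Platform presets for the simulator
#'
#' Ready-made cluster geometries:
#' * `affymetrix_like` — three clusters symmetric about contrast 0 (one-dye
#'   chemistry gives mirror-symmetric clouds) with overlapping Gaussian
#'   tails.  `separation` is the distance between adjacent cluster centers
#'   in units of the contrast spread; the default 7 gives well-separated but
#'   touching clusters.
#' * `illumina_like` — tighter, asymmetric clusters with a quadratic bend
#'   and near-zero density between clusters (two-dye chemistry), yielding
#'   higher calling confidence on equal data.
#' * `low_maf_stress` — affymetrix-like geometry with MAF drawn from
#'   `{0, 0.01, 0.05}`, so some arrays have nearly or exactly empty AB/BB
#'   clusters (exercises the extinct-component path).
#'
#' @param platform one of `"affymetrix_like"`, `"illumina_like"`,
#'   `"low_maf_stress"`.
#' @param n_snps number of SNPs.
#' @param seed RNG seed.
#' @param separation center spacing in contrast-spread units
#'   (affymetrix-like presets).
#' @param spread contrast standard deviation of each cluster
#'   (affymetrix-like presets).
#' @return a `sim_config`.
#' @export
platform_preset <- function(platform = c("affymetrix_like", "illumina_like",
                                         "low_maf_stress"),
                            n_snps = 1e5, seed = 1L,
                            separation = 7, spread = 0.2) {
  platform <- match.arg(platform)
  if (platform == "affymetrix_like" || platform == "low_maf_stress") {
    d <- separation * spread
    centers <- rbind(AA = c(2.2, -d), AB = c(2.3, 0), BB = c(2.2, d))
    spreads <- rep(list(diag(c(0.25, spread)^2)), 3)
    maf <- if (platform == "low_maf_stress") c(0, 0.01, 0.05)
           else list(type = "uniform", min = 0.05, max = 0.5)
    sim_config(n_snps, maf = maf, centers = centers, spreads = spreads,
               skew = c(0, 0, 0), seed = seed)
  } else {
    centers <- rbind(AA = c(2.35, -1.7), AB = c(2.5, 0.15), BB = c(2.3, 1.9))
    spreads <- list(diag(c(0.18, 0.09)^2), diag(c(0.18, 0.12)^2),
                    diag(c(0.18, 0.09)^2))
    sim_config(n_snps, maf = list(type = "uniform", min = 0.05, max = 0.5),
               centers = centers, spreads = spreads,
               skew = c(-0.25, -0.3, -0.25), seed = seed)
  }
}

#' Write a simulated array to TSV files with a JSON sidecar
#'
#' @param sim result of [simulate_array()].
#' @param signals_path,truth_path,config_path output files (`NULL` to skip
#'   truth or config).
#' @export
write_simulated_array <- function(sim, signals_path, truth_path = NULL,
                                  config_path = NULL) {
  utils::write.table(sim$signals, signals_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(truth_path))
    utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(config_path)) {
    cfg <- sim$config
    jsonlite::write_json(
      list(n_snps = cfg$n_snps, maf = cfg$maf, centers = cfg$centers,
           spreads = cfg$spreads, skew = cfg$skew, seed = cfg$seed),
      config_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(signals_path)
}
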