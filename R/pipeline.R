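#' Calling configuration with the advised defaults
#'
#' Collects every tunable of the pipeline in one place.  The defaults are
#' the advised settings: a 100 by 100 histogram, bases of 10+3 cubic
#' B-splines per direction, seed split at contrast -0.2 / 0.2, smoothing
#' parameter 300 shared by both penalty directions, and no NoCall threshold
#' (all three probabilities are stored, so a threshold can be applied
#' later).  Larger grids or bases only increase computing time without
#' changing calls, and the algorithm is relatively insensitive to the exact
#' amount of smoothing.
#'
#' @param nx,ny histogram bins per direction.
#' @param pad_fraction domain padding fraction, see [make_grid()].
#' @param xlim,ylim optional explicit histogram limits.
#' @param nseg,degree B-spline segments and degree per direction.
#' @param lambda smoothing parameter (scalar, or `c(lambda_r, lambda_c)`).
#' @param split_lo,split_hi seed split thresholds on contrast.
#' @param nocall_threshold optional NoCall threshold in `[1/3, 1]`; `NULL`
#'   accepts every classification.
#' @param clip_floor intensity clip floor on the raw scale.
#' @param flip_contrast flip the sign of contrast (reversed channel labels).
#' @param em_tol,em_maxit EM control.
#' @param irls_tol,irls_maxit inner penalized-Poisson solver control.
#' @return list of class `call_config`.
#' @export
call_config <- function(nx = 100, ny = 100, pad_fraction = 0.01,
                        xlim = NULL, ylim = NULL,
                        nseg = 10, degree = 3, lambda = 300,
                        split_lo = -0.2, split_hi = 0.2,
                        nocall_threshold = NULL,
                        clip_floor = 1, flip_contrast = FALSE,
                        em_tol = 1e-6, em_maxit = 50,
                        irls_tol = 1e-6, irls_maxit = 50) {
  structure(as.list(environment()), class = "call_config")
}

#' Genotype all SNPs on a single array
#'
#' The end-to-end pipeline: transform the two-channel intensities to
#' (strength, contrast), build the 2-D histogram, fit the three-component
#' log-concave mixture by EM, and call every SNP from its bin's membership
#' probabilities.  Deterministic: the same input and configuration always
#' produce the same calls.
#'
#' @param signals data frame with `snp_id`, `signal_A`, `signal_B`, or a
#'   path to a TSV file readable by [read_signals()].
#' @param config a [call_config()].
#' @param verbose print per-stage progress and timings to stderr.
#' @return list of class `genotype_run`: `calls` (a `genotype_calls` data
#'   frame), `fit` (`mixture_fit`), `histogram`, `grid`, `transformed`,
#'   `config`, `timings` (named seconds per stage).
#' @examples
#' sim <- simulate_array(platform_preset("affymetrix_like", n_snps = 2000))
#' run <- genotype_array(sim$signals, call_config(nx = 40, ny = 40, nseg = 6))
#' table(run$calls$call, sim$truth$genotype)
#' @export
genotype_array <- function(signals, config = call_config(), verbose = FALSE) {
  stopifnot(inherits(config, "call_config"))
  if (is.character(signals)) signals <- read_signals(signals)
  say <- function(...) if (verbose) message(sprintf(...))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()

  t0 <- tic()
  tt <- transform_signals(signals, clip_floor = config$clip_floor,
                          flip_contrast = config$flip_contrast)
  timings["transform"] <- tic() - t0
  if (any(tt$clipped))
    say("clipped %d SNP(s) at the intensity floor", sum(tt$clipped))

  t0 <- tic()
  grid <- make_grid(tt, nx = config$nx, ny = config$ny,
                    pad_fraction = config$pad_fraction,
                    xlim = config$xlim, ylim = config$ylim)
  h <- build_histogram(tt, grid)
  timings["histogram"] <- tic() - t0
  if (any(h$clamped))
    say("clamped %d SNP(s) to the histogram boundary", sum(h$clamped))
  say("histogram: %d x %d bins, %d SNPs", grid$nx, grid$ny, sum(h$counts))

  t0 <- tic()
  fit <- em_fit(h, nseg = config$nseg, degree = config$degree,
                lambda = config$lambda,
                split_lo = config$split_lo, split_hi = config$split_hi,
                em_tol = config$em_tol, em_maxit = config$em_maxit,
                irls_tol = config$irls_tol, irls_maxit = config$irls_maxit)
  timings["em"] <- tic() - t0
  say("EM: %d iterations (%s)", fit$em_iterations,
      if (fit$converged) "converged" else "not converged")

  t0 <- tic()
  calls <- call_genotypes(tt, fit, h)
  calls <- apply_nocall_threshold(calls, config$nocall_threshold)
  timings["calling"] <- tic() - t0

  structure(list(calls = calls, fit = fit, histogram = h, grid = grid,
                 transformed = tt, config = config, timings = timings),
            class = "genotype_run")
}

#' @export
print.genotype_run <- function(x, ...) {
  tab <- table(factor(x$calls$call, levels = GENO_LEVELS))
  cat(sprintf("Genotype run: %d SNPs on a %d x %d histogram\n",
              nrow(x$calls), x$grid$nx, x$grid$ny))
  cat(sprintf("  calls: AA=%d AB=%d BB=%d NN=%d\n",
              tab[["AA"]], tab[["AB"]], tab[["BB"]], tab[["NN"]]))
  cat(sprintf("  median P* = %.4f, EM iterations = %d\n",
              stats::median(x$calls$pstar), x$fit$em_iterations))
  invisible(x)
}

#' Read a two-channel signal table
#'
#' Reads the tab-separated input format: header `snp_id  signal_A
#' signal_B`, one row per SNP, comment lines starting with `#` ignored.
#' Malformed rows (missing fields, non-numeric signals) abort with the
#' offending line numbers.
#'
#' @param path TSV file.
#' @return data frame with `snp_id`, `signal_A`, `signal_B`.
#' @export
read_signals <- function(path) {
  if (!file.exists(path))
    stop("input error: file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character"))
  needed <- c("snp_id", "signal_A", "signal_B")
  if (!all(needed %in% names(df)))
    stop("parse error: header must contain ",
         paste(needed, collapse = ", "), call. = FALSE)
  for (nm in c("signal_A", "signal_B")) {
    suppressWarnings(v <- as.numeric(df[[nm]]))
    bad <- which(is.na(v) & !(df[[nm]] %in% c("NA", "")))
    if (length(bad))
      stop("parse error: non-numeric ", nm, " on data row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    df[[nm]] <- v
  }
  df
}

#' Read a reference call table
#'
#' TSV with columns `snp_id` and `call` in `{AA, AB, BB, NN}` (a header
#' naming the second column `genotype` is also accepted).
#'
#' @param path TSV file.
#' @return data frame with `snp_id`, `call`.
#' @export
read_reference_calls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  if ("genotype" %in% names(df) && !("call" %in% names(df)))
    names(df)[names(df) == "genotype"] <- "call"
  if (!all(c("snp_id", "call") %in% names(df)))
    stop("parse error: need columns snp_id and call", call. = FALSE)
  bad <- setdiff(unique(df$call), GENO_LEVELS)
  if (length(bad))
    stop("parse error: unknown call label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  df[, c("snp_id", "call")]
}

#' Write a genotype call table as TSV
#'
#' Columns: `snp_id`, `call`, `p_AA`, `p_AB`, `p_BB`, `pstar`, `flags`
#' (semicolon-joined subset of `clipped`, `clamped`, `tie`).
#'
#' @param calls a `genotype_calls` table.
#' @param path output file.
#' @export
write_calls <- function(calls, path) {
  flags <- apply(cbind(ifelse(calls$clipped, "clipped", ""),
                       ifelse(calls$clamped, "clamped", ""),
                       ifelse(calls$tie, "tie", "")), 1L,
                 function(r) paste(r[nzchar(r)], collapse = ";"))
  out <- data.frame(snp_id = calls$snp_id, call = calls$call,
                    p_AA = sprintf("%.6g", calls$p_AA),
                    p_AB = sprintf("%.6g", calls$p_AB),
                    p_BB = sprintf("%.6g", calls$p_BB),
                    pstar = sprintf("%.6g", calls$pstar),
                    flags = flags, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a concordance table (counts and percentages) as TSV
#'
#' @param ct a `concordance_table` from [crosstab()].
#' @param counts_path,percent_path output files (`NULL` to skip one).
#' @export
write_concordance <- function(ct, counts_path, percent_path = NULL) {
  wr <- function(m, p) {
    df <- data.frame(call = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(ct$counts, counts_path)
  if (!is.null(percent_path)) wr(round(ct$percent, 2), percent_path)
  invisible(counts_path)
}

#' Serialize a run configuration to JSON (and read it back)
#'
#' The sidecar records every tunable of a run; [read_config_json()] restores
#' a `call_config` so the run can be reproduced exactly.
#'
#' @param config a `call_config`.
#' @param path JSON file.
#' @export
write_config_json <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- call_config()
  for (nm in names(defaults))
    if (!is.null(obj[[nm]])) defaults[[nm]] <- obj[[nm]]
  defaults
}
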