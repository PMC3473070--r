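#' Transform two-channel allele intensities to (strength, contrast)
#'
#' Maps linear-scale fluorescence intensities for alleles A and B to the
#' plane in which genotype clusters separate: `strength`, the mean of the two
#' log10 intensities (overall signal level), and `contrast`, the log10 ratio
#' of the B over the A channel.  With this orientation the BB cluster sits at
#' positive contrast, AA at negative contrast and heterozygotes near zero, so
#' the three genotype clouds form three horizontal bands.
#'
#' Non-positive or missing intensities are clipped to `clip_floor` before
#' taking logs, so every SNP gets finite coordinates (and eventually a call);
#' clipped SNPs are flagged rather than dropped.
#'
#' @param raw data frame with columns `snp_id`, `signal_A`, `signal_B`
#'   (linear-scale intensities), as returned by [read_signals()].
#' @param clip_floor positive scalar; intensities below it (including zeros,
#'   negatives and `NA`) are raised to this value before the log transform.
#'   Default 1 on the raw intensity scale.
#' @param flip_contrast logical; if `TRUE` the sign of `contrast` is flipped
#'   (use when the platform's channel labelling is reversed).
#' @return data frame of class `transformed_table` with columns `snp_id`,
#'   `strength`, `contrast`, `clipped`.
#' @examples
#' raw <- data.frame(snp_id = c("s1", "s2"),
#'                   signal_A = c(100, 1000), signal_B = c(100, 10))
#' transform_signals(raw)
#' @export
transform_signals <- function(raw, clip_floor = 1, flip_contrast = FALSE) {
  if (!is.data.frame(raw) || nrow(raw) == 0L)
    stop("input error: 'raw' must be a non-empty data frame", call. = FALSE)
  needed <- c("snp_id", "signal_A", "signal_B")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("input error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!is.numeric(clip_floor) || length(clip_floor) != 1L || clip_floor <= 0)
    stop("config error: clip_floor must be a positive scalar", call. = FALSE)

  a <- raw$signal_A
  b <- raw$signal_B
  for (nm in c("signal_A", "signal_B")) {
    v <- raw[[nm]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("parse error: non-numeric ", nm, " for SNP(s) ",
             paste(utils::head(raw$snp_id[bad], 5L), collapse = ", "),
             call. = FALSE)
      if (nm == "signal_A") a <- vn else b <- vn
    }
  }
  if (anyDuplicated(raw$snp_id))
    stop("input error: duplicated snp_id within one array", call. = FALSE)

  tc <- .transform_cpp(a, b, clip_floor, isTRUE(flip_contrast))
  out <- data.frame(snp_id = as.character(raw$snp_id),
                    strength = tc$strength,
                    contrast = tc$contrast,
                    clipped = tc$clipped,
                    stringsAsFactors = FALSE)
  class(out) <- c("transformed_table", class(out))
  out
}

#' Seed partition of SNPs into three contrast sectors
#'
#' Two horizontal lines in the (strength, contrast) plane split the SNPs into
#' three sectors that seed the EM algorithm: contrast below `split_lo` is
#' labelled AA, above `split_hi` BB, and the closed middle band AB.  The
#' defaults -0.2 and 0.2 work for typical arrays; the exact positions are not
#' critical because EM refines the partition.
#'
#' @param transformed a `transformed_table` from [transform_signals()].
#' @param split_lo,split_hi contrast thresholds, `split_lo < split_hi`.
#'   Boundary values (contrast exactly at a threshold) go to AB.
#' @return object of class `seed_partition`: list with `split_lo`,
#'   `split_hi` and `labels`, a character vector in `{"AA","AB","BB"}`
#'   aligned with the rows of `transformed`.
#' @export
seed_labels <- function(transformed, split_lo = -0.2, split_hi = 0.2) {
  stopifnot(is.data.frame(transformed), "contrast" %in% names(transformed))
  if (!(is.numeric(split_lo) && is.numeric(split_hi) && split_lo < split_hi))
    stop("config error: need split_lo < split_hi", call. = FALSE)
  ct <- transformed$contrast
  labels <- ifelse(ct < split_lo, "AA", ifelse(ct > split_hi, "BB", "AB"))
  structure(list(split_lo = split_lo, split_hi = split_hi, labels = labels),
            class = "seed_partition")
}

#' @export
print.seed_partition <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c("AA", "AB", "BB")))
  cat(sprintf("Seed partition at contrast (%g, %g): AA=%d AB=%d BB=%d\n",
              x$split_lo, x$split_hi, tab[["AA"]], tab[["AB"]], tab[["BB"]]))
  invisible(x)
}
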