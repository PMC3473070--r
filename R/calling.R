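GENO_LEVELS <- c("AA", "AB", "BB", "NN")

# Argmax with a fixed deterministic tie order preferring AB, then AA, then
# BB.  Exact ties are measure-zero but must not depend on storage order.
argmax_call <- function(p_aa, p_ab, p_bb) {
  am <- .argmax3_cpp(p_aa, p_ab, p_bb)
  list(call = c("AA", "AB", "BB")[am$code], tie = am$tie, pstar = am$pstar)
}

#' Call genotypes for every SNP from a fitted mixture
#'
#' Each SNP inherits the membership-probability triple of its histogram bin;
#' the genotype with the largest probability is the call, and the maximum
#' itself (`pstar`) measures calling confidence.  Because all three
#' probabilities are stored, a NoCall threshold can be applied later at any
#' time with [apply_nocall_threshold()]; by default no threshold is applied
#' and every SNP is called.
#'
#' @param transformed a `transformed_table` for the array.
#' @param fit a `mixture_fit` for the same array.
#' @param h the `histogram2d` the fit was computed on (provides each SNP's
#'   bin).
#' @return data frame of class `genotype_calls` with columns `snp_id`,
#'   `call` (in AA/AB/BB), `p_AA`, `p_AB`, `p_BB`, `pstar`, and logical
#'   flags `clipped`, `clamped`, `tie`.
#' @export
call_genotypes <- function(transformed, fit, h) {
  stopifnot(inherits(fit, "mixture_fit"), inherits(h, "histogram2d"))
  if (nrow(transformed) != nrow(h$bin_index) ||
      !identical(as.character(transformed$snp_id), as.character(h$snp_id)))
    stop("internal error: transformed table and histogram bin map disagree ",
         "(grid/fit mismatch)", call. = FALSE)
  flat <- h$bin_index
  p_aa <- fit$membership$AA[flat]
  p_ab <- fit$membership$AB[flat]
  p_bb <- fit$membership$BB[flat]
  am <- argmax_call(p_aa, p_ab, p_bb)
  out <- data.frame(
    snp_id = as.character(transformed$snp_id),
    call = am$call,
    p_AA = p_aa, p_AB = p_ab, p_BB = p_bb,
    pstar = am$pstar,
    clipped = if ("clipped" %in% names(transformed)) transformed$clipped
              else FALSE,
    clamped = h$clamped,
    tie = am$tie,
    stringsAsFactors = FALSE)
  class(out) <- c("genotype_calls", class(out))
  out
}

#' Apply (or re-apply) a NoCall threshold
#'
#' SNPs whose maximum membership probability falls below `threshold` are set
#' to NN; their probabilities are retained so the threshold can be changed
#' later.  Thresholding at 1/3 is the identity (the maximum of three
#' probabilities summing to one can never be smaller), and the operation is
#' idempotent and monotone in the threshold.
#'
#' @param calls a `genotype_calls` table.
#' @param threshold numeric in `[1/3, 1]`, or `NULL` for no thresholding
#'   (the default calling policy).
#' @return the table with `call` replaced by NN where `pstar < threshold`.
#' @export
apply_nocall_threshold <- function(calls, threshold = NULL) {
  if (is.null(threshold)) return(calls)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 1 / 3 || threshold > 1)
    stop("config error: threshold must lie in [1/3, 1]", call. = FALSE)
  calls$call[calls$pstar < threshold] <- "NN"
  calls
}

#' Cross-tabulate calls against a reference
#'
#' Builds the 4 x 4 concordance table with this method's calls as rows and
#' the reference calls as columns, both over the label order AA, AB, BB, NN,
#' matched on `snp_id`.  The percentage view normalizes each column to sum
#' to 100, i.e. each reference genotype class is broken down across the
#' method's calls.
#'
#' @param calls a `genotype_calls` table (or any data frame with `snp_id`
#'   and `call`).
#' @param reference data frame with `snp_id` and `call` in AA/AB/BB/NN.
#' @return object of class `concordance_table`: list with `counts` (4 x 4
#'   integer matrix), `percent` (columns summing to 100; `NaN` for empty
#'   reference columns), `n_compared`, `n_only_calls`, `n_only_reference`.
#' @export
crosstab <- function(calls, reference) {
  stopifnot(all(c("snp_id", "call") %in% names(calls)),
            all(c("snp_id", "call") %in% names(reference)))
  m <- merge(calls[, c("snp_id", "call")],
             reference[, c("snp_id", "call")],
             by = "snp_id", suffixes = c("_ours", "_ref"))
  if (nrow(m) == 0L)
    stop("input error: no overlapping snp_id between calls and reference",
         call. = FALSE)
  counts <- table(factor(m$call_ours, levels = GENO_LEVELS),
                  factor(m$call_ref, levels = GENO_LEVELS))
  counts <- unclass(counts)
  colsum <- colSums(counts)
  percent <- sweep(counts, 2, ifelse(colsum > 0, colsum, NA), "/") * 100
  structure(list(counts = counts, percent = percent,
                 n_compared = nrow(m),
                 n_only_calls = length(setdiff(calls$snp_id, reference$snp_id)),
                 n_only_reference = length(setdiff(reference$snp_id,
                                                   calls$snp_id))),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat("Concordance (rows = this method, columns = reference):\n")
  print(x$counts)
  cat(sprintf("%d SNPs compared (%d only in calls, %d only in reference)\n",
              x$n_compared, x$n_only_calls, x$n_only_reference))
  invisible(x)
}

#' Per-SNP minor allele frequency across arrays
#'
#' Pools genotype calls for each SNP over a collection of arrays and
#' computes the B-allele frequency `f = (2 nBB + nAB) / (2 (nAA + nAB +
#' nBB))` and the minor allele frequency `min(f, 1 - f)`.  NN calls are
#' excluded; a SNP with no called genotype on any array gets `NA`.
#'
#' @param call_tables list of `genotype_calls` tables (one per array), or a
#'   single table.
#' @return data frame with columns `snp_id`, `n_called`, `freq_B`, `maf`.
#' @export
compute_maf <- function(call_tables) {
  if (is.data.frame(call_tables)) call_tables <- list(call_tables)
  if (length(call_tables) == 0L)
    stop("input error: need at least one call table", call. = FALSE)
  all_calls <- do.call(rbind, lapply(call_tables, function(ct)
    data.frame(snp_id = ct$snp_id, call = ct$call,
               stringsAsFactors = FALSE)))
  all_calls <- all_calls[all_calls$call != "NN", , drop = FALSE]
  ids <- sort(unique(unlist(lapply(call_tables, `[[`, "snp_id"))))
  tab <- table(factor(all_calls$snp_id, levels = ids),
               factor(all_calls$call, levels = c("AA", "AB", "BB")))
  n_called <- rowSums(tab)
  freq_b <- ifelse(n_called > 0,
                   (2 * tab[, "BB"] + tab[, "AB"]) / (2 * n_called), NA)
  data.frame(snp_id = ids,
             n_called = as.integer(n_called),
             freq_B = as.numeric(freq_b),
             maf = pmin(as.numeric(freq_b), 1 - as.numeric(freq_b)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Calling-quality summaries
#'
#' Summaries used to judge calling confidence: the per-array distribution of
#' the maximum membership probability `pstar` (its support is `[1/3, 1]`),
#' the per-SNP mean `pstar` across arrays (a per-marker quality indicator),
#' and the per-SNP count of distinct genotypes observed across arrays (1, 2
#' or 3; markers showing a single genotype everywhere are typically low-MAF).
#'
#' @param call_tables list of `genotype_calls` tables, or a single table.
#' @return list with `per_array` (data frame: array, n, min/median/mean
#'   pstar), `pstar_ecdf` (pooled empirical CDF function), `per_snp` (data
#'   frame: snp_id, mean_pstar, n_genotypes).
#' @export
quality_summaries <- function(call_tables) {
  if (is.data.frame(call_tables)) call_tables <- list(call_tables)
  if (length(call_tables) == 0L)
    stop("input error: need at least one call table", call. = FALSE)
  per_array <- do.call(rbind, lapply(seq_along(call_tables), function(k) {
    ps <- call_tables[[k]]$pstar
    data.frame(array = k, n = length(ps), min_pstar = min(ps),
               median_pstar = stats::median(ps), mean_pstar = mean(ps))
  }))
  pooled <- unlist(lapply(call_tables, `[[`, "pstar"))
  stacked <- do.call(rbind, lapply(call_tables, function(ct)
    data.frame(snp_id = ct$snp_id, call = ct$call, pstar = ct$pstar,
               stringsAsFactors = FALSE)))
  mean_ps <- tapply(stacked$pstar, stacked$snp_id, mean)
  called <- stacked[stacked$call != "NN", , drop = FALSE]
  n_geno <- tapply(called$call, called$snp_id,
                   function(v) length(unique(v)))
  ids <- names(mean_ps)
  per_snp <- data.frame(snp_id = ids,
                        mean_pstar = as.numeric(mean_ps),
                        n_genotypes = as.integer(n_geno[ids]),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(per_array = per_array, pstar_ecdf = stats::ecdf(pooled),
       per_snp = per_snp)
}
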