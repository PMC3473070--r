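#' Build a uniform 2-D grid over the transformed coordinates
#'
#' Constructs the uniform `nx` by `ny` grid on which the histogram of all
#' SNPs is accumulated.  A 100 by 100 grid is the advised default; finer
#' grids only increase computing time without changing calls.  The domain is
#' the data range in each coordinate, padded by `pad_fraction` of the range
#' on each side so that boundary B-splines are not dominated by edge bins.
#'
#' @param transformed a `transformed_table`, or any data frame with
#'   `strength` and `contrast` columns.
#' @param nx,ny number of bins for strength (x) and contrast (y); at least 8.
#' @param pad_fraction non-negative fraction of the data range added on each
#'   side of the domain.
#' @param xlim,ylim optional explicit domain limits `c(lo, hi)`; when given
#'   they override the data range (padding is not applied to explicit
#'   limits).
#' @return object of class `grid_spec`: list with `nx`, `ny`, `x_edges`,
#'   `y_edges` (length `nx+1`, `ny+1`, strictly increasing) and midpoints
#'   `x_mid`, `y_mid`.
#' @export
make_grid <- function(transformed, nx = 100, ny = 100, pad_fraction = 0.01,
                      xlim = NULL, ylim = NULL) {
  if (nx < 8 || ny < 8)
    stop("config error: nx and ny must be at least 8", call. = FALSE)
  if (pad_fraction < 0)
    stop("config error: pad_fraction must be >= 0", call. = FALSE)

  lim1 <- function(v, lim, what) {
    if (!is.null(lim)) {
      stopifnot(length(lim) == 2L, lim[1] < lim[2])
      return(lim)
    }
    r <- range(v, finite = TRUE)
    if (!(r[2] > r[1]))
      stop("config error: degenerate ", what,
           " range (all SNPs identical); supply explicit limits",
           call. = FALSE)
    r + c(-1, 1) * pad_fraction * diff(r)
  }
  xr <- lim1(transformed$strength, xlim, "strength")
  yr <- lim1(transformed$contrast, ylim, "contrast")

  x_edges <- seq(xr[1], xr[2], length.out = nx + 1L)
  y_edges <- seq(yr[1], yr[2], length.out = ny + 1L)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 x_edges = x_edges, y_edges = y_edges,
                 x_mid = (x_edges[-1] + x_edges[-(nx + 1L)]) / 2,
                 y_mid = (y_edges[-1] + y_edges[-(ny + 1L)]) / 2),
            class = "grid_spec")
}


#' Accumulate the 2-D histogram of all SNPs on one array
#'
#' Counts SNPs in each grid cell and records every SNP's bin, the step that
#' decouples the mixture fit from the number of SNPs: all later computation
#' works on the `nx` by `ny` count matrix, never on the raw points.
#'
#' Bins are half-open `[lo, hi)` with the final bin in each direction closed,
#' so the domain maximum is counted.  Points outside the grid domain are
#' clamped to the nearest boundary bin and flagged (no SNP is ever lost),
#' unless `clamp = FALSE` in which case they raise an error.
#'
#' @param transformed a `transformed_table`.
#' @param grid a `grid_spec` from [make_grid()].
#' @param clamp logical; clamp out-of-domain points to boundary bins.
#' @return object of class `histogram2d`: list with `counts` (`nx` by `ny`
#'   integer matrix, rows index strength bins, columns contrast bins),
#'   `grid`, `bin_index` (n by 2 integer matrix of (i, j) bins per SNP),
#'   `snp_id` and logical `clamped` per SNP.
#' @export
build_histogram <- function(transformed, grid, clamp = TRUE) {
  stopifnot(inherits(grid, "grid_spec"))
  ids <- transformed$snp_id
  bb <- .bin2d_cpp(transformed$strength, transformed$contrast,
                   grid$x_edges, grid$y_edges, clamp)
  if (!clamp && any(bb$clamped))
    stop("range error: ", sum(bb$clamped), " SNP(s) outside the grid ",
         "domain, e.g. ",
         paste(utils::head(ids[bb$clamped], 5L), collapse = ", "),
         call. = FALSE)
  structure(list(counts = bb$counts, grid = grid,
                 bin_index = cbind(i = bb$i, j = bb$j),
                 snp_id = ids,
                 clamped = bb$clamped),
            class = "histogram2d")
}

#' @export
print.histogram2d <- function(x, ...) {
  cat(sprintf("2-D histogram: %d x %d bins, %d SNPs (%d clamped), %d occupied bins\n",
              x$grid$nx, x$grid$ny, sum(x$counts), sum(x$clamped),
              sum(x$counts > 0)))
  invisible(x)
}

#' Write a count matrix as TSV (debug aid)
#'
#' @param h a `histogram2d`.
#' @param path output file.
#' @export
write_histogram_tsv <- function(h, path) {
  utils::write.table(h$counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
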