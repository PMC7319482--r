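#' Discrete cell-volume grid on a log2 lattice
#'
#' Cell volumes are binned into `m` classes whose centers sit on a log2
#' lattice with `p` classes per volume doubling: the center of class i is
#' `v_min * 2^((i-1)/p)`. Class edges sit on the same lattice, half a class
#' width (in log2 space) either side of each center. The lattice guarantees
#' that halving the volume of a class-i cell lands exactly on the center of
#' class i - p, so cell division is an exact shift of p classes.
#'
#' @param v_min volume of the class-1 center (um^3).
#' @param p integer classes per volume doubling.
#' @param m integer number of classes; must exceed `p` (otherwise no class
#'   could divide within the grid).
#' @return an object of class `size_grid`: list with `m`, `v_min`, `p`,
#'   `centers` (length m) and `edges` (length m + 1).
#' @examples
#' g <- size_grid(0.05, p = 1, m = 5)
#' g$centers  # 0.05 0.1 0.2 0.4 0.8
#' @export
size_grid <- function(v_min = 0.02, p = 4L, m = 25L) {
  stopifnot(v_min > 0, p >= 1, m == round(m), p == round(p))
  if (m <= p) {
    stop("m must exceed p: with m <= p no class can divide within the grid")
  }
  i <- seq_len(m)
  g <- structure(list(
    m = as.integer(m), v_min = v_min, p = as.integer(p),
    centers = v_min * 2^((i - 1) / p),
    edges = v_min * 2^((seq_len(m + 1) - 1.5) / p)
  ), class = "size_grid")
  g
}

#' @export
print.size_grid <- function(x, ...) {
  cat(sprintf("size_grid: %d classes, %d per doubling, centers %.4g-%.4g um^3\n",
              x$m, x$p, min(x$centers), max(x$centers)))
  invisible(x)
}
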