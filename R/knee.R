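#' Barcode rank curve
#'
#' Ranks barcode UMI totals in non-increasing order, dropping zero-count
#' barcodes. This is the curve behind the knee plot used to separate
#' cell-containing droplets from ambient barcodes.
#'
#' @param totals numeric vector of per-barcode UMI totals (or a count
#'   matrix, in which case column totals are used).
#' @return an object of class `barcode_rank_curve`: a data frame with
#'   columns `rank` and `total`, non-increasing in `total`.
#' @export
barcode_rank_curve <- function(totals) {
  if (is.matrix(totals) || inherits(totals, "Matrix")) totals <- col_totals(totals)
  totals <- as.numeric(totals)
  totals <- totals[totals > 0]
  if (!length(totals)) stop2("no barcodes with positive counts")
  curve <- data.frame(rank = seq_along(totals),
                      total = sort(totals, decreasing = TRUE))
  class(curve) <- c("barcode_rank_curve", "data.frame")
  curve
}

#' Knee-point threshold for cell calling
#'
#' Finds the knee of the log10(rank) vs log10(count) barcode curve as the
#' rank maximizing the perpendicular distance to the chord joining the first
#' and last points, the standard parameter-free automation of the visual
#' knee plot. The UMI total at that rank is the calling threshold; barcodes
#' with totals at or above it are retained as cells. Ties in the distance
#' are broken toward the larger rank, i.e. more cells retained.
#'
#' @param curve a `barcode_rank_curve`, or anything accepted by
#'   [barcode_rank_curve()].
#' @return a list with `umi_threshold`, `retained` (number of barcodes at or
#'   above the threshold), and `knee_rank`.
#' @export
knee_threshold <- function(curve) {
  if (!inherits(curve, "barcode_rank_curve")) curve <- barcode_rank_curve(curve)
  n <- nrow(curve)
  if (n < 10) stop2("need at least 10 positive barcodes for knee detection")
  y <- log10(curve$total)
  if (length(unique(curve$total)) < 2)
    stop2("degenerate barcode curve: all counts equal, no knee")
  x <- log10(curve$rank)
  d <- .chord_distance(x, y)
  # ties toward larger rank: pick the last index attaining the maximum
  knee <- max(which(d >= max(d) - 1e-12))
  thr <- curve$total[knee]
  list(umi_threshold = thr,
       retained = sum(curve$total >= thr),
       knee_rank = knee)
}

# perpendicular distance of each (x, y) point to the chord from the first
# to the last point of the curve
.chord_distance <- function(x, y) {
  x1 <- x[1]; y1 <- y[1]
  xn <- x[length(x)]; yn <- y[length(y)]
  len <- sqrt((xn - x1)^2 + (yn - y1)^2)
  if (len == 0) return(rep(0, length(x)))
  abs((yn - y1) * x - (xn - x1) * y + xn * y1 - yn * x1) / len
}

#' Call cells from a count matrix by the knee rule
#'
#' Convenience wrapper: builds the barcode rank curve from column totals,
#' finds the knee threshold and subsets the matrix to retained barcodes.
#'
#' @param counts genes x cells count matrix.
#' @return a list with the subset `counts`, the `threshold` result from
#'   [knee_threshold()], and the dropped barcode count.
#' @export
call_cells <- function(counts) {
  totals <- col_totals(counts)
  thr <- knee_threshold(barcode_rank_curve(totals))
  keep <- totals >= thr$umi_threshold
  list(counts = counts[, keep, drop = FALSE],
       threshold = thr,
       dropped = sum(!keep))
}
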