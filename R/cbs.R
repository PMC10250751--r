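#' Best circular arc under the CBS statistic
#'
#' Exhaustively maximizes the two-sample CBS statistic
#' `|mean_in - mean_out| / (s * sqrt(1/k + 1/(n-k)))` over all circular arcs
#' `(i, j]` whose arc and complement both contain at least `min_width`
#' points. Ties keep the first arc in scan order (i ascending, then j).
#' Exposed mainly so the scan can be checked against independent brute-force
#' enumeration.
#'
#' @param values Numeric vector (one chromosome, position-ordered).
#' @param min_width Minimum points on each side of the split.
#' @return list with `i`, `j` (0-based boundary indices: the arc covers
#'   elements `(i+1):j`) and `stat`; `stat` is 0 for constant or too-short
#'   input.
#' @export
cbs_best_arc <- function(values, min_width = 3) {
  stopifnot(is.numeric(values), min_width >= 1)
  cbs_scan_cpp(as.numeric(values), as.integer(min_width))
}

#' Circular binary segmentation
#'
#' Recursive change-point detection on ordered genomic values: the best arc
#' of the current interval (see [cbs_best_arc()]) is accepted as a split if
#' its permutation p-value is below `alpha` (label permutations, seeded,
#' with early stopping once rejection is certain); accepted boundaries are
#' added and the resulting pieces are segmented recursively.
#'
#' @param positions Numeric vector of genomic positions, strictly
#'   increasing; used to validate ordering (the statistic itself is
#'   rank-based on the ordered values).
#' @param values Numeric vector, same length as `positions`.
#' @param alpha Significance level for accepting a split.
#' @param n_perm Number of permutations.
#' @param min_width Minimum number of points in any resulting segment.
#' @param seed Optional integer seed making the permutation stream
#'   reproducible.
#' @return Sorted integer vector of breakpoints as after-indices: a value
#'   `b` means a boundary between `values[b]` and `values[b + 1]`. Empty
#'   when no split is accepted (e.g. fewer than `2 * min_width` points).
#' @examples
#' x <- c(rnorm(20), rnorm(20, mean = 2))
#' cbs_segment(seq_along(x), x, seed = 1)
#' @export
cbs_segment <- function(positions, values, alpha = 0.01, n_perm = 1000,
                        min_width = 3, seed = NULL) {
  stopifnot(length(positions) == length(values),
            !is.unsorted(positions, strictly = TRUE),
            all(is.finite(values)), alpha > 0, alpha < 1, n_perm >= 1,
            min_width >= 1)
  n <- length(values)
  recurse <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 2 * min_width) return(integer(0))
    res <- cbs_split_test_cpp(values[lo:hi], as.integer(min_width),
                              as.integer(n_perm), alpha)
    if (res$stat <= 0 || res$p >= alpha) return(integer(0))
    cuts <- integer(0)
    if (res$i > 0) cuts <- c(cuts, lo - 1 + res$i)
    if (res$j < m) cuts <- c(cuts, lo - 1 + res$j)
    if (!length(cuts)) return(integer(0))
    bounds <- c(lo - 1, cuts, hi)
    kids <- lapply(seq_len(length(bounds) - 1), function(k) {
      recurse(bounds[k] + 1, bounds[k + 1])
    })
    c(cuts, unlist(kids))
  }
  brk <- with_seed(seed, recurse(1, n))
  sort(unique(as.integer(brk)))
}
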