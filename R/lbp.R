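# Local binary patterns (P = 8 neighbors, radius 1).

lbp_offsets <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                    c(1, 1), c(1, 0), c(1, -1), c(0, -1))

#' LBP code of a single 3x3 neighborhood
#'
#' The 8 neighbors are visited clockwise from the top-left corner; bit n is
#' set when `s(diff_n) = 1` with `s(x) = 1` iff `x >= 0`. The default
#' convention takes `diff = center - neighbor`; the canonical LBP convention
#' (`neighbor - center`) is available as the alternative, since the two
#' differ for strict inequalities.
#'
#' @param window A 3x3 numeric matrix.
#' @param convention Sign convention for the thresholded difference.
#' @return Integer code in [0, 255].
#' @export
lbp_code <- function(window,
                     convention = c("center_minus_neighbor",
                                    "neighbor_minus_center")) {
  convention <- match.arg(convention)
  if (!is.matrix(window) || any(dim(window) != c(3, 3))) {
    stop("window must be 3x3", call. = FALSE)
  }
  center <- window[2, 2]
  code <- 0L
  for (n in 0:7) {
    off <- lbp_offsets[[n + 1]]
    nb <- window[2 + off[1], 2 + off[2]]
    d <- if (convention == "center_minus_neighbor") center - nb else
      nb - center
    if (d >= 0) code <- code + 2L^n
  }
  as.integer(code)
}

#' Normalized LBP code histogram of a patch
#'
#' Codes are computed at every interior pixel (radius-1 neighborhood fully
#' inside the patch) and binned into 2^8 = 256 proportions summing to 1.
#' Because codes depend only on intensity differences, the histogram is
#' invariant under positive affine intensity maps.
#'
#' @param patch Numeric matrix, at least 3x3.
#' @param convention See [lbp_code()].
#' @return Numeric vector of 256 proportions (names "lbp_000".."lbp_255").
#' @export
lbp_histogram <- function(patch,
                          convention = c("center_minus_neighbor",
                                         "neighbor_minus_center")) {
  convention <- match.arg(convention)
  stop_if_not_matrix(patch, "patch")
  h <- nrow(patch); w <- ncol(patch)
  if (h < 3 || w < 3) stop("patch must be at least 3x3", call. = FALSE)
  center <- patch[2:(h - 1), 2:(w - 1), drop = FALSE]
  codes <- matrix(0L, h - 2, w - 2)
  for (n in 0:7) {
    off <- lbp_offsets[[n + 1]]
    nb <- patch[(2 + off[1]):(h - 1 + off[1]),
                (2 + off[2]):(w - 1 + off[2]), drop = FALSE]
    d <- if (convention == "center_minus_neighbor") center - nb else
      nb - center
    codes <- codes + (d >= 0) * 2L^n
  }
  counts <- tabulate(as.vector(codes) + 1L, nbins = 256L)
  stats::setNames(counts / sum(counts),
                  sprintf("lbp_%03d", 0:255))
}
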