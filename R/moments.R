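# Image moments and the seven Hu invariants.
#
# Convention: x indexes columns (width), y indexes rows (height), so
# I(x, y) = image[y, x]. Invariance properties do not depend on this choice.

#' Central image moment
#'
#' `mu_{p,q} = sum_x sum_y (x - xbar)^p (y - ybar)^q I(x, y)` with
#' `(xbar, ybar)` the intensity centroid.
#'
#' @param image Numeric matrix with positive total intensity.
#' @param p,q Non-negative integer orders (p along columns, q along rows).
#' @return The moment value.
#' @export
central_moment <- function(image, p, q) {
  stop_if_not_matrix(image)
  if (p < 0 || q < 0) stop("orders must be >= 0", call. = FALSE)
  total <- sum(image)
  if (total <= 0) {
    stop("image has no positive intensity mass; centroid undefined",
         call. = FALSE)
  }
  x <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  y <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  xbar <- sum(x * image) / total
  ybar <- sum(y * image) / total
  sum((x - xbar)^p * (y - ybar)^q * image)
}

#' The seven Hu moment invariants
#'
#' Computed from scale-normalized central moments
#' `eta_{p,q} = mu_{p,q} / mu_{0,0}^(1 + (p+q)/2)`, which makes them
#' invariant to translation, rotation and scale of the intensity pattern.
#' For numeric stability each invariant h is reported log-scaled as
#' `sign(h) * log10(|h| + eps)`, `eps = 1e-30`, unless `log_scale = FALSE`.
#'
#' @param image Numeric matrix with positive total intensity.
#' @param log_scale Report signed log10 magnitudes?
#' @param eps Stabilizer added inside the log.
#' @return Named numeric vector `hu_1`..`hu_7`.
#' @export
hu_invariants <- function(image, log_scale = TRUE, eps = 1e-30) {
  eta <- function(p, q) {
    central_moment(image, p, q) / sum(image)^(1 + (p + q) / 2)
  }
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  h <- numeric(7)
  h[1] <- n20 + n02
  h[2] <- (n20 - n02)^2 + 4 * n11^2
  h[3] <- (n30 - 3 * n12)^2 + (3 * n21 - n03)^2
  h[4] <- (n30 + n12)^2 + (n21 + n03)^2
  h[5] <- (n30 - 3 * n12) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) +
    (3 * n21 - n03) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  h[6] <- (n20 - n02) * ((n30 + n12)^2 - (n21 + n03)^2) +
    4 * n11 * (n30 + n12) * (n21 + n03)
  h[7] <- (3 * n21 - n03) * (n30 + n12) *
    ((n30 + n12)^2 - 3 * (n21 + n03)^2) -
    (n30 - 3 * n12) * (n21 + n03) *
    (3 * (n30 + n12)^2 - (n21 + n03)^2)
  if (log_scale) h <- sign(h) * log10(abs(h) + eps)
  stats::setNames(h, paste0("hu_", 1:7))
}
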