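# Canny edge detection and fixed-length edge summary features.
#
# The detector is the classical pipeline: Gaussian smoothing, Sobel
# gradients, non-maximum suppression along the quantized gradient
# direction, and double-threshold hysteresis (weak edges survive only in
# 8-connected components that contain a strong edge).

# Separable convolution with a 1-D kernel along both axes, replicate
# padding.
gaussian_smooth <- function(img, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_dim <- function(m, along_rows) {
    h <- nrow(m); w <- ncol(m)
    out <- matrix(0, h, w)
    for (t in -r:r) {
      if (along_rows) {
        idx <- clip(seq_len(h) + t, 1, h)
        out <- out + k[t + r + 1] * m[idx, , drop = FALSE]
      } else {
        idx <- clip(seq_len(w) + t, 1, w)
        out <- out + k[t + r + 1] * m[, idx, drop = FALSE]
      }
    }
    out
  }
  conv_dim(conv_dim(img, TRUE), FALSE)
}

sobel_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  pad <- function(m) {
    m <- rbind(m[1, ], m, m[h, ])
    cbind(m[, 1], m, m[, w])
  }
  p <- pad(img)
  at <- function(dr, dc) p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  gx <- (at(-1, 1) + 2 * at(0, 1) + at(1, 1)) -
    (at(-1, -1) + 2 * at(0, -1) + at(1, -1))
  gy <- (at(1, -1) + 2 * at(1, 0) + at(1, 1)) -
    (at(-1, -1) + 2 * at(-1, 0) + at(-1, 1))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Keep pixels whose magnitude is a local maximum along the gradient
# direction quantized to 0/45/90/135 degrees.
non_max_suppress <- function(gx, gy, mag) {
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                   ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  keep <- matrix(FALSE, nrow(mag), ncol(mag))
  nb <- list(`0` = list(c(0, 1), c(0, -1)),
             `45` = list(c(-1, 1), c(1, -1)),
             `90` = list(c(-1, 0), c(1, 0)),
             `135` = list(c(-1, -1), c(1, 1)))
  for (s in c(0L, 45L, 90L, 135L)) {
    offs <- nb[[as.character(s)]]
    m1 <- shift_matrix(mag, -offs[[1]][1], -offs[[1]][2], fill = -Inf)
    m2 <- shift_matrix(mag, -offs[[2]][1], -offs[[2]][2], fill = -Inf)
    keep <- keep | (sector == s & mag >= m1 & mag >= m2)
  }
  keep & mag > 0
}

# Count 8-connected components of a logical mask (igraph on the pixel
# adjacency graph; isolated foreground pixels count as components).
count_components8 <- function(mask) {
  n_fg <- sum(mask)
  if (n_fg == 0) return(0L)
  id <- matrix(NA_integer_, nrow(mask), ncol(mask))
  id[mask] <- seq_len(n_fg)
  edges <- list()
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    a <- id
    b <- shift_matrix(id, -off[1], -off[2], fill = NA_integer_)
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) edges[[length(edges) + 1]] <- cbind(a[ok], b[ok])
  }
  if (length(edges) == 0) return(as.integer(n_fg))
  g <- igraph::make_graph(t(do.call(rbind, edges)), n = n_fg,
                          directed = FALSE)
  igraph::components(g)$no
}

canny_edges <- function(patch, low = NULL, high = NULL, sigma = 1) {
  g <- sobel_gradients(gaussian_smooth(patch, sigma))
  mag <- g$mag
  nms <- non_max_suppress(g$gx, g$gy, mag)
  pos <- mag[nms]
  if (length(pos) == 0) {
    return(list(edges = matrix(FALSE, nrow(patch), ncol(patch)), mag = mag))
  }
  if (is.null(high)) high <- stats::quantile(pos, 0.9, names = FALSE)
  if (is.null(low)) low <- 0.4 * high
  if (low < 0 || low >= high) {
    stop("need 0 <= low < high for hysteresis thresholds", call. = FALSE)
  }
  strong <- nms & mag >= high
  cand <- nms & mag >= low
  if (!any(strong)) {
    return(list(edges = matrix(FALSE, nrow(patch), ncol(patch)), mag = mag))
  }
  # hysteresis: keep candidate components containing a strong pixel
  n_fg <- sum(cand)
  id <- matrix(NA_integer_, nrow(patch), ncol(patch))
  id[cand] <- seq_len(n_fg)
  edges <- list()
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    a <- id
    b <- shift_matrix(id, -off[1], -off[2], fill = NA_integer_)
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) edges[[length(edges) + 1]] <- cbind(a[ok], b[ok])
  }
  comp <- if (length(edges) == 0) {
    seq_len(n_fg)
  } else {
    g2 <- igraph::make_graph(t(do.call(rbind, edges)), n = n_fg,
                             directed = FALSE)
    igraph::components(g2)$membership
  }
  strong_comps <- unique(comp[id[strong]])
  keep_px <- comp %in% strong_comps
  out <- matrix(FALSE, nrow(patch), ncol(patch))
  out[cand][keep_px] <- TRUE
  list(edges = out, mag = mag)
}

#' Edge-based summary features of a patch
#'
#' Runs the Canny detector and summarizes the edge map with three fixed
#' scalars: edge density (edge pixels / total pixels), the number of
#' 8-connected components of the edge map, and the mean gradient magnitude
#' over the whole patch. By default the hysteresis thresholds adapt to the
#' patch: high = 90th percentile of the suppressed gradient magnitudes,
#' low = 0.4 * high.
#'
#' @param patch Numeric matrix.
#' @param low,high Optional explicit hysteresis thresholds,
#'   `0 <= low < high`.
#' @param sigma Gaussian pre-smoothing sigma in pixels.
#' @return Named numeric vector: `edge_density`, `edge_component_count`,
#'   `mean_gradient_magnitude`.
#' @export
edge_features <- function(patch, low = NULL, high = NULL, sigma = 1) {
  stop_if_not_matrix(patch, "patch")
  if (!is.null(low) && !is.null(high) && (low < 0 || low >= high)) {
    stop("need 0 <= low < high", call. = FALSE)
  }
  res <- canny_edges(patch, low = low, high = high, sigma = sigma)
  c(edge_density = mean(res$edges),
    edge_component_count = as.numeric(count_components8(res$edges)),
    mean_gradient_magnitude = mean(res$mag))
}
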