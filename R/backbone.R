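# Convolutional feature-extractor backbones.
#
# The deep-feature contract is: a frozen backbone maps a fixed-size patch
# to a fixed-length vector, taken as the spatially pooled activations of
# its final convolutional stage. Any object implementing `deep_forward()`
# and declaring `input_size` / `output_length` satisfies it; the bundled
# `tiny_backbone()` is a small random-frozen CNN so the whole pipeline runs
# without downloaded pretrained weights. Weights for a large pretrained
# residual network can be loaded into the same contract by supplying a
# custom backbone object.

#' A small frozen convolutional backbone
#'
#' Stacked stages of 3x3 same-padding convolution, ReLU and 2x2 max
#' pooling, followed by global average pooling over the final stage's
#' channels. Weights are He-scaled Gaussian draws from `seed` and never
#' trained — the backbone is a deterministic feature extractor.
#'
#' @param seed Integer seed for the frozen weights.
#' @param filters Integer vector: output channels per stage.
#' @param filter_size Odd kernel size (default 3).
#' @param input_size Expected patch size (rows, cols).
#' @return A `conv_backbone`.
#' @export
tiny_backbone <- function(seed = 0, filters = c(4, 8), filter_size = 3,
                          input_size = c(64, 64)) {
  stopifnot(filter_size %% 2 == 1, length(filters) >= 1)
  stages <- withr::with_seed(as.integer(seed), {
    in_ch <- 1L
    lapply(filters, function(f) {
      fan_in <- filter_size * filter_size * in_ch
      w <- array(stats::rnorm(filter_size^2 * in_ch * f,
                              sd = sqrt(2 / fan_in)),
                 dim = c(filter_size, filter_size, in_ch, f))
      b <- rep(0, f)
      in_ch <<- f
      list(weights = w, bias = b)
    })
  })
  structure(list(stages = stages, filter_size = as.integer(filter_size),
                 input_size = as.integer(input_size),
                 output_length = as.integer(filters[length(filters)])),
            class = "conv_backbone")
}

# Same-padding multi-channel 2-D convolution: the k*k*C shifted copies of
# the input are assembled once into a design matrix, then one matrix
# product applies every filter (im2col + GEMM).
# x: H x W x C array; w: k x k x C x F; returns H x W x F.
conv2d_same <- function(x, w, bias) {
  h <- dim(x)[1]; wd <- dim(x)[2]; cin <- dim(x)[3]
  k <- dim(w)[1]; f <- dim(w)[4]
  r <- (k - 1L) %/% 2L
  cols <- vector("list", k * k * cin)
  m <- 1L
  for (cc in seq_len(cin)) {
    xc <- x[, , cc]
    for (dx in -r:r) for (dy in -r:r) {
      cols[[m]] <- as.vector(shift_matrix(xc, -dy, -dx, fill = 0))
      m <- m + 1L
    }
  }
  design <- do.call(cbind, cols)
  # weight layout must match the column order above: (dy, dx, channel)
  wmat <- matrix(aperm(w, c(1, 2, 3, 4)), k * k * cin, f)
  out <- design %*% wmat
  out <- sweep(out, 2, bias, "+")
  array(out, dim = c(h, wd, f))
}

max_pool2 <- function(x) {
  h <- (dim(x)[1] %/% 2L) * 2L
  w <- (dim(x)[2] %/% 2L) * 2L
  f <- dim(x)[3]
  out <- array(0, dim = c(h %/% 2L, w %/% 2L, f))
  for (ff in seq_len(f)) {
    m <- x[seq_len(h), seq_len(w), ff]
    out[, , ff] <- pmax(m[seq(1, h, 2), seq(1, w, 2)],
                        m[seq(2, h, 2), seq(1, w, 2)],
                        m[seq(1, h, 2), seq(2, w, 2)],
                        m[seq(2, h, 2), seq(2, w, 2)])
  }
  out
}

#' Forward pass of a convolutional backbone
#' @param backbone A `conv_backbone`.
#' @param patch Numeric matrix matching the backbone's `input_size`.
#' @return Numeric vector of length `backbone$output_length` (globally
#'   averaged final-stage activations).
#' @export
deep_forward <- function(backbone, patch) {
  stopifnot(inherits(backbone, "conv_backbone"))
  if (!all(dim(patch) == backbone$input_size)) {
    stop("patch shape (", paste(dim(patch), collapse = "x"),
         ") does not match backbone input (",
         paste(backbone$input_size, collapse = "x"), ")", call. = FALSE)
  }
  x <- array(patch, dim = c(dim(patch), 1L))
  for (st in backbone$stages) {
    x <- conv2d_same(x, st$weights, st$bias)
    x[x < 0] <- 0
    x <- max_pool2(x)
  }
  apply(x, 3, mean)
}

#' Extract deep features for a batch of patches
#'
#' One fixed-length row per patch; deterministic for a frozen backbone.
#' Patches must already match the backbone input size (resize or pad them
#' first — see [pad_patch()] / [resize_image()]).
#'
#' @param patches List of patch matrices.
#' @param backbone A `conv_backbone` (or compatible object).
#' @return Matrix with `length(patches)` rows, columns `deep_001`..
#' @export
extract_deep_features <- function(patches, backbone) {
  rows <- lapply(patches, function(p) deep_forward(backbone, p))
  out <- do.call(rbind, rows)
  colnames(out) <- sprintf("deep_%03d", seq_len(ncol(out)))
  out
}
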