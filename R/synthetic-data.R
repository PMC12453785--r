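# Synthetic phantom mammograms: textured backgrounds with bright elliptical
# lesions and ground-truth masks, so the whole pipeline is testable without
# any external imaging data.

#' Specify a synthetic lesion
#'
#' Describes a bright elliptical lesion to be painted into a phantom. A
#' smooth boundary (`boundary_roughness = 0`) marks the benign class; a
#' radially perturbed, irregular boundary (`boundary_roughness > 0`) marks
#' the malignant class, mimicking the irregular margins of malignant masses.
#'
#' @param center Numeric length-2, lesion center as (row, col) in pixels.
#' @param axes Numeric length-2, (semi-major, semi-minor) axis lengths in
#'   pixels; both must be positive.
#' @param rotation Rotation of the major axis in radians.
#' @param boundary_roughness Amplitude of the radial sinusoidal boundary
#'   perturbation; 0 gives a smooth ellipse.
#' @param intensity_gain Multiplicative brightening applied inside the
#'   lesion; must be > 0.
#' @return A `lesion_spec` object.
#' @export
lesion_spec <- function(center, axes, rotation = 0, boundary_roughness = 0,
                        intensity_gain = 1.6) {
  stopifnot(length(center) == 2, length(axes) == 2)
  if (any(axes <= 0)) stop("lesion axes must be positive", call. = FALSE)
  if (boundary_roughness < 0) {
    stop("boundary_roughness must be >= 0", call. = FALSE)
  }
  if (intensity_gain <= 0) stop("intensity_gain must be > 0", call. = FALSE)
  structure(
    list(center = as.numeric(center), axes = as.numeric(axes),
         rotation = as.numeric(rotation),
         boundary_roughness = as.numeric(boundary_roughness),
         intensity_gain = as.numeric(intensity_gain)),
    class = "lesion_spec")
}

# Boundary radius model: r(theta) = r0 * (1 + roughness * sin(5 theta + phi)).
# Membership is evaluated in the ellipse frame: a pixel is inside when its
# normalized elliptical radius rho satisfies rho <= 1 + roughness*sin(5t+phi).
lesion_membership <- function(height, width, lesion, phase) {
  rows <- matrix(seq_len(height), height, width)
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  dy <- rows - lesion$center[1]
  dx <- cols - lesion$center[2]
  ct <- cos(lesion$rotation); st <- sin(lesion$rotation)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  rho <- sqrt((u / lesion$axes[1])^2 + (v / lesion$axes[2])^2)
  theta <- atan2(v, u)
  rho <= 1 + lesion$boundary_roughness * sin(5 * theta + phase)
}

#' Generate one synthetic phantom mammogram
#'
#' The background is band-limited noise: Gaussian white noise low-pass
#' filtered with a sigma = 4 px Gaussian, then affinely mapped to mean 120,
#' sd 25 — a breast-tissue-like mid-gray mottle. If a lesion is supplied its
#' support is brightened by `intensity_gain` and written to the ground-truth
#' mask. Intensities are clipped to [0, 255]. Generation is bit-reproducible
#' for a fixed seed.
#'
#' @param height,width Image dimensions in pixels (both >= 32).
#' @param lesion A [lesion_spec()] or `NULL` for a lesion-free phantom.
#' @param seed Non-negative integer seed.
#' @return A `phantom` object: list with `image` (matrix in [0, 255]),
#'   `mask` (binary matrix), `label` ("benign" or "malignant") and `seed`.
#' @export
generate_phantom <- function(height, width, lesion = NULL, seed = 0) {
  if (height < 32 || width < 32) {
    stop("height and width must be >= 32", call. = FALSE)
  }
  if (seed < 0) stop("seed must be >= 0", call. = FALSE)
  if (!is.null(lesion) && !inherits(lesion, "lesion_spec")) {
    stop("lesion must be a lesion_spec or NULL", call. = FALSE)
  }
  out <- withr::with_seed(as.integer(seed), {
    phase <- stats::runif(1, 0, 2 * pi)
    noise <- matrix(stats::rnorm(height * width), height, width)
    bg <- EBImage::gblur(noise, sigma = 4)
    bg <- (bg - mean(bg)) / stats::sd(as.vector(bg))
    img <- 120 + 25 * bg
    mask <- matrix(0L, height, width)
    if (!is.null(lesion)) {
      inside <- lesion_membership(height, width, lesion, phase)
      if (!any(inside)) {
        stop("lesion lies fully outside the frame: center (",
             lesion$center[1], ", ", lesion$center[2], "), axes (",
             lesion$axes[1], ", ", lesion$axes[2], ")", call. = FALSE)
      }
      img[inside] <- img[inside] * lesion$intensity_gain
      mask[inside] <- 1L
    }
    list(img = img, mask = mask)
  })
  label <- if (!is.null(lesion) && lesion$boundary_roughness > 0) {
    "malignant"
  } else {
    "benign"
  }
  structure(
    list(image = clip(out$img, 0, 255), mask = out$mask, label = label,
         seed = as.integer(seed), lesion = lesion),
    class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %dx%d, label %s, seed %d, %d mask px>\n",
              nrow(x$image), ncol(x$image), x$label, x$seed, sum(x$mask)))
  invisible(x)
}

# Draw a lesion spec for one phantom. Axes scale with the frame so that at
# the 256 px study size the lesion area is around one 64 px patch
# (semi-major 34-44 px, semi-minor 24-34 px), which lets the majority rule
# assign malignant labels to whole patches; malignant boundaries get a
# roughness amplitude of 0.25-0.45.
sample_lesion <- function(height, width, malignant, intensity_gain) {
  ref <- min(height, width)
  a <- stats::runif(1, 34, 44) / 256 * ref
  b <- stats::runif(1, 24, 34) / 256 * ref
  margin <- a + 4
  center <- c(stats::runif(1, margin, height - margin),
              stats::runif(1, margin, width - margin))
  rot <- stats::runif(1, 0, pi)
  rough <- if (malignant) stats::runif(1, 0.25, 0.45) else 0
  lesion_spec(center, c(a, b), rotation = rot, boundary_roughness = rough,
              intensity_gain = intensity_gain)
}

#' Generate a seeded phantom dataset
#'
#' Produces `n_images` phantoms of which exactly
#' `round(n_images * malignant_fraction)` are malignant (rough-boundary
#' lesions); the remainder carry smooth benign lesions. Per-phantom seeds are
#' derived deterministically from the master seed. When `dir` is given,
#' image/mask pairs are written as 8-bit grayscale PNGs and the manifest as a
#' CSV with header `path,mask_path,label,seed`.
#'
#' @param n_images Number of phantoms (> 0).
#' @param malignant_fraction Proportion of malignant phantoms in [0, 1].
#' @param height,width Phantom dimensions in pixels.
#' @param seed Master seed.
#' @param intensity_gain Lesion brightening factor, applied to both classes.
#' @param dir Optional output directory for PNGs and the manifest CSV.
#' @return A `phantom_set`: list with `manifest` (data.frame with columns
#'   path, mask_path, label, seed) and `phantoms` (list of `phantom`).
#' @export
generate_dataset <- function(n_images, malignant_fraction, height = 256,
                             width = 256, seed = 0, intensity_gain = 1.6,
                             dir = NULL) {
  if (n_images <= 0) stop("n_images must be positive", call. = FALSE)
  if (malignant_fraction < 0 || malignant_fraction > 1) {
    stop("malignant_fraction must lie in [0, 1]", call. = FALSE)
  }
  n_mal <- round(n_images * malignant_fraction)
  is_mal <- c(rep(TRUE, n_mal), rep(FALSE, n_images - n_mal))
  gen <- withr::with_seed(as.integer(seed), {
    seeds <- sample.int(.Machine$integer.max - 1L, n_images)
    lesions <- lapply(seq_len(n_images), function(i) {
      sample_lesion(height, width, is_mal[i], intensity_gain)
    })
    list(seeds = seeds, lesions = lesions)
  })
  phantoms <- lapply(seq_len(n_images), function(i) {
    generate_phantom(height, width, gen$lesions[[i]], seed = gen$seeds[i])
  })
  path <- rep(NA_character_, n_images)
  mask_path <- rep(NA_character_, n_images)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_images)) {
      path[i] <- file.path(dir, sprintf("phantom_%04d.png", i))
      mask_path[i] <- file.path(dir, sprintf("phantom_%04d_mask.png", i))
      write_gray_png(phantoms[[i]]$image / 255, path[i])
      write_gray_png(phantoms[[i]]$mask, mask_path[i])
    }
  }
  manifest <- data.frame(
    path = path, mask_path = mask_path,
    label = vapply(phantoms, `[[`, character(1), "label"),
    seed = gen$seeds, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(list(manifest = manifest, phantoms = phantoms),
            class = "phantom_set")
}

# 8-bit grayscale PNG writer/reader; values in [0, 1].
write_gray_png <- function(x, path) {
  png::writePNG(clip(x, 0, 1), path)
}

read_gray_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x
}
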