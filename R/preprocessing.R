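# Preprocessing: resizing, [0,1] normalization, CLAHE contrast enhancement,
# on-the-fly augmentation, feature standardization and dataset splitting.

#' Resize a grayscale image
#'
#' Bilinear resize to `target_size`, with the output clipped to the input's
#' intensity range so interpolation overshoot cannot expand it.
#'
#' @param image Nonempty numeric matrix.
#' @param target_size Integer length-2 (rows, cols), both > 0.
#' @return Matrix of dimension `target_size`.
#' @export
resize_image <- function(image, target_size = c(256, 256)) {
  stop_if_not_matrix(image)
  if (any(target_size <= 0)) stop("target_size must be positive", call. = FALSE)
  if (all(dim(image) == target_size)) return(image)
  out <- EBImage::resize(image, w = target_size[1], h = target_size[2],
                         filter = "bilinear")
  out <- matrix(as.numeric(out), target_size[1], target_size[2])
  clip(out, min(image), max(image))
}

#' Normalize 8-bit intensities to [0, 1]
#'
#' Divides every pixel by 255 exactly. Values outside [0, 255] raise an
#' error, which guards against accidentally normalizing twice.
#' @param image Numeric matrix with values in [0, 255].
#' @return Matrix with values in [0, 1].
#' @export
normalize_image <- function(image) {
  stop_if_not_matrix(image)
  if (min(image) < 0 || max(image) > 255) {
    stop("image values must lie in [0, 255]; was it already normalized?",
         call. = FALSE)
  }
  image / 255
}

#' Map [0, 1] intensities back to the 8-bit range
#' @param image Numeric matrix with values in [0, 1].
#' @return Matrix with values in [0, 255].
#' @export
denormalize_image <- function(image) {
  stop_if_not_matrix(image)
  if (min(image) < 0 || max(image) > 1) {
    stop("image values must lie in [0, 1]", call. = FALSE)
  }
  image * 255
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit, applied to a
#' normalized image. Output stays in [0, 1] by construction and is
#' deterministic for a fixed configuration.
#'
#' @param image Numeric matrix with values in [0, 1].
#' @param clip_limit CLAHE clip limit (default 2).
#' @param tile_grid Integer length-2: contextual tiles along (rows, cols).
#' @return Enhanced matrix, same shape, values in [0, 1].
#' @export
clahe_enhance <- function(image, clip_limit = 2, tile_grid = c(8, 8)) {
  stop_if_not_matrix(image)
  if (min(image) < 0 || max(image) > 1) {
    stop("clahe_enhance expects a normalized image in [0, 1]", call. = FALSE)
  }
  if (nrow(image) < tile_grid[1] || ncol(image) < tile_grid[2]) {
    stop("image smaller than one CLAHE tile", call. = FALSE)
  }
  out <- EBImage::clahe(image, nx = tile_grid[1], ny = tile_grid[2],
                        limit = clip_limit)
  clip(matrix(as.numeric(out), nrow(image), ncol(image)), 0, 1)
}

#' Apply an affine augmentation to a patch
#'
#' Rotation about the patch center, isotropic zoom, optional horizontal
#' flip, and translation by a fraction of the patch size, composed in that
#' order and sampled with bilinear interpolation. Regions mapped from
#' outside the frame are filled with 0 (the dark mammogram surround).
#' Identity parameters reproduce the input exactly.
#'
#' Parameter ranges are capped at the training ranges (|rotation| <= 30
#' degrees, zoom in [0.8, 1.2], |translation| <= 0.1) unless
#' `allow_any_range = TRUE`.
#'
#' @param patch Numeric matrix.
#' @param rotation Rotation in degrees.
#' @param zoom Zoom factor (> 1 magnifies).
#' @param flip Horizontal flip?
#' @param translation Length-2 fractions of (rows, cols) to translate by.
#' @param allow_any_range Disable the range guards.
#' @return Augmented patch, same shape as the input.
#' @export
augment_patch <- function(patch, rotation = 0, zoom = 1, flip = FALSE,
                          translation = c(0, 0), allow_any_range = FALSE) {
  stop_if_not_matrix(patch, "patch")
  if (!allow_any_range) {
    if (abs(rotation) > 30) stop("|rotation| must be <= 30", call. = FALSE)
    if (zoom < 0.8 || zoom > 1.2) {
      stop("zoom must lie in [0.8, 1.2]", call. = FALSE)
    }
    if (any(abs(translation) > 0.1)) {
      stop("|translation| components must be <= 0.1", call. = FALSE)
    }
  }
  h <- nrow(patch); w <- ncol(patch)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  rows <- matrix(seq_len(h), h, w) - cr
  cols <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
  # invert the forward map: translate -> flip -> zoom -> rotate
  rr <- rows - translation[1] * h
  col2 <- cols - translation[2] * w
  if (flip) col2 <- -col2
  rr <- rr / zoom
  col2 <- col2 / zoom
  th <- -rotation * pi / 180
  sr <- rr * cos(th) - col2 * sin(th)
  sc <- rr * sin(th) + col2 * cos(th)
  out <- bilinear_sample(patch, sr + cr, sc + cc, fill = 0)
  matrix(out, h, w)
}

#' Draw random augmentation parameters
#'
#' Rotation ~ U(-30, 30) degrees, zoom ~ U(0.8, 1.2), flip ~ Bernoulli(0.5),
#' translation components ~ U(-0.1, 0.1). Draws come from R's current RNG
#' stream, so wrap in [withr::with_seed()] for reproducibility.
#'
#' @param n Number of parameter sets to draw.
#' @return data.frame with columns rotation, zoom, flip, t_row, t_col.
#' @export
sample_augmentation <- function(n = 1) {
  data.frame(
    rotation = stats::runif(n, -30, 30),
    zoom = stats::runif(n, 0.8, 1.2),
    flip = stats::runif(n) < 0.5,
    t_row = stats::runif(n, -0.1, 0.1),
    t_col = stats::runif(n, -0.1, 0.1))
}

#' Fit a feature standardizer
#'
#' Per-column mean and population (n-denominator) standard deviation,
#' intended to be fitted on the training split only. Zero-variance columns
#' are dropped with a warning.
#'
#' @param features Numeric matrix with >= 2 rows.
#' @return A `standardizer`: list with `mean`, `sd` and `keep` (retained
#'   column indices).
#' @export
fit_standardizer <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 2) {
    stop("need >= 2 rows to fit a standardizer", call. = FALSE)
  }
  mu <- colMeans(features)
  sdev <- sqrt(colMeans(sweep(features, 2, mu)^2))
  keep <- which(sdev > 1e-15)
  if (length(keep) < length(sdev)) {
    warning(sprintf("dropping %d zero-variance feature column(s)",
                    length(sdev) - length(keep)), call. = FALSE)
  }
  structure(list(mean = mu[keep], sd = sdev[keep], keep = keep),
            class = "standardizer")
}

#' Apply a fitted standardizer
#' @param features Numeric matrix with the same columns the standardizer saw.
#' @param stats A `standardizer` from [fit_standardizer()].
#' @return Matrix of standardized retained columns.
#' @export
apply_standardizer <- function(features, stats) {
  stopifnot(inherits(stats, "standardizer"))
  features <- as.matrix(features)[, stats$keep, drop = FALSE]
  sweep(sweep(features, 2, stats$mean), 2, stats$sd, "/")
}

#' Split a manifest into train and test sets
#'
#' Seeded shuffling; `round(train_fraction * n)` rows go to training. With
#' `stratify = TRUE` class proportions are preserved to within one item per
#' class (largest-remainder apportionment over the per-class counts).
#'
#' @param manifest data.frame with a `label` column.
#' @param train_fraction Proportion in (0, 1); default 0.7 (a 70-30 split).
#' @param stratify Preserve class proportions?
#' @param seed Integer seed for the shuffle.
#' @return List with `train` and `test` data.frames (disjoint, covering the
#'   input).
#' @export
split_dataset <- function(manifest, train_fraction = 0.7, stratify = TRUE,
                          seed = 0) {
  if (nrow(manifest) == 0) stop("manifest is empty", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  n <- nrow(manifest)
  n_train <- round(train_fraction * n)
  idx_train <- withr::with_seed(as.integer(seed), {
    if (!stratify) {
      sample.int(n)[seq_len(n_train)]
    } else {
      labs <- as.character(manifest$label)
      classes <- sort(unique(labs))
      if (any(table(labs) < 1)) stop("empty class", call. = FALSE)
      counts <- vapply(classes, function(cl) sum(labs == cl), integer(1))
      exact <- train_fraction * counts
      base <- floor(exact)
      extra <- n_train - sum(base)
      if (extra > 0) {
        ord <- order(exact - base, decreasing = TRUE)
        base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
      } else if (extra < 0) {
        ord <- order(exact - base)
        base[ord[seq_len(-extra)]] <- base[ord[seq_len(-extra)]] - 1
      }
      unlist(lapply(seq_along(classes), function(k) {
        pool <- which(labs == classes[k])
        pool <- pool[sample.int(length(pool))]
        pool[seq_len(base[k])]
      }))
    }
  })
  list(train = manifest[sort(idx_train), , drop = FALSE],
       test = manifest[sort(setdiff(seq_len(n), idx_train)), , drop = FALSE])
}

#' Stratified cross-validation fold assignment
#'
#' Seeded, stratified: within each class, indices are shuffled and dealt to
#' folds round-robin, so fold class proportions match the data to within one
#' item.
#'
#' @param labels Vector of class labels.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in 1..n_folds.
#' @export
make_cv_folds <- function(labels, n_folds = 5, seed = 0) {
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  labs <- as.character(labels)
  if (any(table(labs) < n_folds)) {
    stop("a class has fewer members than folds; use fewer folds",
         call. = FALSE)
  }
  folds <- integer(length(labs))
  withr::with_seed(as.integer(seed), {
    for (cl in sort(unique(labs))) {
      pool <- which(labs == cl)
      pool <- pool[sample.int(length(pool))]
      folds[pool] <- rep_len(seq_len(n_folds), length(pool))
    }
  })
  folds
}
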