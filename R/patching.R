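# Sliding-window patch extraction and majority-region patch labeling.
#
# Coordinates are 0-based, row-major, with half-open [start, stop) pixel
# intervals; a unit test pins the correspondence to 1-based closed index
# notation.

#' Define a patch grid
#'
#' @param patch_height,patch_width Patch dimensions in pixels.
#' @param step_vertical,step_horizontal Window steps; equal to the patch
#'   dimension for non-overlapping tiling, smaller for overlap. Steps larger
#'   than the patch are rejected.
#' @return A `patch_grid_spec`.
#' @export
patch_grid_spec <- function(patch_height, patch_width = patch_height,
                            step_vertical = patch_height,
                            step_horizontal = patch_width) {
  vals <- c(patch_height, patch_width, step_vertical, step_horizontal)
  if (any(vals <= 0) || any(vals != round(vals))) {
    stop("patch dimensions and steps must be positive integers",
         call. = FALSE)
  }
  if (step_vertical > patch_height || step_horizontal > patch_width) {
    stop("steps must not exceed the patch dimensions", call. = FALSE)
  }
  structure(list(patch_height = as.integer(patch_height),
                 patch_width = as.integer(patch_width),
                 step_vertical = as.integer(step_vertical),
                 step_horizontal = as.integer(step_horizontal)),
            class = "patch_grid_spec")
}

is_non_overlapping <- function(spec) {
  spec$step_vertical == spec$patch_height &&
    spec$step_horizontal == spec$patch_width
}

#' Number of complete patches in a non-overlapping tiling
#'
#' `floor(W / P_w) * floor(H / P_h)`: only complete patches count; leftover
#' border pixels are ignored. Overlapping specs are rejected — their count
#' follows from [extract_patches()].
#'
#' @param height,width Image dimensions in pixels.
#' @param spec A non-overlapping [patch_grid_spec()].
#' @return Integer patch count.
#' @export
count_patches <- function(height, width, spec) {
  stopifnot(inherits(spec, "patch_grid_spec"))
  if (!is_non_overlapping(spec)) {
    stop("count_patches applies to non-overlapping grids only; ",
         "use extract_patches for overlapping windows", call. = FALSE)
  }
  (width %/% spec$patch_width) * (height %/% spec$patch_height)
}

# 0-based window start offsets along one dimension.
# Non-overlap (S == P): complete windows only. Overlap (S < P): starts at
# multiples of S up to the smallest k*S whose window reaches the image edge;
# the final window is clamped (possibly smaller than P).
window_starts <- function(len, patch, step) {
  if (step == patch) {
    n <- len %/% patch
    if (n == 0) return(integer(0))
    return(seq(0L, by = patch, length.out = n))
  }
  if (len <= patch) return(0L)
  k <- ceiling((len - patch) / step)
  seq(0L, by = step, length.out = k + 1L)
}

#' Extract sliding-window patches
#'
#' Windows start at multiples of the step sizes. With steps equal to the
#' patch size only complete windows are emitted (exact tiling); with smaller
#' steps the windows overlap and the trailing window in each dimension is
#' clamped to the image bounds, which can make edge patches smaller than the
#' nominal size (they carry `clamped = TRUE`). Patches are emitted in
#' row-major grid order.
#'
#' @param image Numeric matrix.
#' @param spec A [patch_grid_spec()].
#' @return List of `patch_record`s: `i`, `j` (0-based grid index),
#'   `row_start`/`row_stop`/`col_start`/`col_stop` (half-open, 0-based),
#'   `pixels`, `clamped`.
#' @export
extract_patches <- function(image, spec) {
  stop_if_not_matrix(image)
  stopifnot(inherits(spec, "patch_grid_spec"))
  h <- nrow(image); w <- ncol(image)
  rs <- window_starts(h, spec$patch_height, spec$step_vertical)
  cs <- window_starts(w, spec$patch_width, spec$step_horizontal)
  if (length(rs) == 0 || length(cs) == 0) {
    message("patch grid larger than image; no complete patches")
    return(list())
  }
  out <- vector("list", length(rs) * length(cs))
  k <- 1
  for (ii in seq_along(rs)) {
    r0 <- rs[ii]
    r1 <- min(h, r0 + spec$patch_height)
    for (jj in seq_along(cs)) {
      c0 <- cs[jj]
      c1 <- min(w, c0 + spec$patch_width)
      out[[k]] <- structure(
        list(i = ii - 1L, j = jj - 1L,
             row_start = r0, row_stop = r1,
             col_start = c0, col_stop = c1,
             pixels = image[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE],
             clamped = (r1 - r0 < spec$patch_height) ||
               (c1 - c0 < spec$patch_width)),
        class = "patch_record")
      k <- k + 1
    }
  }
  out
}

#' Zero-pad a clamped patch to the nominal grid size
#' @param pixels Patch pixel matrix.
#' @param spec The governing [patch_grid_spec()].
#' @return Matrix of exactly (patch_height, patch_width).
#' @export
pad_patch <- function(pixels, spec) {
  stopifnot(inherits(spec, "patch_grid_spec"))
  out <- matrix(0, spec$patch_height, spec$patch_width)
  out[seq_len(nrow(pixels)), seq_len(ncol(pixels))] <- pixels
  out
}

#' Label a patch by majority region
#'
#' The malignant area fraction is the share of mask-positive pixels in the
#' window; the patch is malignant when that fraction reaches `threshold`.
#' Ties at exactly the threshold are labeled malignant, favoring
#' sensitivity.
#'
#' @param mask_window Binary matrix covering the patch window.
#' @param threshold Majority threshold in (0, 1]; default 0.5.
#' @return List with `label` and `malignant_area_fraction`.
#' @export
label_patch <- function(mask_window, threshold = 0.5) {
  if (length(mask_window) == 0) stop("empty mask window", call. = FALSE)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]", call. = FALSE)
  }
  fraction <- sum(mask_window > 0) / length(mask_window)
  list(label = if (fraction >= threshold) "malignant" else "benign",
       malignant_area_fraction = fraction)
}

#' Build a patch-level dataset from phantoms or a manifest
#'
#' Every image is tiled by `spec`; each patch is labeled by the majority
#' rule against the image's malignant region. A mask marks the lesion for
#' both classes, so the malignant region is the mask only when the image
#' itself is malignant — lesion patches of benign images stay benign.
#'
#' @param data A `phantom_set` from [generate_dataset()], or a data.frame
#'   manifest with `path`, `mask_path`, `label` columns (PNG files).
#' @param spec A [patch_grid_spec()].
#' @param threshold Majority threshold passed to [label_patch()].
#' @param images Optional list of preprocessed images (same order as the
#'   manifest) to tile instead of the raw stored pixels; masks are still
#'   taken from `data`.
#' @return A `patch_set`: list with `records` (data.frame: source_id, label
#'   of source, i, j, bounds, patch label, malignant_fraction, clamped) and
#'   `pixels` (list of patch matrices), plus the `spec`.
#' @export
patch_dataset <- function(data, spec, threshold = 0.5, images = NULL) {
  stopifnot(inherits(spec, "patch_grid_spec"))
  if (inherits(data, "phantom_set")) {
    n <- length(data$phantoms)
    get_img <- function(i) data$phantoms[[i]]$image
    get_mask <- function(i) data$phantoms[[i]]$mask
    labs <- vapply(data$phantoms, `[[`, character(1), "label")
  } else {
    n <- nrow(data)
    labs <- as.character(data$label)
    get_img <- function(i) read_gray_png(data$path[i]) * 255
    get_mask <- function(i) {
      if (is.na(data$mask_path[i]) || !file.exists(data$mask_path[i])) {
        stop("missing mask file for manifest row ", i, call. = FALSE)
      }
      (read_gray_png(data$mask_path[i]) > 0.5) * 1L
    }
  }
  rec_list <- vector("list", n)
  pix_list <- vector("list", n)
  for (idx in seq_len(n)) {
    img <- if (!is.null(images)) images[[idx]] else get_img(idx)
    mask <- get_mask(idx)
    mal_mask <- mask * (labs[idx] == "malignant")
    patches <- extract_patches(img, spec)
    mpatches <- extract_patches(mal_mask, spec)
    m <- length(patches)
    if (m == 0) next
    lab <- character(m); frac <- numeric(m)
    for (k in seq_len(m)) {
      lp <- label_patch(mpatches[[k]]$pixels, threshold)
      lab[k] <- lp$label
      frac[k] <- lp$malignant_area_fraction
    }
    rec_list[[idx]] <- data.frame(
      source_id = idx,
      source_label = labs[idx],
      i = vapply(patches, `[[`, integer(1), "i"),
      j = vapply(patches, `[[`, integer(1), "j"),
      row_start = vapply(patches, `[[`, numeric(1), "row_start"),
      row_stop = vapply(patches, `[[`, numeric(1), "row_stop"),
      col_start = vapply(patches, `[[`, numeric(1), "col_start"),
      col_stop = vapply(patches, `[[`, numeric(1), "col_stop"),
      label = lab,
      malignant_fraction = frac,
      clamped = vapply(patches, `[[`, logical(1), "clamped"),
      stringsAsFactors = FALSE)
    pix_list[[idx]] <- lapply(patches, `[[`, "pixels")
  }
  structure(list(records = do.call(rbind, rec_list),
                 pixels = do.call(c, pix_list),
                 spec = spec),
            class = "patch_set")
}

#' Write a patch set to disk
#'
#' Patch pixels go to PNG files; the manifest CSV has columns
#' `source_id,i,j,row_start,row_stop,col_start,col_stop,label,
#' malignant_fraction,patch_path`.
#'
#' @param patch_set A `patch_set` from [patch_dataset()]. Pixel values are
#'   rescaled to [0, 1] by the source range for writing.
#' @param dir Output directory.
#' @return The manifest data.frame, invisibly.
#' @export
write_patch_set <- function(patch_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- patch_set$records
  paths <- character(nrow(rec))
  hi <- max(1, max(vapply(patch_set$pixels, max, numeric(1))))
  for (k in seq_len(nrow(rec))) {
    paths[k] <- file.path(dir, sprintf("patch_%05d.png", k))
    write_gray_png(patch_set$pixels[[k]] / hi, paths[k])
  }
  manifest <- cbind(rec[, c("source_id", "i", "j", "row_start", "row_stop",
                            "col_start", "col_stop", "label",
                            "malignant_fraction")],
                    patch_path = paths)
  utils::write.csv(manifest, file.path(dir, "patches.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
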