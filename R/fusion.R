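# Handcrafted descriptor assembly and deep/handcrafted feature fusion.

#' Handcrafted feature vector of a patch
#'
#' Concatenates the 256-bin LBP histogram, the seven log-scaled Hu moment
#' invariants and the three Canny edge statistics — 266 values describing
#' texture, shape and boundary structure.
#'
#' @param patch Numeric matrix (at least 3x3).
#' @param lbp_convention Passed to [lbp_histogram()].
#' @param canny_low,canny_high Optional explicit hysteresis thresholds.
#' @return Named numeric vector of length 266.
#' @export
handcrafted_features <- function(patch,
                                 lbp_convention = "center_minus_neighbor",
                                 canny_low = NULL, canny_high = NULL) {
  hu <- if (sum(patch) > 0) {
    hu_invariants(patch)
  } else {
    stats::setNames(rep(0, 7), paste0("hu_", 1:7))
  }
  c(lbp_histogram(patch, convention = lbp_convention),
    hu,
    edge_features(patch, low = canny_low, high = canny_high))
}

#' Fuse deep and handcrafted features
#'
#' Plain concatenation, deep first then handcrafted; no rescaling happens
#' here (standardization is fitted on the training split separately). An
#' empty handcrafted vector is allowed for deep-only ablations.
#'
#' @param deep Non-empty numeric vector.
#' @param handcrafted Numeric vector (possibly empty).
#' @return Fused numeric vector of length `length(deep) +
#'   length(handcrafted)`.
#' @export
fuse_features <- function(deep, handcrafted = numeric(0)) {
  if (length(deep) == 0) stop("deep feature vector is empty", call. = FALSE)
  c(deep, handcrafted)
}

#' Feature matrix for a patch set
#'
#' Pads clamped patches to the grid size, extracts deep and/or handcrafted
#' features per patch and fuses them row-wise.
#'
#' @param patch_set A `patch_set` from [patch_dataset()].
#' @param backbone Backbone for deep features, or `NULL` to skip them.
#' @param handcrafted Include handcrafted features?
#' @param lbp_convention Passed through to [handcrafted_features()].
#' @return List with `features` (matrix, one row per patch), `labels`
#'   (character vector) and `records`.
#' @export
patch_features <- function(patch_set, backbone = NULL, handcrafted = TRUE,
                           lbp_convention = "center_minus_neighbor") {
  stopifnot(inherits(patch_set, "patch_set"))
  if (is.null(backbone) && !handcrafted) {
    stop("at least one feature family must be enabled", call. = FALSE)
  }
  spec <- patch_set$spec
  pixels <- lapply(patch_set$pixels, function(p) {
    if (nrow(p) == spec$patch_height && ncol(p) == spec$patch_width) p
    else pad_patch(p, spec)
  })
  deep <- NULL
  if (!is.null(backbone)) {
    if (!all(c(spec$patch_height, spec$patch_width) ==
             backbone$input_size)) {
      pixels_deep <- lapply(pixels, resize_image,
                            target_size = backbone$input_size)
    } else {
      pixels_deep <- pixels
    }
    deep <- extract_deep_features(pixels_deep, backbone)
  }
  hand <- NULL
  if (handcrafted) {
    hand <- do.call(rbind, lapply(pixels, handcrafted_features,
                                  lbp_convention = lbp_convention))
  }
  feats <- if (is.null(deep)) hand else if (is.null(hand)) deep else
    cbind(deep, hand)
  list(features = feats,
       labels = patch_set$records$label,
       records = patch_set$records)
}
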