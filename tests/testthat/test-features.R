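test_that("3x3 LBP codes match hand-worked values", {
  expect_equal(lbp_code(matrix(5, 3, 3)), 255L)  # every s(0) = 1
  low_center <- matrix(9, 3, 3); low_center[2, 2] <- 1
  expect_equal(lbp_code(low_center), 0L)
  # neighbors alternate 3, 7 clockwise from the top-left: bits set at even n
  alt <- matrix(c(3, 7, 3, 7, 5, 7, 3, 7, 3), 3, 3, byrow = TRUE)
  expect_equal(lbp_code(alt), 85L)
  # canonical convention flips every strict comparison: bits at odd n
  expect_equal(lbp_code(alt, convention = "neighbor_minus_center"), 170L)
  expect_error(lbp_code(matrix(1, 2, 3)), "3x3")
})

test_that("LBP histograms are normalized and difference-based", {
  patch <- fixture_image(seed = 8)[1:32, 1:32]
  h <- lbp_histogram(patch)
  expect_length(h, 256)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(unname(lbp_histogram(matrix(3, 10, 10))["lbp_255"]), 1)
  # shifting all intensities leaves every difference unchanged
  expect_identical(h, lbp_histogram(patch + 0.1))
  expect_error(lbp_histogram(matrix(1, 2, 2)), "3x3")
})

test_that("LBP histograms are invariant under positive affine maps", {
  set.seed(10)
  for (k in 1:50) {
    ph <- generate_phantom(64, 64, lesion = NULL, seed = k)
    patch <- ph$image[1:32, 1:32]
    a <- runif(1, 0.2, 3); b <- runif(1, -20, 20)
    expect_identical(lbp_histogram(patch),
                     lbp_histogram(a * patch + b))
  }
})

test_that("central moments match direct evaluation", {
  img <- matrix(c(1, 3, 2, 4), 2, 2)  # I(x=1,y=1)=1, I(x=2,y=2)=4
  expect_equal(central_moment(img, 0, 0), sum(img))
  expect_equal(central_moment(img, 1, 0), 0)
  expect_equal(central_moment(img, 0, 1), 0)
  # independent double-sum oracle for mu_{2,0} (x = column index)
  total <- sum(img)
  xbar <- sum(col(img) * img) / total
  mu20 <- 0
  for (r in 1:2) for (c in 1:2) mu20 <- mu20 + (c - xbar)^2 * img[r, c]
  expect_equal(central_moment(img, 2, 0), mu20)
  expect_error(central_moment(matrix(0, 3, 3), 2, 0), "mass")
})

test_that("Hu invariants survive translation, rotation and scaling", {
  set.seed(3)
  for (k in 1:20) {
    ph <- generate_phantom(
      96, 96,
      lesion_spec(c(48, 48), c(20, 12), rotation = runif(1, 0, pi),
                  boundary_roughness = runif(1, 0.1, 0.4)),
      seed = k)
    img <- ph$image * ph$mask  # asymmetric bright blob on black
    hu <- hu_invariants(img)
    # translation by (5, 9) with zero padding
    big <- matrix(0, 120, 120)
    big[6:101, 10:105] <- img
    expect_equal(hu_invariants(big), hu, tolerance = 1e-9)
    # 90 degree rotation is an exact raster permutation
    rot <- t(img[nrow(img):1, ])
    expect_lt(max(abs(hu_invariants(rot) - hu)), 1e-6)
    # 2x nearest-neighbor upscale: discretization-limited invariance
    scl <- img[rep(seq_len(nrow(img)), each = 2),
               rep(seq_len(ncol(img)), each = 2)]
    expect_lt(max(abs(hu_invariants(scl) - hu)), 5e-2)
  }
})

test_that("mirroring flips the seventh invariant only", {
  img <- fixture_image(seed = 9) * (fixture_image(seed = 9) > 0.6)
  hu <- hu_invariants(img, log_scale = FALSE)
  hu_m <- hu_invariants(img[, ncol(img):1], log_scale = FALSE)
  expect_equal(hu_m[1:6], hu[1:6], tolerance = 1e-9)
  expect_equal(unname(hu_m[7]), -unname(hu[7]), tolerance = 1e-9)
})

test_that("edge features behave on canonical inputs", {
  expect_equal(unname(edge_features(matrix(0.7, 32, 32))), c(0, 0, 0))
  step <- cbind(matrix(0, 32, 16), matrix(1, 32, 16))
  ef <- edge_features(step)
  expect_gt(ef[["edge_density"]], 0)
  expect_equal(ef[["edge_component_count"]], 1)
  expect_gt(ef[["mean_gradient_magnitude"]], 0)
  expect_error(edge_features(step, low = 0.5, high = 0.1), "low < high")
})

test_that("raising hysteresis thresholds never adds edge pixels", {
  patch <- fixture_image(seed = 11)[1:64, 1:64]
  base <- edge_features(patch, low = 0.02, high = 0.1)
  for (mult in c(1.5, 2.5, 4)) {
    harder <- edge_features(patch, low = 0.02 * mult, high = 0.1 * mult)
    expect_lte(harder[["edge_density"]], base[["edge_density"]])
  }
})

test_that("rough lesions produce busier edge maps than smooth ones", {
  smooth <- generate_phantom(128, 128, lesion_spec(c(64, 64), c(30, 22)),
                             seed = 31)
  rough <- generate_phantom(
    128, 128, lesion_spec(c(64, 64), c(30, 22), boundary_roughness = 0.4),
    seed = 31)
  es <- edge_features(normalize_image(smooth$image)[33:96, 33:96])
  er <- edge_features(normalize_image(rough$image)[33:96, 33:96])
  expect_gt(er[["edge_density"]], es[["edge_density"]])
})

test_that("deep features obey the backbone contract", {
  bb <- tiny_backbone(seed = 0, input_size = c(16, 16))
  p1 <- fixture_image(seed = 12)[1:16, 1:16]
  p2 <- fixture_image(seed = 12)[17:32, 17:32]
  feats <- extract_deep_features(list(p1, p1, p2), bb)
  expect_equal(dim(feats), c(3, bb$output_length))
  expect_identical(feats[1, ], feats[2, ])
  expect_false(identical(feats[1, ], feats[3, ]))
  expect_error(deep_forward(bb, matrix(0, 8, 8)), "does not match")
})

test_that("backbone forward equals a straight-line manual pass", {
  bb <- tiny_backbone(seed = 0, filters = c(2, 3), input_size = c(12, 12))
  patch <- withr::with_seed(4, matrix(runif(144), 12, 12))
  expect_equal(deep_forward(bb, patch), manual_backbone_forward(bb, patch),
               tolerance = 1e-12)
})

test_that("fusion concatenates deep-then-handcrafted exactly", {
  deep <- withr::with_seed(1, rnorm(512))
  hand <- withr::with_seed(2, rnorm(266))
  fused <- fuse_features(deep, hand)
  expect_length(fused, 778)
  expect_identical(fused[1:512], deep)
  expect_identical(fused[513:778], hand)
  expect_identical(fuse_features(deep, numeric(0)), deep)
  expect_error(fuse_features(numeric(0), hand), "empty")
  # injectivity on distinct pairs
  expect_false(identical(fuse_features(deep, hand),
                         fuse_features(deep, hand + 1e-12)))
})

test_that("handcrafted vectors have the documented layout", {
  hf <- handcrafted_features(fixture_image(seed = 13)[1:64, 1:64])
  expect_length(hf, 266)
  expect_equal(sum(hf[1:256]), 1, tolerance = 1e-9)
  expect_named(hf[257:263], paste0("hu_", 1:7))
  expect_named(hf[264:266], c("edge_density", "edge_component_count",
                              "mean_gradient_magnitude"))
})

test_that("feature extraction for a seeded dataset is reproducible", {
  ds <- fixture_phantoms(n = 2, seed = 77)
  pset <- patch_dataset(ds, patch_grid_spec(64))
  bb <- tiny_backbone(seed = 1)
  f1 <- patch_features(pset, backbone = bb)
  f2 <- patch_features(pset, backbone = bb)
  expect_identical(f1$features, f2$features)
  expect_equal(nrow(f1$features), 8)
  expect_equal(ncol(f1$features), bb$output_length + 266)
})
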