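# Shared fixtures, built in code at test time.

# Small phantom set with lesions sized to the 64 px patch grid.
fixture_phantoms <- function(n = 6, seed = 42, height = 128, width = 128) {
  generate_dataset(n, 0.5, height = height, width = width, seed = seed)
}

# A single normalized phantom image with a rough lesion.
fixture_image <- function(seed = 7, roughness = 0.35) {
  ph <- generate_phantom(
    128, 128,
    lesion_spec(c(64, 64), c(30, 22), rotation = 0.4,
                boundary_roughness = roughness),
    seed = seed)
  normalize_image(ph$image)
}

# Independent brute-force window enumerator applying the min/max clamping
# rule pixel by pixel (the oracle stays a plain double loop).
brute_force_windows <- function(image, ph, pw, sh, sw) {
  h <- nrow(image); w <- ncol(image)
  # per-dimension start rule: steps equal to the patch size emit complete
  # windows only; smaller steps advance until the window reaches the edge
  # (the trailing window is clamped by min/max)
  starts_1d <- function(len, p, s) {
    if (s == p) {
      st <- c()
      i <- 0
      while ((i + 1) * p <= len) {
        st <- c(st, i * p)
        i <- i + 1
      }
      return(st)
    }
    st <- 0
    while (tail(st, 1) + p < len) st <- c(st, tail(st, 1) + s)
    st
  }
  row_starts <- starts_1d(h, ph, sh)
  col_starts <- starts_1d(w, pw, sw)
  out <- list()
  for (r0 in row_starts) {
    r1 <- min(h, r0 + ph)
    for (c0 in col_starts) {
      c1 <- min(w, c0 + pw)
      out[[length(out) + 1]] <- list(
        r0 = max(0, r0), r1 = r1, c0 = max(0, c0), c1 = c1,
        px = image[(max(0, r0) + 1):r1, (max(0, c0) + 1):c1,
                   drop = FALSE])
    }
  }
  out
}

expect_patches_match_oracle <- function(image, ph, pw, sh, sw) {
  spec <- patch_grid_spec(ph, pw, sh, sw)
  got <- suppressMessages(extract_patches(image, spec))
  want <- brute_force_windows(image, ph, pw, sh, sw)
  expect_length(got, length(want))
  for (k in seq_along(got)) {
    expect_equal(
      as.numeric(c(got[[k]]$row_start, got[[k]]$row_stop,
                   got[[k]]$col_start, got[[k]]$col_stop)),
      as.numeric(c(want[[k]]$r0, want[[k]]$r1, want[[k]]$c0,
                   want[[k]]$c1)))
    expect_identical(got[[k]]$pixels, want[[k]]$px)
  }
}

# Straight-line manual forward pass for the tiny backbone (independent of
# the package's conv implementation): plain quadruple loops.
manual_backbone_forward <- function(backbone, patch) {
  x <- array(patch, dim = c(dim(patch), 1))
  for (st in backbone$stages) {
    w <- st$weights
    k <- dim(w)[1]; r <- (k - 1) / 2
    h <- dim(x)[1]; wd <- dim(x)[2]
    cin <- dim(w)[3]; f <- dim(w)[4]
    out <- array(0, dim = c(h, wd, f))
    for (ff in seq_len(f)) {
      for (yy in seq_len(h)) for (xx in seq_len(wd)) {
        acc <- st$bias[ff]
        for (cc in seq_len(cin)) {
          for (dy in -r:r) for (dx in -r:r) {
            sy <- yy + dy; sx <- xx + dx
            if (sy >= 1 && sy <= h && sx >= 1 && sx <= wd) {
              acc <- acc + w[dy + r + 1, dx + r + 1, cc, ff] * x[sy, sx, cc]
            }
          }
        }
        out[yy, xx, ff] <- max(0, acc)  # conv + ReLU fused
      }
    }
    # 2x2 max pool
    h2 <- floor(h / 2); w2 <- floor(wd / 2)
    pooled <- array(0, dim = c(h2, w2, f))
    for (ff in seq_len(f)) for (yy in seq_len(h2)) for (xx in seq_len(w2)) {
      pooled[yy, xx, ff] <- max(out[(2 * yy - 1):(2 * yy),
                                    (2 * xx - 1):(2 * xx), ff])
    }
    x <- pooled
  }
  apply(x, 3, mean)
}

# Separable two-cloud feature fixture (n points, 4 sigma separation).
fixture_clouds <- function(n = 400, d = 5, sep = 4, seed = 0) {
  withr::with_seed(seed, {
    half <- n / 2
    x <- rbind(matrix(rnorm(half * d), half),
               matrix(rnorm(half * d, mean = sep / sqrt(d)), half))
    list(x = x, y = rep(c(0, 1), each = half))
  })
}
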