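# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Derive k reproducible child seeds from a master seed. Values stay below
# .Machine$integer.max so they are always valid set.seed() arguments.
derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, k))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_binary_image <- function(x) is.matrix(x) && all(x %in% c(0, 1))

stop_if_not_matrix <- function(x, what = "image") {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0) {
    stop(what, " must be a nonempty numeric matrix", call. = FALSE)
  }
}

# Shift a matrix by (dr, dc), filling exposed entries with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Bilinear sample of matrix `m` at fractional (row, col) coordinates.
# Out-of-frame samples return `fill`.
bilinear_sample <- function(m, r, c, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  val <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out <- rep(fill, length(ri))
    idx <- which(ok)
    out[idx] <- m[cbind(ri[idx], ci[idx])]
    out
  }
  v00 <- val(r0, c0); v01 <- val(r0, c0 + 1)
  v10 <- val(r0 + 1, c0); v11 <- val(r0 + 1, c0 + 1)
  v00 * (1 - fr) * (1 - fc) + v01 * (1 - fr) * fc +
    v10 * fr * (1 - fc) + v11 * fr * fc
}

# Recursively sort list names so serialization is order-independent.
canonicalize <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, canonicalize)
  } else if (is.list(x)) {
    lapply(x, canonicalize)
  } else {
    x
  }
}

# MD5 fingerprint of a canonicalized config list (stable cache key across
# machines for identical configs).
config_hash <- function(config) {
  canon <- jsonlite::toJSON(canonicalize(config), auto_unbox = TRUE,
                            digits = NA, null = "null")
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(canon), tf)
  unname(tools::md5sum(tf))
}
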