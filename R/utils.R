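# Internal helpers: seeded evaluation that does not disturb the caller's RNG
# stream, seed derivation for sub-streams, and bilinear upsampling.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Fold integer components into one 31-bit seed (LCG-style mixing; all
# intermediates stay below 2^53 so double arithmetic is exact).
derive_seed <- function(seed, ...) {
  s <- as.double(seed %% 2147483647)
  for (x in c(...)) s <- (s * 69069 + as.double(x %% 2147483647) + 1) %% 2147483647
  as.integer(s)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

# Bilinear upsampling of a small matrix to `out_h` x `out_w`, mapping
# pixel centers (half-pixel alignment, edge-clamped).
bilinear_upsample <- function(m, out_h, out_w) {
  h <- nrow(m); w <- ncol(m)
  if (h == out_h && w == out_w) return(m)
  sy <- h / out_h; sx <- w / out_w
  yc <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), h - 1)
  xc <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), w - 1)
  y0 <- pmin(floor(yc), h - 1); y1 <- pmin(y0 + 1, h - 1); fy <- yc - y0
  x0 <- pmin(floor(xc), w - 1); x1 <- pmin(x0 + 1, w - 1); fx <- xc - x0
  a <- m[y0 + 1, x0 + 1, drop = FALSE]; b <- m[y0 + 1, x1 + 1, drop = FALSE]
  c_ <- m[y1 + 1, x0 + 1, drop = FALSE]; d <- m[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, out_h, out_w); wx <- matrix(fx, out_h, out_w, byrow = TRUE)
  a * (1 - wy) * (1 - wx) + b * (1 - wy) * wx + c_ * wy * (1 - wx) + d * wy * wx
}

# Coerce an image to H x W x C array form (C = 1 for a matrix).
as_image_array <- function(image) {
  if (is.matrix(image)) array(image, c(dim(image), 1L))
  else if (is.array(image) && length(dim(image)) == 3L) image
  else stopf("image must be an H x W matrix or H x W x C array")
}

restore_image_form <- function(arr, original) {
  if (is.matrix(original)) arr[, , 1L] else arr
}
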