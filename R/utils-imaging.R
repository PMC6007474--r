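# Internal imaging primitives shared across modules.
#
# EBImage supplies flat-structuring-element morphology, watershed, distance
# transforms and CLAHE; the pieces it does not ship -- grayscale morphological
# reconstruction, a local Shannon-entropy filter, the homomorphic filter and
# numeric HSV conversion -- are implemented here.

as_eb <- function(m) EBImage::Image(m)

# run expr under a fixed RNG state when seed is given, untouched otherwise
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

# min-max normalization to [0, 1]; a flat image maps to all zeros
minmax_norm <- function(m) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(m)))
  (m - rng[1]) / (rng[2] - rng[1])
}

# flat disc structuring element, odd side length
disc_brush <- function(radius_px) {
  radius_px <- max(1L, as.integer(round(radius_px)))
  EBImage::makeBrush(2L * radius_px + 1L, shape = "disc")
}

# normalized disc kernel for filter2 (local window averaging)
disc_kernel <- function(radius_px) {
  b <- disc_brush(radius_px)
  b / sum(b)
}

# Sobel gradient magnitude; replicate boundary
sobel_magnitude <- function(m) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- EBImage::filter2(as_eb(m), kx, boundary = "replicate")
  gy <- EBImage::filter2(as_eb(m), t(kx), boundary = "replicate")
  sqrt(as.matrix(gx)^2 + as.matrix(gy)^2)
}

# Grayscale morphological reconstruction by dilation: grow 'marker' under
# 'mask' with a 3x3 flat element until stable.
reconstruct_gray <- function(marker, mask, tol = 1e-7, max_iter = 2048L) {
  stopifnot(all(dim(marker) == dim(mask)))
  m <- pmin(marker, mask)
  b3 <- EBImage::makeBrush(3L, shape = "box")
  for (i in seq_len(max_iter)) {
    m2 <- pmin(as.matrix(EBImage::dilate(as_eb(m), b3)), mask)
    if (max(abs(m2 - m)) <= tol) return(m2)
    m <- m2
  }
  m
}

# opening by reconstruction: erosion as marker, reconstructed under the image.
# EBImage grayscale morphology clamps to [0, 1], so rescale around it.
open_reconstruct <- function(m, radius_px) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(m)
  u <- (m - rng[1]) / (rng[2] - rng[1])
  er <- as.matrix(EBImage::erode(as_eb(u), disc_brush(radius_px)))
  reconstruct_gray(er, u) * (rng[2] - rng[1]) + rng[1]
}

# closing by reconstruction via complementation
close_reconstruct <- function(m, radius_px) {
  top <- max(m)
  top - open_reconstruct(top - m, radius_px)
}

# Local Shannon entropy (bits) of the intensity distribution inside a disc
# window, computed from per-bin occupancy maps convolved with the window.
local_entropy <- function(m, radius_px, bins = 32L) {
  rng <- range(m)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(m)))
  q <- findInterval(m, seq(rng[1], rng[2], length.out = bins + 1L),
                    rightmost.closed = TRUE, all.inside = TRUE)
  k <- disc_kernel(radius_px)
  ent <- array(0, dim(m))
  for (b in seq_len(bins)) {
    ind <- array(0, dim(m)); ind[q == b] <- 1
    if (sum(ind) == 0) next
    p <- as.matrix(EBImage::filter2(as_eb(ind), k, boundary = "replicate"))
    p[p < 1e-12] <- 0
    nz <- p > 0
    ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
  }
  ent
}

# local standard deviation inside a disc window
local_sd <- function(m, radius_px) {
  k <- disc_kernel(radius_px)
  mu <- as.matrix(EBImage::filter2(as_eb(m), k, boundary = "replicate"))
  mu2 <- as.matrix(EBImage::filter2(as_eb(m^2), k, boundary = "replicate"))
  sqrt(pmax(mu2 - mu^2, 0))
}

# Homomorphic filter: high-pass in the log domain attenuates multiplicative
# illumination (low frequencies scaled by gamma_low, detail by gamma_high).
homomorphic_filter <- function(m, sigma_px, gamma_low = 0.3, gamma_high = 1,
                               roi = NULL) {
  eps <- 1e-4 * max(max(m), 1e-12)
  l <- log(pmax(m, 0) + eps)
  low <- as.matrix(EBImage::gblur(as_eb(l), sigma = sigma_px, boundary = "replicate"))
  base <- if (is.null(roi)) mean(low) else mean(low[roi])
  exp(gamma_high * (l - low) + gamma_low * low + (1 - gamma_low) * base) - eps
}

# Numeric HSV -> RGB conversion (vectorized, no 8-bit quantization).
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 1) * 6
  i <- floor(h); f <- h - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  i <- i %% 6
  idx <- i == 0; r[idx] <- v[idx]; g[idx] <- t[idx]; b[idx] <- p[idx]
  idx <- i == 1; r[idx] <- q[idx]; g[idx] <- v[idx]; b[idx] <- p[idx]
  idx <- i == 2; r[idx] <- p[idx]; g[idx] <- v[idx]; b[idx] <- t[idx]
  idx <- i == 3; r[idx] <- p[idx]; g[idx] <- q[idx]; b[idx] <- v[idx]
  idx <- i == 4; r[idx] <- t[idx]; g[idx] <- p[idx]; b[idx] <- v[idx]
  idx <- i == 5; r[idx] <- v[idx]; g[idx] <- p[idx]; b[idx] <- q[idx]
  cbind(r = r, g = g, b = b)
}

# Numeric RGB -> hue/saturation (hue in [0,1], undefined hue -> 0 with s = 0)
rgb_to_hs <- function(r, g, b) {
  hsv <- grDevices::rgb2hsv(rbind(as.vector(r), as.vector(g), as.vector(b)),
                            maxColorValue = 1)
  list(h = hsv[1, ], s = hsv[2, ])
}

# Otsu threshold of an arbitrary-range matrix (EBImage::otsu wants [0,1])
otsu_threshold <- function(m, roi = NULL, levels = 256L) {
  v <- if (is.null(roi)) as.vector(m) else m[roi]
  rng <- range(v)
  if (rng[2] - rng[1] <= 0) return(rng[1])
  vv <- (v - rng[1]) / (rng[2] - rng[1])
  th <- EBImage::otsu(EBImage::Image(matrix(vv, ncol = 1)), range = c(0, 1),
                      levels = levels)
  rng[1] + th * (rng[2] - rng[1])
}

# connected-component label matrix of a logical mask
label_mask <- function(mask) as.matrix(EBImage::bwlabel(as_eb(mask * 1)))

# drop labeled components with pixel count below a floor; returns logical mask
drop_small_components <- function(mask, min_px) {
  if (min_px <= 1 || !any(mask)) return(mask)
  lab <- label_mask(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_px)
  array(lab %in% keep, dim(mask))
}
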