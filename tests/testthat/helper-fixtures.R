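# Shared fixture builders. Everything is generated in code under fixed seeds;
# sizes are kept small so the full suite runs quickly.

jaccard <- function(a, b) sum(a & b) / sum(a | b)

# small three-channel fluorescence scene
small_fluor <- function(seed = 1, noise_sd = 0, n_cells = 4,
                        frame_shape = c(160L, 160L), ...) {
  make_fluorescence_frames(fluor_frames_spec(
    frame_shape = frame_shape, n_cells = n_cells, noise_sd = noise_sd,
    seed = seed, ...))
}

# place n non-touching spheres inside the default well by rejection sampling
random_spheres <- function(n, seed = 1, dmin = 70, dmax = 160, gap_um = 30,
                           well_radius = 540, frame_shape = c(480L, 480L),
                           pixel_size = 2.5, eccs = 0) {
  set.seed(seed)
  ctr <- frame_shape / 2 * pixel_size
  sp <- list(); tries <- 0L
  while (length(sp) < n && tries < 5000L) {
    tries <- tries + 1L
    d <- runif(1, dmin, dmax)
    a <- runif(1, 0, 2 * pi)
    r <- sqrt(runif(1)) * (well_radius - d - 40)
    cand <- ctr + r * c(cos(a), sin(a))
    ok <- all(vapply(sp, function(s)
      sqrt(sum((s$center - cand)^2)) > (s$diameter + d) / 2 + gap_um, TRUE))
    if (ok)
      sp[[length(sp) + 1L]] <- sphere_spec(cand, d,
                                           eccentricity = sample(rep(eccs, 2), 1),
                                           orientation = runif(1, 0, pi))
  }
  stopifnot(length(sp) == n)
  sp
}

# full sphere pipeline, default parameters, returning filtered records
run_sphere_pipeline <- function(well_image) {
  wm <- detect_well_interior(well_image$image)
  enh <- enhance_contrast(correct_illumination(well_image$image, wm))
  filter_spheres(detect_spheres(enh, wm))
}

# 1 x n strip of pure-hue pixels as a color_frame
hue_strip <- function(hues, s = 0.8, v = 0.6) {
  rgb <- hsv_to_rgb_test(hues, rep(s, length(hues)), rep(v, length(hues)))
  px <- array(0, c(1L, length(hues), 3L))
  px[1, , 1] <- rgb[, 1]; px[1, , 2] <- rgb[, 2]; px[1, , 3] <- rgb[, 3]
  color_frame(px, 1)
}

# independent HSV->RGB for the hue sweep (piecewise formula written directly
# from the hexcone definition, not shared with package internals)
hsv_to_rgb_test <- function(h, s, v) {
  t(vapply(seq_along(h), function(i) {
    hh <- (h[i] %% 1) * 6
    c1 <- v[i] * (1 - s[i])
    x <- v[i] * (1 - s[i] * abs(hh %% 2 - 1))
    sector <- floor(hh) %% 6
    base <- switch(as.character(sector),
                   "0" = c(v[i], x, c1), "1" = c(x, v[i], c1),
                   "2" = c(c1, v[i], x), "3" = c(c1, x, v[i]),
                   "4" = c(x, c1, v[i]), "5" = c(v[i], c1, x))
    base
  }, numeric(3)))
}
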