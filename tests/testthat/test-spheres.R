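# The sphere pipeline tests use a handful of seeded wells; the acceptance
# suite runs the larger seeded batteries.

test_that("well rim is recovered with high overlap, with and without vignetting", {
  w <- make_well_image(well_image_spec(spheres = list(), seed = 1))
  wm <- detect_well_interior(w$image)
  expect_gte(jaccard(wm$interior, w$truth_well_mask), 0.98)
  wv <- make_well_image(well_image_spec(spheres = list(),
                                        vignetting_strength = 0.3, seed = 2))
  wmv <- detect_well_interior(wv$image)
  expect_gte(jaccard(wmv$interior, wv$truth_well_mask), 0.95)
})

test_that("a rimless frame fails well detection unless the fallback is enabled", {
  flat <- intensity_frame(matrix(30000, 200, 200), 2.5)
  expect_error(detect_well_interior(flat), "rim not found")
})

test_that("illumination correction flattens a 2x gradient and keeps detail", {
  cv <- function(x) stats::sd(x) / mean(x)
  w <- make_well_image(well_image_spec(spheres = list(),
                                       illumination_gradient = 2,
                                       noise_sd = 0, seed = 1))
  wm <- detect_well_interior(w$image)
  corr <- correct_illumination(w$image, wm)
  expect_lt(cv(corr$pixels[wm$interior]),
            0.25 * cv(w$image$pixels[wm$interior]))
  # flat input passes through flat
  flat <- intensity_frame(matrix(30000, 200, 200), 2.5)
  wmf <- structure(list(interior = matrix(TRUE, 200, 200), contour = NULL,
                        center = c(100, 100), radius_px = 100),
                   class = "well_mask")
  cf <- correct_illumination(flat, wmf, se_diameter_um = 200)
  expect_lt(diff(range(cf$pixels)), 1e-6 * 30000)
  # oversized structuring element is rejected
  expect_error(correct_illumination(flat, wmf, se_diameter_um = 2000),
               "larger than the image")
})

test_that("correction preserves sphere contrast within 20% of gradient-free", {
  sp <- random_spheres(5, seed = 9)
  contrast_of <- function(g) {
    w <- make_well_image(well_image_spec(spheres = sp,
                                         illumination_gradient = g,
                                         noise_sd = 0, seed = 9))
    wm <- detect_well_interior(w$image)
    corr <- correct_illumination(w$image, wm)
    m <- Reduce(`|`, lapply(sp, function(s)
      gliomaquant:::paint_ellipse(c(480L, 480L), s$center / 2.5,
                                  s$diameter / 5, s$diameter / 5, 0)))
    stats::sd(corr$pixels[m & wm$interior]) /
      mean(corr$pixels[wm$interior & !m])
  }
  c_flat <- contrast_of(1); c_grad <- contrast_of(2)
  expect_lt(abs(c_grad - c_flat) / c_flat, 0.2)
})

test_that("enhancement boosts a low-contrast sphere boundary at least 2x", {
  ctr <- c(240, 240) * 2.5
  w <- make_well_image(well_image_spec(
    spheres = list(sphere_spec(ctr, 150, contrast = 0.05)),
    noise_sd = 0.005, seed = 4))
  band <- gliomaquant:::paint_ellipse(c(480L, 480L), c(240, 240), 34, 34, 0) &
    !gliomaquant:::paint_ellipse(c(480L, 480L), c(240, 240), 26, 26, 0)
  local_contrast <- function(img) {
    s <- gliomaquant:::local_sd(gliomaquant:::minmax_norm(img), 3)
    mean(s[band])
  }
  enh <- enhance_contrast(w$image)
  expect_gte(local_contrast(enh$pixels) / local_contrast(w$image$pixels), 2)
  # constant image is passed through unchanged
  const <- intensity_frame(matrix(0.4, 64, 64), 2.5)
  expect_identical(enhance_contrast(const)$pixels, const$pixels)
})

test_that("CLAHE keeps coarse and local ordering on a smooth ramp", {
  ramp <- intensity_frame(matrix(rep(seq(0, 1, length.out = 256), each = 256),
                                 256, 256), 1)
  er <- enhance_contrast(ramp)
  # the ramp direction must survive at coarse scale: half-tile-width column
  # blocks keep strictly increasing means
  blk <- vapply(seq(1, 256, by = 16),
                function(j) mean(er$pixels[, j:(j + 15)]), numeric(1))
  expect_true(all(diff(blk) > 0))
  # tiled CLAHE remaps locally, so only require local ordering to be largely
  # preserved inside tiles
  for (tile in list(1:32, 101:132, 225:256)) {
    rk_in <- rank(ramp$pixels[tile, tile])
    rk_out <- rank(er$pixels[tile, tile])
    expect_gt(stats::cor(rk_in, rk_out, method = "spearman"), 0.8)
  }
})

test_that("a blank well produces zero candidates and zero records", {
  w <- make_well_image(well_image_spec(spheres = list(),
                                       illumination_gradient = 1.5, seed = 3))
  rec <- run_sphere_pipeline(w)
  expect_identical(nrow(rec), 0L)
  s <- summarize_well(rec, "empty")
  expect_identical(s$sphere_count, 0L)
  expect_length(s$areas, 0)
})

test_that("non-touching spheres are each found near their true centroid", {
  sp <- random_spheres(6, seed = 21)
  w <- make_well_image(well_image_spec(spheres = sp,
                                       illumination_gradient = 2,
                                       vignetting_strength = 0.2, seed = 21))
  rec <- run_sphere_pipeline(w)
  expect_identical(nrow(rec), 6L)
  for (i in seq_len(nrow(w$truth))) {
    d_px <- sqrt((rec$centroid_row - w$truth$centroid_row[i])^2 +
                   (rec$centroid_col - w$truth$centroid_col[i])^2)
    r_px <- w$truth$equivalent_diameter_um[i] / 2 / 2.5
    expect_lt(min(d_px), r_px)
  }
})

test_that("overlapping pairs are separated into two objects by watershed", {
  ctr <- c(240, 240) * 2.5
  splits <- vapply(1:5, function(seed) {
    set.seed(seed)
    d <- runif(1, 90, 140); ang <- runif(1, 0, 2 * pi)
    off <- 0.8 * d   # centres 0.8 d apart = 20%-of-diameter overlap
    cs <- list(ctr - off / 2 * c(cos(ang), sin(ang)),
               ctr + off / 2 * c(cos(ang), sin(ang)))
    w <- make_well_image(well_image_spec(
      spheres = lapply(cs, sphere_spec, diameter = d),
      illumination_gradient = 2, seed = seed))
    wm <- detect_well_interior(w$image)
    nrow(detect_spheres(enhance_contrast(correct_illumination(w$image, wm)), wm))
  }, numeric(1))
  expect_gte(mean(splits == 2), 0.8)
})

test_that("the physical filter applies strict diameter and eccentricity cuts", {
  cand <- data.frame(label = 1:5,
                     centroid_row = 0, centroid_col = 0,
                     area_px = pi * (c(20, 30, 25, 50, 50) / 2)^2,
                     eccentricity = c(0.1, 0.1, 0.1, 0.85, 0.5))
  rec <- filter_spheres(cand, pixel_size = 2)
  # diameters (um): 40 excluded, 60 kept, 50 excluded (strict >),
  # ecc 0.85 excluded, 0.5 kept
  expect_identical(nrow(rec), 2L)
  expect_equal(sort(rec$equivalent_diameter_um), c(60, 100))
  expect_error(filter_spheres(cand[, ], pixel_size = NULL), "pixel_size")
})

test_that("raising the thresholds never increases the sphere count", {
  sp <- random_spheres(7, seed = 31, dmin = 55, dmax = 160,
                       eccs = c(0, 0.4, 0.7))
  w <- make_well_image(well_image_spec(spheres = sp, seed = 31))
  wm <- detect_well_interior(w$image)
  cand <- detect_spheres(enhance_contrast(correct_illumination(w$image, wm)), wm)
  n_base <- nrow(filter_spheres(cand, 2.5))
  for (md in c(60, 80, 100))
    expect_lte(nrow(filter_spheres(cand, 2.5, min_diameter_um = md)), n_base)
  for (me in c(0.6, 0.4, 0.2))
    expect_lte(nrow(filter_spheres(cand, 2.5, max_eccentricity = me)), n_base)
})

test_that("rotating the well by 90 degrees leaves the area multiset stable", {
  sp <- random_spheres(5, seed = 41)
  w <- make_well_image(well_image_spec(spheres = sp,
                                       illumination_gradient = 2, seed = 41))
  rec <- run_sphere_pipeline(w)
  rot <- intensity_frame(t(w$image$pixels)[ncol(w$image$pixels):1, ],
                         w$image$pixel_size)
  rec_rot <- run_sphere_pipeline(list(image = rot))
  expect_identical(nrow(rec_rot), nrow(rec))
  a <- sort(rec$area_um2); b <- sort(rec_rot$area_um2)
  expect_lt(max(abs(a - b) / a), 0.02)
})

test_that("well summaries count large spheres above 1e5 um2 strictly", {
  rec <- data.frame(sphere_id = 1:2, centroid_row = 0, centroid_col = 0,
                    area_um2 = c(2e4, 1.2e5),
                    equivalent_diameter_um = 2 * sqrt(c(2e4, 1.2e5) / pi),
                    eccentricity = 0)
  s <- summarize_well(rec, "w1")
  expect_identical(s$sphere_count, 2L)
  expect_identical(s$large_sphere_count, 1L)
  # replicate-well mean count equals the direct mean
  counts <- c(3L, 5L, 4L)
  summaries <- lapply(counts, function(n)
    summarize_well(rec[rep(1, n), ], "w"))
  expect_identical(mean(vapply(summaries, `[[`, 0L, "sphere_count")),
                   mean(counts))
})
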