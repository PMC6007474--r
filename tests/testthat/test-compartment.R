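test_that("noiseless two-level frames segment exactly to generator truth", {
  fr <- small_fluor(seed = 3, noise_sd = 0)
  nuc <- segment_nuclei(fr$dapi)
  cyt <- segment_cytoplasm(fr$phalloidin, nuc)
  expect_identical(unname(nuc), unname(fr$truth$nuclear))
  expect_identical(unname(cyt), unname(fr$truth$cytoplasmic))
})

test_that("flat and all-zero frames give empty masks with a warning", {
  zero <- intensity_frame(matrix(0, 32, 32), 1)
  expect_warning(m <- segment_nuclei(zero), "flat")
  expect_false(any(m))
})

test_that("noisy frames still recover masks and means accurately", {
  for (s in 1:4) {
    fr <- small_fluor(seed = s, noise_sd = 20, n_cells = 5,
                      frame_shape = c(192L, 192L))
    nuc <- segment_nuclei(fr$dapi)
    cyt <- segment_cytoplasm(fr$phalloidin, nuc)
    expect_gt(jaccard(nuc, fr$truth$nuclear), 0.9)
    q <- quantify_frame(fr$marker, list(nuclear = nuc, cytoplasmic = cyt))
    expect_lt(abs(q$nuclear_mean - 200) / 200, 0.05)
    expect_lt(abs(q$cytoplasmic_mean - 100) / 100, 0.05)
    expect_false(any(nuc & cyt))
  }
})

test_that("closing bridges sub-6-um gaps, matching a brute-force oracle", {
  fr <- small_fluor(seed = 6, noise_sd = 0, n_cells = 1)
  phal <- fr$phalloidin
  # punch a 4-px (2 um at 0.5 um/px) slit through the cell footprint
  centre <- round(fr$truth$centers[1, ])
  slit_cols <- centre[2] + (-1:2)
  phal$pixels[, slit_cols][fr$truth$nuclear[, slit_cols] |
                             fr$truth$cytoplasmic[, slit_cols]] <- 10
  nuc <- segment_nuclei(fr$dapi)
  cyt <- segment_cytoplasm(phal, nuc)
  footprint <- cyt | nuc
  # oracle: brute-force binary closing (dilate then erode) of the slit image
  raw <- phal$pixels > 100
  b <- EBImage::makeBrush(13L, "disc")
  oracle <- as.matrix(EBImage::erode(EBImage::dilate(
    EBImage::Image(raw * 1), b), b)) > 0.5
  expect_true(all(footprint[, slit_cols] == oracle[, slit_cols]))
  # the slit interior is recovered as cell area
  expect_true(any(footprint[centre[1], slit_cols]))
})

test_that("quantification is exact on truth masks and flags empty compartments", {
  fr <- small_fluor(seed = 2, noise_sd = 0)
  q <- quantify_frame(fr$marker, fr$truth)
  expect_identical(q$nuclear_mean, 200)
  expect_identical(q$cytoplasmic_mean, 100)
  expect_equal(q$nuclear_area_um2, sum(fr$truth$nuclear) * 0.25)
  d <- dim(fr$marker$pixels)
  const <- intensity_frame(matrix(42, d[1], d[2]), 0.5)
  qc <- quantify_frame(const, fr$truth)
  expect_identical(qc$nuclear_mean, 42)
  expect_identical(qc$cytoplasmic_mean, 42)
  empty <- list(nuclear = matrix(FALSE, d[1], d[2]),
                cytoplasmic = fr$truth$cytoplasmic)
  expect_true(is.na(quantify_frame(fr$marker, empty)$nuclear_mean))
  overlapping <- list(nuclear = fr$truth$nuclear, cytoplasmic = fr$truth$nuclear)
  expect_error(quantify_frame(fr$marker, overlapping), "disjoint")
})

test_that("marker intensity scaling scales both means exactly", {
  fr <- small_fluor(seed = 4, noise_sd = 10)
  nuc <- segment_nuclei(fr$dapi)
  cyt <- segment_cytoplasm(fr$phalloidin, nuc)
  masks <- list(nuclear = nuc, cytoplasmic = cyt)
  q1 <- quantify_frame(fr$marker, masks)
  scaled <- intensity_frame(fr$marker$pixels * 3, fr$marker$pixel_size)
  q3 <- quantify_frame(scaled, masks)
  expect_equal(q3$nuclear_mean, 3 * q1$nuclear_mean)
  expect_equal(q3$cytoplasmic_mean, 3 * q1$cytoplasmic_mean)
})

test_that("halving pixel size changes recovered means by under 2 percent", {
  base <- fluor_frames_spec(frame_shape = c(128L, 128L), pixel_size = 1,
                            n_cells = 4, noise_sd = 0, seed = 11)
  fine <- fluor_frames_spec(frame_shape = c(256L, 256L), pixel_size = 0.5,
                            n_cells = 4, noise_sd = 0, seed = 11)
  q <- lapply(list(base, fine), function(sp) {
    fr <- make_fluorescence_frames(sp)
    nuc <- segment_nuclei(fr$dapi)
    cyt <- segment_cytoplasm(fr$phalloidin, nuc)
    quantify_frame(fr$marker, list(nuclear = nuc, cytoplasmic = cyt))
  })
  expect_lt(abs(q[[1]]$nuclear_mean - q[[2]]$nuclear_mean) / q[[1]]$nuclear_mean,
            0.02)
  expect_lt(abs(q[[1]]$cytoplasmic_mean - q[[2]]$cytoplasmic_mean) /
              q[[1]]$cytoplasmic_mean, 0.02)
})

test_that("coarse calibration making the 6-um disc sub-pixel is an error", {
  fr <- small_fluor(seed = 1)
  coarse <- intensity_frame(fr$phalloidin$pixels, pixel_size = 8)
  expect_error(segment_cytoplasm(coarse, fr$truth$nuclear), "pixel")
})

test_that("set summaries average non-excluded frames with equal weights", {
  rows <- do.call(rbind, lapply(1:4, function(i)
    data.frame(frame_id = paste0("f", i), nuclear_mean = 100 * i,
               cytoplasmic_mean = 50 * i, nuclear_area_um2 = 1,
               cytoplasmic_area_um2 = 1)))
  s <- summarize_set(rows, condition = "ctrl")
  expect_identical(s$nuclear_mean, 250)
  one <- summarize_set(rows[2, ], condition = "one")
  expect_identical(one$nuclear_mean, 200)
  ex <- summarize_set(rows, excluded_frames = c("f1", "f4"), condition = "qc")
  expect_identical(ex$n_frames, 2L)
  expect_identical(ex$n_excluded, 2L)
  expect_identical(ex$nuclear_mean, mean(c(200, 300)))
  expect_error(summarize_set(rows, excluded_frames = paste0("f", 1:4)),
               "all frames excluded")
})
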