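#' Run a pipeline stage over a directory of inputs
#'
#' Shared batch driver for all stages. Inputs are processed in lexicographic
#' order (deterministic across platforms), excluded frames are logged and
#' skipped, and a failure on one item is recorded while the batch continues;
#' the returned status is nonzero when any item failed. Result tables and a
#' plain-text log are written to \code{out_dir}.
#'
#' @param stage One of "ifquant", "sabgal", "spheres", "synergy", "synth".
#' @param inputs Directory of images (a single CSV file for "synergy";
#'   ignored for "synth").
#' @param config A [gq_config()].
#' @param exclusions Character vector of input file names flagged by the
#'   reviewer (must exist in the input set).
#' @param out_dir Output directory; created if needed.
#' @return List: \code{results} (stage-dependent data.frame), \code{failures}
#'   (named character vector of error messages), \code{log} (character),
#'   \code{status} (0 = clean).
#' @export
run_batch <- function(stage, inputs, config = gq_config(),
                      exclusions = character(), out_dir = ".") {
  stage <- match.arg(stage, c("ifquant", "sabgal", "spheres", "synergy", "synth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- c(sprintf("stage=%s inputs=%s", stage, inputs),
           sprintf("config: pixel_size=%s seed=%s", config$pixel_size,
                   if (is.null(config$seed)) "NULL" else config$seed))
  failures <- character()

  if (stage == "synth") {
    res <- synth_demo_set(config, out_dir)
    log <- c(log, sprintf("wrote synthetic demo set to %s", out_dir))
    writeLines(log, file.path(out_dir, "batch.log"))
    return(list(results = res, failures = failures, log = log, status = 0L))
  }

  if (stage == "synergy") {
    tab <- utils::read.csv(inputs, stringsAsFactors = FALSE)
    rep_df <- synergy_report(tab, alpha = config$synergy$alpha,
                             pairing = config$synergy$pairing,
                             multiplicity = config$synergy$multiplicity,
                             control_group = config$synergy$control_group)
    write_result_csv(rep_df, file.path(out_dir, "synergy_calls.csv"))
    log <- c(log, sprintf("%d dose level(s) classified", nrow(rep_df)))
    writeLines(log, file.path(out_dir, "batch.log"))
    return(list(results = rep_df, failures = failures, log = log, status = 0L))
  }

  files <- sort(list.files(inputs, pattern = "\\.(tif|tiff|png)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no input images found in ", inputs)
  unknown <- setdiff(exclusions, files)
  if (length(unknown))
    stop("exclusion list names files not in the input set: ",
         paste(unknown, collapse = ", "))

  rows <- list()
  for (f in files) {
    if (f %in% exclusions) {
      log <- c(log, sprintf("EXCLUDED %s (reviewer flag)", f))
      next
    }
    res <- tryCatch(
      switch(stage,
             ifquant = batch_item_ifquant(file.path(inputs, f), f, config),
             sabgal = batch_item_sabgal(file.path(inputs, f), f, config),
             spheres = batch_item_spheres(file.path(inputs, f), f, config)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[f] <- conditionMessage(res)
      log <- c(log, sprintf("FAILED %s: %s", f, conditionMessage(res)))
    } else {
      rows[[f]] <- res
      log <- c(log, sprintf("ok %s", f))
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(results)) {
    rownames(results) <- NULL
    write_result_csv(results, file.path(out_dir, paste0(stage, "_frames.csv")))
  }
  writeLines(log, file.path(out_dir, "batch.log"))
  list(results = results, failures = failures, log = log,
       status = if (length(failures)) 1L else 0L)
}

# one multi-plane TIFF (channels per config$channel_map) -> compartment row
batch_item_ifquant <- function(path, frame_id, config) {
  planes <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(planes)) planes <- list(planes)
  ps <- ome_pixel_size(attr(planes[[1]], "description"))
  if (is.null(ps)) ps <- config$pixel_size
  if (is.null(ps) || is.na(ps)) stop("no pixel size for ", frame_id)
  ch <- function(role) {
    i <- config$channel_map[[role]]
    if (i > length(planes)) stop("channel_map asks for plane ", i,
                                 " but file has ", length(planes))
    intensity_frame(round(planes[[i]] * 65535), ps)
  }
  quantify_if_frame(ch("dapi"), ch("phalloidin"), ch("marker"),
                    frame_id = frame_id,
                    min_area_um2 = config$compartment$nuclear_min_area_um2)
}

batch_item_sabgal <- function(path, frame_id, config) {
  frame <- read_image(path, config = config)
  if (!inherits(frame, "color_frame"))
    stop("sabgal stage expects RGB images; ", frame_id, " is grayscale")
  s <- config$sabgal
  sabgal_fraction(frame, frame_id = frame_id, hue_lo = s$hue_lo,
                  hue_hi = s$hue_hi, s_min = s$s_min,
                  dilate_px = s$dilate_px, erode_px = s$erode_px,
                  min_object_um2 = s$min_object_um2)
}

batch_item_spheres <- function(path, well_id, config) {
  frame <- read_image(path, config = config)
  if (!inherits(frame, "intensity_frame"))
    stop("spheres stage expects grayscale images; ", well_id, " is RGB")
  out <- analyze_well(frame, well_id = well_id, config = config)
  s <- out$summary
  data.frame(well_id = s$well_id, sphere_count = s$sphere_count,
             large_sphere_count = s$large_sphere_count,
             median_area_um2 = if (s$sphere_count) stats::median(s$areas) else NA_real_,
             total_area_um2 = sum(s$areas))
}

# small seeded demonstration set covering every generator
synth_demo_set <- function(config, out_dir) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  fr <- make_fluorescence_frames(fluor_frames_spec(
    frame_shape = c(256L, 256L), n_cells = 12L, noise_sd = 20, seed = seed))
  write_image(fr$dapi, file.path(out_dir, "fluor_dapi.tif"))
  write_image(fr$phalloidin, file.path(out_dir, "fluor_phalloidin.tif"))
  write_image(fr$marker, file.path(out_dir, "fluor_marker.tif"))
  sb <- make_sabgal_image(sabgal_image_spec(seed = seed))
  write_image(sb$rgb, file.path(out_dir, "sabgal.png"))
  wl <- make_well_image(well_image_spec(
    spheres = list(sphere_spec(c(500, 500), 120),
                   sphere_spec(c(700, 650), 90)),
    illumination_gradient = 2, seed = seed))
  write_image(wl$image, file.path(out_dir, "well.tif"))
  tab <- make_viability_table(viability_sim_spec(seed = seed))
  write_result_csv(tab, file.path(out_dir, "viability.csv"))
  write_result_csv(wl$truth, file.path(out_dir, "well_truth.csv"))
  data.frame(artifact = c("fluor_dapi.tif", "fluor_phalloidin.tif",
                          "fluor_marker.tif", "sabgal.png", "well.tif",
                          "viability.csv", "well_truth.csv"))
}
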