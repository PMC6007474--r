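#' Default run configuration
#'
#' Central registry of every tunable used by the pipelines, with the fixed
#' method constants (hue window 0.265-0.58, 6 um closing disc, sphere filter
#' > 50 um diameter and < 0.8 eccentricity, alpha = 0.05) as documented
#' defaults. Any subset of keys may be overridden; unknown keys are rejected
#' to catch typos.
#'
#' @param ... Named overrides, either top-level (\code{pixel_size = 0.5}) or
#'   nested lists (\code{spheres = list(min_diameter_um = 60)}).
#' @return A nested list of class \code{gq_config}.
#' @examples
#' cfg <- gq_config(pixel_size = 1, sabgal = list(s_min = 0))
#' cfg$sabgal$hue_lo
#' @export
gq_config <- function(...) {
  defaults <- list(
    pixel_size = NA_real_,          # um/pixel; must come from metadata or here
    seed = NULL,
    output_dir = ".",
    channel_map = list(dapi = 1L, phalloidin = 2L, marker = 3L),
    compartment = list(
      nuclear_min_area_um2 = 10,
      closing_diameter_um = 6
    ),
    sabgal = list(
      hue_lo = 0.265, hue_hi = 0.58, s_min = 0.1,
      dilate_px = 2, erode_px = 3, min_object_um2 = 50
    ),
    spheres = list(
      min_diameter_um = 50, max_eccentricity = 0.8, large_area_um2 = 1e5,
      se_diameter_um = 320, gamma_low = 0.3,
      compression_k = 2, clahe_tiles = 8L, clahe_limit = 4,
      entropy_radius_px = NULL, entropy_bins = 32L,
      ws_sigma = 2, ws_tolerance = 0.5, refine_radius_px = 1L,
      well_fallback = "none"
    ),
    synergy = list(
      alpha = 0.05, pairing = "matched", multiplicity = "joint",
      control_group = "control"
    )
  )
  cfg <- merge_config(defaults, list(...), path = "")
  validate_config(cfg)
  structure(cfg, class = "gq_config")
}

# recursive merge of overrides into defaults, rejecting unknown keys
merge_config <- function(defaults, overrides, path) {
  if (length(overrides) == 0L) return(defaults)
  nms <- names(overrides)
  if (is.null(nms) || any(nms == ""))
    stop("config overrides must be named", if (nzchar(path)) paste0(" (in '", path, "')"))
  unknown <- setdiff(nms, names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(if (nzchar(path)) paste0(path, "."), unknown, collapse = ", "))
  for (nm in nms) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste0(if (nzchar(path)) paste0(path, "."), nm))
    } else {
      defaults[nm] <- overrides[nm]   # [<- keeps explicit NULLs meaningful
    }
  }
  defaults
}

validate_config <- function(cfg) {
  fail <- function(key, why) stop("invalid config: '", key, "' ", why)
  if (!is.na(cfg$pixel_size) && (!is.numeric(cfg$pixel_size) || cfg$pixel_size <= 0))
    fail("pixel_size", "must be a positive number (um/pixel)")
  s <- cfg$sabgal
  if (s$hue_lo < 0 || s$hue_hi > 1 || s$hue_lo > s$hue_hi)
    fail("sabgal.hue_lo/hue_hi", "must satisfy 0 <= hue_lo <= hue_hi <= 1")
  if (s$s_min < 0 || s$s_min > 1) fail("sabgal.s_min", "must lie in [0, 1]")
  sp <- cfg$spheres
  if (sp$min_diameter_um <= 0) fail("spheres.min_diameter_um", "must be > 0")
  if (sp$max_eccentricity <= 0 || sp$max_eccentricity > 1)
    fail("spheres.max_eccentricity", "must lie in (0, 1]")
  if (!sp$well_fallback %in% c("none", "threshold"))
    fail("spheres.well_fallback", "must be 'none' or 'threshold'")
  sy <- cfg$synergy
  if (sy$alpha <= 0 || sy$alpha >= 1) fail("synergy.alpha", "must lie in (0, 1)")
  if (!sy$pairing %in% c("matched", "pairwise"))
    fail("synergy.pairing", "must be 'matched' or 'pairwise'")
  if (!sy$multiplicity %in% c("joint", "per_dose"))
    fail("synergy.multiplicity", "must be 'joint' or 'per_dose'")
  cp <- cfg$compartment
  if (cp$closing_diameter_um <= 0)
    fail("compartment.closing_diameter_um", "must be > 0")
  invisible(cfg)
}

#' Load a run configuration from a YAML file
#'
#' Reads a (possibly partial) key-value file, merges it over the documented
#' defaults of [gq_config()], and validates. Unknown keys raise an error so
#' that typos are caught rather than silently ignored; an empty file yields
#' the full defaults.
#'
#' @param path Path to a YAML config file.
#' @return A validated \code{gq_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(gq_config, raw)
}

#' Save a run configuration to a YAML file
#'
#' @param config A \code{gq_config}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "gq_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
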