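#' Analyze one micrograph: nanostructure to predicted reflectance
#'
#' Runs the single-image pipeline: load (or accept) a grayscale
#' cross-section image, crop a square analysis region, segment it into two
#' phases, assign refractive indices, take the 2-D Fourier power spectrum,
#' radially average it, and map the profile to a predicted reflectance
#' spectrum with its peak wavelength.
#'
#' @param x A file path (PNG/TIFF), a `raster_image`, or a
#'   `synthetic_image`.
#' @param pixel_size nm per pixel; required when `x` is a path, otherwise
#'   taken from the object.
#' @param crop_size Side of the square analysis region in pixels; default
#'   the largest centered square.
#' @param n_high,n_low Refractive indices for the two phases (defaults
#'   chitin 1.56, air 1.0).
#' @param binarize_method,threshold,invert Passed to [binarize_phases()].
#' @param window Passed to [power_spectrum_2d()].
#' @param bin_width Radial annulus width in cycles/nm; default one
#'   frequency step.
#' @param lambda_max_method,visible_band Passed to [predicted_reflectance()].
#' @return A `predicted_spectrum` with the `radial_profile` attached as
#'   `$profile` and the analyzed crop's `fill` fraction recorded.
#' @examples
#' img <- generate_multilayer_image(bilayer(110, 111), periods = 5)
#' ps <- analyze_image(img)
#' ps$lambda_max  # ~565 nm
#' @export
analyze_image <- function(x, pixel_size = NULL, crop_size = NULL,
                          n_high = 1.56, n_low = 1.0,
                          binarize_method = "otsu", threshold = NULL,
                          invert = FALSE, window = "none",
                          bin_width = NULL,
                          lambda_max_method = "parabolic",
                          visible_band = c(350, 700)) {
  img <- if (is.character(x)) {
    load_image(x, pixel_size = pixel_size)
  } else if (inherits(x, "raster_image")) {
    x
  } else {
    stop("x must be a file path or raster_image", call. = FALSE)
  }
  if (is.null(crop_size)) crop_size <- min(dim(img$pixels))
  img <- select_square_region(img, crop_size)
  phase <- binarize_phases(img, method = binarize_method,
                           threshold = threshold, invert = invert)
  imap <- build_index_map(phase, n_high = n_high, n_low = n_low)
  ps <- power_spectrum_2d(imap, window = window)
  prof <- if (is.null(bin_width)) radial_average(ps)
          else radial_average(ps, bin_width = bin_width)
  spec <- predicted_reflectance(prof, n_bar = imap$n_bar,
                                lambda_max_method = lambda_max_method,
                                visible_band = visible_band)
  spec$profile <- prof
  spec$fill <- imap$fill
  spec
}

#' Assemble a reconstruction run configuration
#'
#' @param zones A list of zone entries, each a list with `name`, `images`
#'   (character paths and/or `raster_image` objects), and optionally
#'   `pixel_size` (required for paths).
#' @param n_high,n_low Refractive indices of the two phases.
#' @param crop_size,bin_width,window,binarize_method,threshold,invert,
#'   lambda_max_method,visible_band Pipeline options, as in
#'   [analyze_image()].
#' @param lambda_max_which `"visible"` (default) or `"unrestricted"`: which
#'   peak feeds the color reconstruction.
#' @param aggregate `"mean"` (default) or `"median"` across replicate
#'   images of a zone.
#' @param rgb_methods Conversion methods for [consensus_rgb()].
#' @param out_dir Optional directory for the report (JSON + CSV) and swatch
#'   panel (PNG).
#' @param deterministic Suppress timestamps in the report so re-runs are
#'   byte-identical (default TRUE).
#' @param seed Seed echoed into the report (the analysis itself is
#'   deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(zones,
                       n_high = 1.56, n_low = 1.0,
                       crop_size = NULL, bin_width = NULL,
                       window = "none",
                       binarize_method = "otsu", threshold = NULL,
                       invert = FALSE,
                       lambda_max_method = "parabolic",
                       visible_band = c(350, 700),
                       lambda_max_which = c("visible", "unrestricted"),
                       aggregate = c("mean", "median"),
                       rgb_methods = c("bruton", "cie", "bruton_linear"),
                       out_dir = NULL,
                       deterministic = TRUE,
                       seed = 0) {
  stopifnot(length(zones) >= 1)
  nm <- vapply(zones, function(z) z$name %||% NA_character_, character(1))
  if (anyNA(nm) || anyDuplicated(nm)) {
    stop("every zone needs a unique `name`", call. = FALSE)
  }
  for (z in zones) {
    if (length(z$images) < 1) {
      stop("zone '", z$name, "' has no images", call. = FALSE)
    }
  }
  if (!(n_high > n_low)) stop("need n_high > n_low", call. = FALSE)
  structure(
    list(zones = zones, n_high = n_high, n_low = n_low,
         crop_size = crop_size, bin_width = bin_width, window = window,
         binarize_method = binarize_method, threshold = threshold,
         invert = invert, lambda_max_method = lambda_max_method,
         visible_band = visible_band,
         lambda_max_which = match.arg(lambda_max_which),
         aggregate = match.arg(aggregate),
         rgb_methods = rgb_methods, out_dir = out_dir,
         deterministic = deterministic, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' The file mirrors the arguments of [run_config()]: a `zones` list (each
#' with `name`, `images`, `pixel_size`) plus any pipeline options.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    stop("config must be YAML or JSON", call. = FALSE)
  }
  if (is.null(raw$zones)) stop("config has no `zones`", call. = FALSE)
  zones <- lapply(raw$zones, function(z) {
    z$images <- unlist(z$images)
    z
  })
  raw$zones <- NULL
  args <- c(list(zones = zones), raw)
  do.call(run_config, args)
}

#' Run the full color reconstruction
#'
#' For every zone and replicate image: load, crop, segment, build the index
#' map, Fourier-transform, radially average, and extract the predicted peak
#' wavelength. Replicate peaks are aggregated per zone (mean by default) and
#' converted to a consensus RGB color. Degenerate segmentations are flagged
#' (the zone's peak becomes `NA`) and the run continues; unreadable files
#' are an error naming the zone and path.
#'
#' @param config A `run_config`, or a path to a YAML/JSON config file.
#' @return A `reconstruction_report`: list with `zones` (tibble: zone,
#'   n_replicates, lambda_max mean/min/max, consensus `r`,`g`,`b`, `hex`,
#'   `flag`), `replicates` (tibble: zone, replicate, source, lambda_max
#'   visible and unrestricted, n_bar, fill), `config` echo, and `version`.
#'   When `config$out_dir` is set, writes `report.json`, `zones.csv`,
#'   `replicates.csv`, and `reconstruction.png` there.
#' @export
run_reconstruction <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  reps <- purrr::map_dfr(config$zones, function(z) {
    purrr::imap_dfr(z$images, function(im, k) {
      src <- if (is.character(im)) im else sprintf("<in-memory %d>", k)
      if (is.character(im) && !file.exists(im)) {
        stop("zone '", z$name, "': image not readable: ", im, call. = FALSE)
      }
      res <- tryCatch(
        analyze_image(im,
          pixel_size = z$pixel_size,
          crop_size = config$crop_size,
          n_high = config$n_high, n_low = config$n_low,
          binarize_method = config$binarize_method,
          threshold = config$threshold, invert = config$invert,
          window = config$window, bin_width = config$bin_width,
          lambda_max_method = config$lambda_max_method,
          visible_band = config$visible_band),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        if (grepl("degenerate", conditionMessage(res))) {
          warning("zone '", z$name, "', ", src, ": ", conditionMessage(res),
                  call. = FALSE)
          return(tibble::tibble(
            zone = z$name, replicate = k, source = src,
            lambda_max = NA_real_, lambda_max_unrestricted = NA_real_,
            n_bar = NA_real_, fill = NA_real_, flag = "degenerate"))
        }
        stop("zone '", z$name, "', ", src, ": ", conditionMessage(res),
             call. = FALSE)
      }
      tibble::tibble(
        zone = z$name, replicate = k, source = src,
        lambda_max = res$lambda_max,
        lambda_max_unrestricted = res$lambda_max_unrestricted,
        n_bar = res$n_bar, fill = res$fill, flag = "ok")
    })
  })

  agg_fun <- if (config$aggregate == "mean") mean else stats::median
  peak_col <- if (config$lambda_max_which == "visible") "lambda_max"
              else "lambda_max_unrestricted"
  zones_tbl <- reps |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      lambda_lo = suppressWarnings(min(.data[[peak_col]][.data$flag == "ok"])),
      lambda_hi = suppressWarnings(max(.data[[peak_col]][.data$flag == "ok"])),
      lambda_max = agg_fun(.data[[peak_col]][.data$flag == "ok"]),
      flag = if (all(.data$flag == "ok")) "ok" else "degenerate",
      .groups = "drop"
    )
  # preserve config zone order
  zones_tbl <- zones_tbl[match(vapply(config$zones, `[[`, "", "name"),
                               zones_tbl$zone), ]
  ok <- !is.na(zones_tbl$lambda_max)
  cols <- consensus_rgb(ifelse(ok, zones_tbl$lambda_max, 1), config$rgb_methods)
  zones_tbl$r <- ifelse(ok, cols$r, NA_integer_)
  zones_tbl$g <- ifelse(ok, cols$g, NA_integer_)
  zones_tbl$b <- ifelse(ok, cols$b, NA_integer_)
  zones_tbl$hex <- ifelse(
    ok, grDevices::rgb(cols$r, cols$g, cols$b, maxColorValue = 255),
    NA_character_)

  report <- structure(
    list(zones = zones_tbl, replicates = reps,
         config = config_echo(config),
         version = as.character(utils::packageVersion("chromoscale")),
         timestamp = if (config$deterministic) NULL
                     else format(Sys.time(), tz = "UTC")),
    class = "reconstruction_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

config_echo <- function(config) {
  e <- unclass(config)
  e$zones <- lapply(e$zones, function(z) {
    z$images <- vapply(seq_along(z$images), function(k) {
      if (is.character(z$images[[k]])) z$images[[k]]
      else sprintf("<in-memory %d>", k)
    }, character(1))
    z
  })
  e$out_dir <- NULL
  e
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(zones = report$zones, replicates = report$replicates,
         config = report$config, version = report$version,
         timestamp = report$timestamp),
    file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  utils::write.csv(report$zones, file.path(out_dir, "zones.csv"),
                   row.names = FALSE)
  utils::write.csv(report$replicates, file.path(out_dir, "replicates.csv"),
                   row.names = FALSE)
  okz <- report$zones[!is.na(report$zones$lambda_max), ]
  if (nrow(okz) > 0) {
    render_reconstruction(okz, file.path(out_dir, "reconstruction.png"))
  }
  invisible(out_dir)
}

#' @export
print.reconstruction_report <- function(x, ...) {
  cat("<reconstruction_report> chromoscale ", x$version, "\n", sep = "")
  print(x$zones)
  invisible(x)
}

#' @rdname run_reconstruction
#' @param x A `reconstruction_report`.
#' @param ... Unused.
#' @export
tidy.reconstruction_report <- function(x, ...) x$replicates

#' @rdname run_reconstruction
#' @export
glance.reconstruction_report <- function(x, ...) x$zones
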