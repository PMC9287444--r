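# The iFDO factory: orchestrates curation of a raw image directory plus a
# navigation track into one validated iFDO document. Pipeline order matters:
# UUIDs are minted into the image files *before* hashing, because the hash
# fingerprints the final bytes; positions are interpolated from the curated
# (outlier-free, smoothed) track; fields shared by every item are factored
# into the header as defaults.

#' Project configuration for the iFDO factory
#'
#' Bundles the project-level information that accompanies an image
#' acquisition: context and ownership fields, reuse permissions, the handle
#' server used to build persistent identifiers, the camera geometry used for
#' footprint derivation, navigation curation parameters and capture-section
#' defaults.
#'
#' @param project,event,platform,sensor,context,abstract free-text context
#'   fields; project, event and sensor must be filename-safe (letters,
#'   digits, `.`, `_`, `-`) because they enter the canonical filename.
#' @param pi principal investigator, `list(name =, orcid =)`.
#' @param creators list of `list(name =, orcid =)` entries.
#' @param license,copyright reuse permission strings.
#' @param handle_server,handle_prefix handle URL components.
#' @param set_name optional set name; defaults to `<project> <event> <sensor>`.
#' @param crs coordinate reference system identifier for positions.
#' @param camera optional [camera_geometry()].
#' @param altitude_meters optional constant camera altitude above ground, in
#'   meters, used for footprint derivation.
#' @param nav_window,nav_k,nav_uncertainty_meters navigation curation
#'   parameters: outlier/smoothing window (samples), MAD multiplier and
#'   base sensor uncertainty (meters).
#' @param capture named list of capture-section defaults (e.g. acquisition,
#'   deployment, illumination, capture_mode, objective ...).
#' @return object of class `ifdo_config`.
#' @export
ifdo_config <- function(project, event, platform, sensor,
                        context = project, abstract = "",
                        pi = NULL, creators = list(),
                        license = "CC-BY-4.0", copyright = "",
                        handle_server = "https://hdl.handle.net",
                        handle_prefix = "20.500.12085",
                        set_name = NULL,
                        crs = "EPSG:4326",
                        camera = NULL, altitude_meters = NULL,
                        nav_window = 11L, nav_k = 5,
                        nav_uncertainty_meters = 0,
                        capture = list()) {
  for (comp in c(project, event, sensor))
    if (!grepl("^[A-Za-z0-9._-]+$", comp))
      stop("filename-unsafe component: '", comp, "'", call. = FALSE)
  structure(list(
    project = project, event = event, platform = platform, sensor = sensor,
    context = context, abstract = abstract, pi = pi, creators = creators,
    license = license, copyright = copyright,
    handle_server = handle_server, handle_prefix = handle_prefix,
    set_name = set_name %||% paste(project, event, sensor),
    crs = crs, camera = camera, altitude_meters = altitude_meters,
    nav_window = nav_window, nav_k = nav_k,
    nav_uncertainty_meters = nav_uncertainty_meters,
    capture = capture
  ), class = "ifdo_config")
}

#' Read a project configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [ifdo_config()];
#'   `camera` is a mapping with `horizontal_fov`, `vertical_fov`,
#'   `image_width`, `image_height`.
#' @return object of class `ifdo_config`.
#' @export
read_ifdo_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$camera)) raw$camera <- do.call(camera_geometry, raw$camera)
  do.call(ifdo_config, raw)
}

#' Camera geometry for footprint derivation
#'
#' @param horizontal_fov,vertical_fov full fields of view in degrees,
#'   each in (0, 180).
#' @param image_width,image_height sensor resolution in pixels.
#' @return object of class `camera_geometry`.
#' @export
camera_geometry <- function(horizontal_fov, vertical_fov,
                            image_width, image_height) {
  if (horizontal_fov <= 0 || horizontal_fov >= 180 ||
      vertical_fov <= 0 || vertical_fov >= 180)
    stop("fields of view must be in (0, 180) degrees", call. = FALSE)
  if (image_width <= 0 || image_height <= 0)
    stop("image dimensions must be positive", call. = FALSE)
  structure(list(horizontal_fov = horizontal_fov,
                 vertical_fov = vertical_fov,
                 image_width = image_width, image_height = image_height),
            class = "camera_geometry")
}

#' Canonical curated filename for an image
#'
#' `<project>_<event>_<sensor>_<YYYYMMDD>_<HHMMSS.sss>.<ext>` with the
#' original extension lowercased. When `dir` is given and a *different*
#' file already occupies the name, numeric suffixes `_1`, `_2`, ... are
#' tried (with a warning).
#'
#' @param config an `ifdo_config`.
#' @param datetime POSIXct or ISO 8601 UTC string.
#' @param original original file name (supplies the extension).
#' @param dir optional directory to check for collisions.
#' @return the canonical file name (no directory part).
#' @export
rename_file <- function(config, datetime, original, dir = NULL) {
  if (is.character(datetime)) {
    datetime <- parse_ifdo_datetime(datetime)
    if (is.na(datetime)) stop("invalid datetime", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(original))
  canon <- format_ifdo_datetime(datetime)  # YYYY-MM-DDTHH:MM:SS.sssZ
  date_part <- gsub("-", "", substr(canon, 1, 10))
  time_part <- paste0(gsub(":", "", substr(canon, 12, 19)),
                      substr(canon, 20, 23))
  stem <- paste(config$project, config$event, config$sensor,
                date_part, time_part, sep = "_")
  name <- paste0(stem, ".", ext)
  if (!is.null(dir)) {
    k <- 0L
    while (file.exists(file.path(dir, name))) {
      k <- k + 1L
      name <- paste0(stem, "_", k, ".", ext)
    }
    if (k > 0L)
      warning("filename collision; using suffix _", k, " for '",
              original, "'", call. = FALSE)
  }
  name
}

#' Seafloor footprint of a nadir camera
#'
#' Pinhole model looking straight down: at altitude `h` the imaged width is
#' `2 h tan(hfov / 2)` and the height `2 h tan(vfov / 2)`; the footprint
#' area is their product and the scale is `image_width / width_m` pixels
#' per meter. Populates the `image-area-square-meter` and
#' `image-meters-above-ground` fields.
#'
#' @param geometry a [camera_geometry()].
#' @param altitude camera altitude above ground in meters, > 0.
#' @return list with `area_square_meter`, `pixels_per_meter`, `width_m`,
#'   `height_m`.
#' @export
footprint <- function(geometry, altitude) {
  if (!is.numeric(altitude) || altitude <= 0)
    stop("altitude must be > 0 meters", call. = FALSE)
  width_m <- 2 * altitude * tan(geometry$horizontal_fov / 2 * pi / 180)
  height_m <- 2 * altitude * tan(geometry$vertical_fov / 2 * pi / 180)
  list(area_square_meter = width_m * height_m,
       pixels_per_meter = geometry$image_width / width_m,
       width_m = width_m, height_m = height_m)
}

#' Overlap fraction of two rectangular footprints
#'
#' Intersection area divided by the smaller footprint's area, for two
#' axis-aligned nadir footprints in a common local meter frame.
#'
#' @param fp_a,fp_b lists with `center` (`c(x, y)` meters), `width_m`,
#'   `height_m`.
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(fp_a, fp_b) {
  ix <- max(0, min(fp_a$center[1] + fp_a$width_m / 2,
                   fp_b$center[1] + fp_b$width_m / 2) -
               max(fp_a$center[1] - fp_a$width_m / 2,
                   fp_b$center[1] - fp_b$width_m / 2))
  iy <- max(0, min(fp_a$center[2] + fp_a$height_m / 2,
                   fp_b$center[2] + fp_b$height_m / 2) -
               max(fp_a$center[2] - fp_a$height_m / 2,
                   fp_b$center[2] - fp_b$height_m / 2))
  inter <- ix * iy
  inter / min(fp_a$width_m * fp_a$height_m, fp_b$width_m * fp_b$height_m)
}

# capture datetime of one image: embedded metadata wins, filename is the
# fallback, a conflict between the two is an error
image_capture_datetime <- function(path) {
  embedded <- NULL
  if (file_format(path) == "png") {
    bytes <- readBin(path, "raw", n = file.size(path))
    embedded <- png_text_read(bytes, "image-datetime")
  }
  m <- regmatches(basename(path),
                  regexec("(\\d{8})[T_](\\d{6}(?:\\.\\d+)?)", basename(path)))[[1]]
  from_name <- if (length(m)) {
    parse_ifdo_datetime(paste0(
      sub("(\\d{4})(\\d{2})(\\d{2})", "\\1-\\2-\\3", m[2]), "T",
      sub("(\\d{2})(\\d{2})(\\d{2}(?:\\.\\d+)?)", "\\1:\\2:\\3", m[3]), "Z"))
  } else NULL
  if (!is.null(embedded)) {
    t_emb <- parse_ifdo_datetime(embedded)
    if (is.na(t_emb))
      stop("unparseable embedded datetime in '", basename(path), "'",
           call. = FALSE)
    if (!is.null(from_name) && !is.na(from_name) &&
        abs(as.numeric(t_emb) - as.numeric(from_name)) > 0.0005)
      stop("embedded and filename datetimes conflict for '",
           basename(path), "'", call. = FALSE)
    return(t_emb)
  }
  if (!is.null(from_name) && !is.na(from_name)) return(from_name)
  stop("no capture datetime for '", basename(path),
       "' (neither embedded metadata nor filename pattern)", call. = FALSE)
}

# factor fields shared (identically) by every item into header defaults
factor_header_defaults <- function(metas) {
  if (length(metas) == 0L)
    return(list(defaults = list(), items = list()))
  shared <- Reduce(intersect, lapply(metas, names))
  defaults <- list()
  for (nm in shared) {
    vals <- lapply(metas, `[[`, nm)
    if (all(vapply(vals[-1], identical, logical(1), vals[[1]])))
      defaults[[nm]] <- vals[[1]]
  }
  items <- lapply(metas, function(m) m[setdiff(names(m), names(defaults))])
  list(defaults = defaults, items = items)
}

#' Assemble an iFDO document from an image directory
#'
#' Runs the full factory pipeline: (1) verify UTC timing of the image
#' capture times; (2) curate the navigation track (outlier rejection, then
#' smoothing); (3) generate one UUID per image and one for the set;
#' (4) mint each UUID into its image file; (5) rename the images to the
#' canonical `<project>_<event>_<sensor>_<date>_<time>` scheme; (6) hash
#' the minted files (SHA-256); (7) interpolate positions to the capture
#' times; (8) derive footprint fields when the camera geometry and altitude
#' are configured; (9) assemble the document, factoring fields shared by
#' all items into the header; (10) validate against the vocabulary.
#'
#' All file work happens in a staging copy; only when every stage has
#' succeeded (and validation is clean, unless `force`) are the curated
#' files written to `out_dir` — partial outputs are never left behind.
#'
#' @param image_dir directory of raw PNG/JPEG images; capture datetimes come
#'   from embedded metadata or a `YYYYMMDD[T_]HHMMSS(.sss)` filename pattern.
#' @param nav an `ifdo_track` (curation is applied here) or path to a
#'   navigation CSV.
#' @param config an `ifdo_config`.
#' @param out_dir directory for the curated (renamed, minted) image files;
#'   defaults to `image_dir` (in-place curation).
#' @param force emit the document even when validation reports errors.
#' @return the validated `ifdo` document, with attribute `validation`.
#' @export
create_ifdo <- function(image_dir, nav, config, out_dir = image_dir,
                        force = FALSE) {
  files <- sort(list.files(image_dir, pattern = "\\.(png|jpe?g)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (is.character(nav)) nav <- load_track(nav)

  if (length(files) > 0L) {
    times <- lapply(files, function(f)
      tryCatch(image_capture_datetime(f), error = function(e) e))
    bad <- vapply(times, inherits, logical(1), "error")
    if (any(bad))
      stop("capture-time errors:\n", paste0("  ", basename(files[bad]), ": ",
           vapply(times[bad], conditionMessage, character(1)),
           collapse = "\n"), call. = FALSE)
    times <- .POSIXct(vapply(times, as.numeric, numeric(1)), tz = "UTC")
    utc <- verify_utc(format_ifdo_datetime(times), max_gap_seconds = Inf)
    if (length(utc$non_utc))
      stop("non-UTC image capture times", call. = FALSE)
    # deterministic processing order: by capture time, then name
    o <- order(as.numeric(times), basename(files), method = "radix")
    files <- files[o]; times <- times[o]
  } else {
    times <- .POSIXct(numeric(0), tz = "UTC")
  }

  track <- smooth_track(remove_outliers(nav, config$nav_window, config$nav_k),
                        config$nav_window)

  set_uuid <- generate_uuid()
  item_uuids <- if (length(files)) generate_uuid(length(files)) else character(0)
  set_handle <- format(build_handle_url(config$handle_server,
                                        config$handle_prefix, set_uuid,
                                        "ifdo"))

  stage <- tempfile("ifdo-stage-")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  pos <- if (length(files))
    interpolate_to(track, times,
                   sensor_uncertainty_meters = config$nav_uncertainty_meters)
  else NULL
  if (!is.null(pos) && any(!pos$ok))
    stop("position errors:\n",
         paste0("  ", basename(files[!pos$ok]), ": ", pos$message[!pos$ok],
                collapse = "\n"), call. = FALSE)

  fp <- if (!is.null(config$camera) && !is.null(config$altitude_meters))
    footprint(config$camera, config$altitude_meters) else NULL

  item_names <- character(length(files))
  metas <- vector("list", length(files))
  errors <- character(0)
  for (i in seq_along(files)) {
    name <- rename_file(config, times[i], basename(files[i]), dir = stage)
    staged <- file.path(stage, name)
    file.copy(files[i], staged)
    res <- tryCatch({
      mint_uuid(staged, item_uuids[i])
      h <- compute_hash(staged)
      meta <- list(
        datetime = format_ifdo_datetime(times[i]),
        latitude = pos$latitude[i], longitude = pos$longitude[i],
        depth = pos$depth[i],
        coordinate_reference_system = config$crs,
        coordinate_uncertainty_meters = pos$uncertainty_meters[i],
        uuid = item_uuids[i], hash_sha256 = h,
        context = config$context, project = config$project,
        event = config$event, platform = config$platform,
        sensor = config$sensor, abstract = config$abstract,
        license = config$license, copyright = config$copyright
      )
      if (!is.null(config$pi)) meta$pi <- config$pi
      if (length(config$creators)) meta$creators <- config$creators
      if (!is.null(fp)) {
        meta$area_square_meter <- fp$area_square_meter
        meta$meters_above_ground <- config$altitude_meters
      }
      for (nm in names(config$capture)) meta[[nm]] <- config$capture[[nm]]
      meta
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, paste0(basename(files[i]), ": ",
                                 conditionMessage(res)))
    } else {
      item_names[i] <- name
      metas[[i]] <- res
    }
  }
  if (length(errors))
    stop("factory stage failures:\n", paste0("  ", errors, collapse = "\n"),
         call. = FALSE)

  fac <- factor_header_defaults(metas)
  items <- fac$items
  names(items) <- item_names
  doc <- ifdo_document(set_name = config$set_name, set_uuid = set_uuid,
                       set_handle = set_handle, defaults = fac$defaults,
                       items = items)
  report <- validate_ifdo(doc)
  if (!report$is_fair && !force)
    stop("refusing to emit iFDO with validation errors (use force = TRUE):\n",
         paste0("  ", report$findings$item[report$findings$severity == "error"],
                " / ", report$findings$field[report$findings$severity == "error"],
                ": ",
                report$findings$message[report$findings$severity == "error"],
                collapse = "\n"),
         call. = FALSE)

  # commit: move curated files out of staging
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (i in seq_along(files)) {
    file.copy(file.path(stage, item_names[i]), file.path(out_dir,
                                                         item_names[i]),
              overwrite = TRUE)
    if (normalizePath(out_dir) == normalizePath(image_dir) &&
        basename(files[i]) != item_names[i])
      unlink(files[i])
  }
  attr(doc, "validation") <- report
  doc
}
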