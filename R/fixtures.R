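# Deterministic synthetic-data generator. Every other module is testable
# against these fixtures without any download: images with a known particle
# count, exact mean colour and histogram; navigation tracks with a known
# ground-truth trajectory, recorded noise level and recorded spike indices;
# and complete factory-ready datasets. Everything regenerates byte-
# identically from (seed, parameters).

#' Generate a synthetic particle image
#'
#' Renders bright disks (the "particles") on a uniform gray background into
#' an 8-bit grayscale PNG. Disks are placed by rejection sampling so they
#' never overlap or touch (8-connectivity-safe: at least one background
#' pixel between disks) and keep clear of the border. The returned ground
#' truth records the particle count, the exact mean intensity and the full
#' histogram of the written pixels. An `image-datetime` text chunk is
#' embedded when a capture time is given.
#'
#' @param path output PNG path.
#' @param seed integer seed; the image is a pure function of
#'   (seed, parameters).
#' @param size `c(width, height)` in pixels.
#' @param particles number of disks, >= 0.
#' @param background background gray level, 0–255.
#' @param disk_value disk gray level, 0–255.
#' @param radius disk radius in pixels.
#' @param datetime optional capture time (POSIXct or ISO 8601 UTC string)
#'   embedded as PNG text metadata.
#' @return list ground truth: `particle_count`, `mean_gray` (0–255 scale),
#'   `mean_colour` (RGB triple), `histogram` (256 counts), `centers`.
#' @export
make_image <- function(path, seed, size = c(256L, 256L), particles = 7L,
                       background = 64L, disk_value = 230L, radius = 5L,
                       datetime = NULL) {
  stopifnot(particles >= 0L)
  img <- withr::with_seed(seed, {
    w <- size[1]; h <- size[2]
    m <- matrix(as.numeric(background), nrow = h, ncol = w)
    centers <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(centers) < particles) {
      tries <- tries + 1L
      if (tries > 1000L * max(particles, 1L))
        stop("cannot place ", particles, " non-overlapping disks in a ",
             w, "x", h, " image", call. = FALSE)
      cx <- sample.int(w - 2L * (radius + 2L), 1L) + radius + 1L
      cy <- sample.int(h - 2L * (radius + 2L), 1L) + radius + 1L
      if (nrow(centers) > 0L &&
          any((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2 <
              (2L * radius + 3L)^2)) next
      centers <- rbind(centers, c(cx, cy))
    }
    for (j in seq_len(nrow(centers))) {
      cx <- centers[j, 1]; cy <- centers[j, 2]
      for (dy in -radius:radius) for (dx in -radius:radius)
        if (dx * dx + dy * dy <= radius * radius)
          m[cy + dy, cx + dx] <- disk_value
    }
    attr(m, "centers") <- centers
    m
  })
  centers <- attr(img, "centers")
  attr(img, "centers") <- NULL
  png::writePNG(img / 255, path)
  if (!is.null(datetime)) {
    if (!is.character(datetime)) datetime <- format_ifdo_datetime(datetime)
    bytes <- readBin(path, "raw", n = file.size(path))
    writeBin(png_text_insert(bytes, "image-datetime", datetime), path)
  }
  list(particle_count = nrow(centers),
       mean_gray = mean(img),
       mean_colour = round(rep(mean(img), 3L), 2),
       histogram = tabulate(as.integer(img) + 1L, nbins = 256L),
       centers = centers)
}

#' Generate a synthetic navigation track
#'
#' Simulates a slow survey transect (about 1 m/s with gentle sinusoidal
#' curvature) in a local meter frame mapped to latitude/longitude, adds
#' zero-mean Gaussian position noise of `noise_sigma` meters and injects
#' horizontal spikes of `spike_magnitude` meters at recorded indices. Spike
#' indices keep a minimum spacing (and distance from the track ends) so a
#' centered running-median window never contains two spikes. Timestamps are
#' strictly increasing UTC at `rate` Hz.
#'
#' @param path output CSV path (columns datetime, latitude, longitude,
#'   depth).
#' @param seed integer seed.
#' @param duration track length in seconds.
#' @param rate sample rate in Hz, > 0.
#' @param noise_sigma Gaussian position noise, meters.
#' @param outliers number of injected spikes.
#' @param spike_magnitude spike displacement in meters.
#' @param start_time first timestamp (ISO 8601 UTC).
#' @param origin `c(latitude, longitude)` of the track origin.
#' @param depth nominal depth in meters.
#' @return list ground truth: `truth` (data frame of noise-free,
#'   spike-free positions), `outlier_indices`, `noise_sigma`,
#'   `spike_magnitude`, `n`.
#' @export
make_track <- function(path, seed, duration = 600, rate = 1,
                       noise_sigma = 1, outliers = 5,
                       spike_magnitude = 100,
                       start_time = "2022-07-15T10:00:00.000Z",
                       origin = c(54.33, 10.18), depth = 2000) {
  if (rate <= 0) stop("sample rate must be > 0", call. = FALSE)
  n <- as.integer(duration * rate)
  t0 <- parse_ifdo_datetime(start_time)
  tt <- t0 + seq_len(n) / rate - 1 / rate
  gt <- withr::with_seed(seed, {
    s <- seq_len(n) / rate              # seconds along track
    x <- s * 1.0                        # ~1 m/s easting
    y <- 10 * sin(s / 1200)             # very gentle curvature
    z <- depth + 5 * sin(s / 90)
    lat <- origin[1] + y / .m_per_deg
    lon <- origin[2] + x / (.m_per_deg * cos(origin[1] * pi / 180))
    nx <- stats::rnorm(n, 0, noise_sigma)
    ny <- stats::rnorm(n, 0, noise_sigma)
    idx <- integer(0)
    if (outliers > 0) {
      min_gap <- 25L
      candidates <- seq(min_gap, n - min_gap)
      for (k in seq_len(outliers)) {
        if (length(candidates) == 0L)
          stop("cannot place ", outliers, " spaced spikes in ", n,
               " samples", call. = FALSE)
        pick <- candidates[sample.int(length(candidates), 1L)]
        idx <- c(idx, pick)
        candidates <- candidates[abs(candidates - pick) >= min_gap]
      }
      idx <- sort(idx)
      ang <- stats::runif(outliers, 0, 2 * pi)
      nx[idx] <- nx[idx] + spike_magnitude * cos(ang)
      ny[idx] <- ny[idx] + spike_magnitude * sin(ang)
    }
    list(lat_true = lat, lon_true = lon, depth_true = z,
         lat = lat + ny / .m_per_deg,
         lon = lon + nx / (.m_per_deg * cos(origin[1] * pi / 180)),
         idx = idx)
  })
  df <- data.frame(datetime = format_ifdo_datetime(tt),
                   latitude = sprintf("%.10f", gt$lat),
                   longitude = sprintf("%.10f", gt$lon),
                   depth = sprintf("%.3f", gt$depth_true))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  list(truth = data.frame(datetime = tt, latitude = gt$lat_true,
                          longitude = gt$lon_true, depth = gt$depth_true),
       outlier_indices = gt$idx, noise_sigma = noise_sigma,
       spike_magnitude = spike_magnitude, n = n)
}

#' Generate a complete factory-ready dataset
#'
#' Creates a directory holding raw images (with embedded capture times
#' lying inside the track's span), a navigation CSV and a project
#' configuration YAML, together with a manifest of all ground truth. The
#' result feeds [create_ifdo()] end to end.
#'
#' @param dir output directory (created; must not already contain a
#'   dataset).
#' @param seed integer seed.
#' @param n_images number of images, >= 0.
#' @param noise_sigma,outliers passed to [make_track()].
#' @return the manifest: list with `seed`, `images` (per-image ground truth
#'   incl. capture datetime), `track` ground truth, `config` and `paths`.
#' @export
make_dataset <- function(dir, seed, n_images = 20L, noise_sigma = 1,
                         outliers = 5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  duration <- 600
  track_gt <- make_track(file.path(dir, "nav.csv"), seed = seed,
                         duration = duration, noise_sigma = noise_sigma,
                         outliers = outliers)
  t0 <- track_gt$truth$datetime[1]
  images <- list()
  if (n_images > 0L) {
    # capture times strictly inside the track span, evenly spread
    offsets <- round(seq(30, duration - 30, length.out = n_images), 1)
    counts <- withr::with_seed(seed + 1L,
                               sample(0:10, n_images, replace = TRUE))
    for (i in seq_len(n_images)) {
      dt <- t0 + offsets[i]
      fname <- sprintf("raw_%03d.png", i)
      gt <- make_image(file.path(img_dir, fname), seed = seed + 100L + i,
                       particles = counts[i], datetime = dt)
      gt$datetime <- format_ifdo_datetime(dt)
      gt$file <- fname
      images[[i]] <- gt
    }
  }
  config <- ifdo_config(
    project = "SOX", event = "SOX-1_001", platform = "OFOS", sensor = "CAM-1",
    context = "synthetic seafloor survey",
    abstract = "Synthetic image set generated for pipeline testing.",
    pi = list(name = "Josiah Carberry", orcid = "0000-0002-1825-0097"),
    creators = list(list(name = "Josiah Carberry",
                         orcid = "0000-0002-1825-0097")),
    license = "CC-BY-4.0", copyright = "(c) 2022 synthetic",
    camera = camera_geometry(90, 70, 256, 256),
    altitude_meters = 2,
    capture = list(acquisition = "photo", deployment = "survey",
                   illumination = "artificial light", capture_mode = "timer",
                   objective = "synthetic test coverage",
                   target_environment = "abyssal plain (synthetic)")
  )
  cfg_out <- list(
    project = config$project, event = config$event,
    platform = config$platform, sensor = config$sensor,
    context = config$context, abstract = config$abstract,
    pi = config$pi, creators = config$creators,
    license = config$license, copyright = config$copyright,
    camera = list(horizontal_fov = 90, vertical_fov = 70,
                  image_width = 256, image_height = 256),
    altitude_meters = 2,
    capture = config$capture
  )
  yaml::write_yaml(cfg_out, file.path(dir, "config.yaml"))
  manifest <- list(seed = seed, images = images, track = track_gt,
                   config = config,
                   paths = list(images = img_dir,
                                nav = file.path(dir, "nav.csv"),
                                config = file.path(dir, "config.yaml")))
  manifest
}
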