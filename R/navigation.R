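# Navigation track curation. Raw underwater position data (ship GPS, USBL,
# dead reckoning) is noisy and carries spikes; before positions are attached
# to image capture times the track is cleaned with a robust running-median /
# MAD outlier rejection and a centered moving-average smoother, then
# interpolated linearly to the image timestamps.
#
# Horizontal distances use a local equirectangular approximation, which is
# accurate at marine survey scales (meters to kilometers) and degrades only
# very close to the poles.

.earth_radius_m <- 6371008.8
.m_per_deg <- pi / 180 * .earth_radius_m

# local meter frame around a reference latitude
track_local_xy <- function(lat, lon, lat_ref = stats::median(lat)) {
  list(x = lon * .m_per_deg * cos(lat_ref * pi / 180),
       y = lat * .m_per_deg)
}

new_track <- function(df) {
  stopifnot(all(c("datetime", "latitude", "longitude", "depth") %in%
                names(df)))
  if (is.null(df$flags)) df$flags <- ""
  rownames(df) <- NULL
  structure(df, class = c("ifdo_track", "data.frame"))
}

#' @export
print.ifdo_track <- function(x, ...) {
  cat("navigation track:", nrow(x), "samples,",
      format(min(x$datetime)), "UTC to", format(max(x$datetime)), "UTC\n")
  flagged <- sum(nzchar(x$flags))
  if (flagged) cat("  flagged samples:", flagged, "\n")
  invisible(x)
}

#' Load a navigation track from CSV
#'
#' Reads a timestamped position table with columns `datetime`, `latitude`,
#' `longitude`, `depth` (optional `uncertainty_meters`). Datetimes must be
#' ISO 8601 in UTC; an explicit non-UTC offset is rejected. Rows are sorted
#' by time (flagged when re-ordering was needed) and rows sharing a
#' timestamp are collapsed to their mean position (flagged).
#'
#' @param path CSV file path.
#' @return object of class `ifdo_track` (a data frame with POSIXct
#'   `datetime`, numeric `latitude`, `longitude`, `depth`, character
#'   `flags`, plus attribute `raw_datetime` holding the lexical timestamps).
#' @export
load_track <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("datetime", "latitude", "longitude", "depth")
  if (!all(need %in% names(df)))
    stop("navigation CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  offs <- grepl("[+-]\\d{2}:?\\d{2}$", df$datetime) &
    !grepl("\\+00:?00$", df$datetime)
  if (any(offs))
    stop("non-UTC timestamp at row ", which(offs)[1], ": '",
         df$datetime[which(offs)[1]], "' (tracks must be UTC)",
         call. = FALSE)
  t <- parse_ifdo_datetime(df$datetime)
  if (anyNA(t))
    stop("unparseable datetime at row ", which(is.na(t))[1], ": '",
         df$datetime[which(is.na(t))[1]], "'", call. = FALSE)
  df$flags <- ""
  out <- data.frame(datetime = t, latitude = df$latitude,
                    longitude = df$longitude, depth = df$depth,
                    flags = df$flags, stringsAsFactors = FALSE)
  raw_dt <- df$datetime
  if (is.unsorted(t)) {
    o <- order(t)
    out <- out[o, ]
    raw_dt <- raw_dt[o]
    out$flags <- paste0(out$flags, "reordered;")
  }
  if (anyDuplicated(out$datetime)) {
    agg <- stats::aggregate(out[c("latitude", "longitude", "depth")],
                            by = list(datetime = out$datetime), FUN = mean)
    agg <- agg[order(agg$datetime), ]
    dup_times <- unique(out$datetime[duplicated(out$datetime)])
    agg$flags <- ifelse(agg$datetime %in% dup_times,
                        "duplicate-collapsed;", "")
    raw_dt <- raw_dt[!duplicated(out$datetime)]
    out <- agg[c("datetime", "latitude", "longitude", "depth", "flags")]
  }
  tr <- new_track(out)
  attr(tr, "raw_datetime") <- raw_dt
  tr
}

#' Verify UTC timing of a track or timestamp list
#'
#' Flags timestamps lacking an explicit UTC designator (`Z` or `+00:00`),
#' non-monotone sequences and gaps larger than a threshold. For a track
#' loaded with [load_track()] the lexical timestamps are taken from its
#' `raw_datetime` attribute.
#'
#' @param x an `ifdo_track` or a character vector of timestamps.
#' @param max_gap_seconds gap threshold in seconds.
#' @return list with `clean` (logical), `naive` (indices without UTC
#'   designator), `non_utc` (indices with a non-UTC offset), `non_monotone`
#'   (indices where time steps backwards) and `gaps` (data frame of gaps
#'   exceeding the threshold).
#' @export
verify_utc <- function(x, max_gap_seconds = 10) {
  if (inherits(x, "ifdo_track")) {
    stamps <- attr(x, "raw_datetime") %||% format_ifdo_datetime(x$datetime)
  } else stamps <- x
  has_desig <- grepl("(Z|\\+00:?00)$", stamps)
  has_off <- grepl("[+-]\\d{2}:?\\d{2}$", stamps) &
    !grepl("\\+00:?00$", stamps)
  t <- parse_ifdo_datetime(stamps)
  dt <- diff(as.numeric(t))
  non_monotone <- which(dt < 0) + 1L
  gap_idx <- which(dt > max_gap_seconds)
  gaps <- data.frame(after = gap_idx, seconds = dt[gap_idx])
  res <- list(
    clean = all(has_desig) && !any(has_off) && length(non_monotone) == 0L &&
      nrow(gaps) == 0L,
    naive = which(!has_desig & !has_off),
    non_utc = which(has_off),
    non_monotone = non_monotone,
    gaps = gaps
  )
  res
}

# Hampel-style screen in up to two dimensions: for each sample, distances of
# all window members to the window's running-median point; the sample is an
# outlier when its own distance exceeds k times the MAD of those distances
# (floored to avoid zero-division on static tracks). The MAD then reflects
# the platform's motion within the window, so samples neighbouring a spike
# are not dragged over the threshold by the small median shift the spike
# causes.
hampel_flags <- function(x, y, window, k, floor_) {
  n <- length(x)
  half <- window %/% 2L
  medx <- stats::runmed(x, window, endrule = "median")
  medy <- if (is.null(y)) NULL else stats::runmed(y, window,
                                                  endrule = "median")
  flag <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    dj <- if (is.null(y)) abs(x[lo:hi] - medx[i])
          else sqrt((x[lo:hi] - medx[i])^2 + (y[lo:hi] - medy[i])^2)
    scale_ <- max(stats::mad(dj), floor_)
    di <- dj[i - lo + 1L]
    flag[i] <- di > k * scale_
  }
  flag
}

#' Remove position spikes from a navigation track
#'
#' A sample is an outlier when its horizontal distance to the running median
#' track (centered window) exceeds `k` times the median absolute deviation
#' of those distances within the window. The MAD is floored at 1 cm so that
#' perfectly static tracks do not divide by zero. Depth is screened the same
#' way, independently. Outliers are removed; the removed indices are
#' recorded in the `removed` attribute of the result.
#'
#' If more than half the samples would be removed the track is returned
#' unchanged with a warning — wholesale deletion is never silent. Tracks
#' shorter than the window are returned unchanged with a warning.
#'
#' @param track an `ifdo_track`.
#' @param window centered window size in samples; odd, >= 3.
#' @param k MAD multiplier.
#' @return curated `ifdo_track` with attribute `removed` (integer indices
#'   into the input track).
#' @export
remove_outliers <- function(track, window = 11L, k = 5) {
  stopifnot(window >= 3L, window %% 2L == 1L, k > 0)
  n <- nrow(track)
  if (n < window) {
    warning("track shorter than window (", n, " < ", window,
            "); returned unchanged", call. = FALSE)
    attr(track, "removed") <- integer(0)
    return(track)
  }
  xy <- track_local_xy(track$latitude, track$longitude)
  out_h <- hampel_flags(xy$x, xy$y, window, k, 0.01)
  out_v <- hampel_flags(track$depth, NULL, window, k, 0.01)
  bad <- which(out_h | out_v)
  if (length(bad) > n / 2) {
    warning("outlier screen would remove ", length(bad), " of ", n,
            " samples (> 50%); track returned unchanged", call. = FALSE)
    attr(track, "removed") <- integer(0)
    return(track)
  }
  out <- track
  if (length(bad)) {
    out <- new_track(as.data.frame(track)[-bad, , drop = FALSE])
    rdt <- attr(track, "raw_datetime")
    if (!is.null(rdt)) attr(out, "raw_datetime") <- rdt[-bad]
  }
  attr(out, "removed") <- bad
  out
}

#' Smooth a navigation track with a centered moving average
#'
#' Applies a centered moving average per coordinate (latitude, longitude,
#' depth). Near the track ends the largest available symmetric window is
#' used, so the first and last samples pass through unchanged. Outliers
#' should be removed first — a moving average smears spikes instead of
#' rejecting them.
#'
#' @param track an `ifdo_track`.
#' @param window window size in samples; odd.
#' @return smoothed `ifdo_track`.
#' @export
smooth_track <- function(track, window = 11L) {
  stopifnot(window >= 3L, window %% 2L == 1L)
  n <- nrow(track)
  if (n < window) {
    warning("track shorter than window (", n, " < ", window,
            "); returned unchanged", call. = FALSE)
    return(track)
  }
  half <- window %/% 2L
  sm <- function(v) {
    out <- v
    for (i in seq_len(n)) {
      h <- min(half, i - 1L, n - i)
      out[i] <- mean(v[(i - h):(i + h)])
    }
    out
  }
  out <- track
  lon_u <- unwrap_longitude(track$longitude)
  out$latitude <- sm(track$latitude)
  out$longitude <- wrap_longitude(sm(lon_u))
  out$depth <- sm(track$depth)
  out
}

# unwrap longitudes so consecutive differences are <= 180 degrees
unwrap_longitude <- function(lon) {
  if (length(lon) < 2L) return(lon)
  d <- diff(lon)
  adj <- cumsum(c(0, ifelse(d > 180, -360, ifelse(d < -180, 360, 0))))
  lon + adj
}

wrap_longitude <- function(lon) ((lon + 180) %% 360) - 180

#' Interpolate a track to image capture times
#'
#' Piecewise-linear interpolation, independently per coordinate (longitudes
#' are unwrapped across the antimeridian first), exact at the track's own
#' sample times. The reported position uncertainty is the configured sensor
#' uncertainty plus half the horizontal displacement of the bracketing
#' sample pair — the position can be anywhere along that segment.
#' Timestamps outside the track's span by more than `tolerance_seconds` get
#' a per-timestamp error entry; within the tolerance the nearest endpoint
#' position is used.
#'
#' @param track an `ifdo_track` (curated).
#' @param timestamps POSIXct vector or ISO 8601 UTC strings.
#' @param sensor_uncertainty_meters base uncertainty of the positioning
#'   sensor, added to every estimate.
#' @param tolerance_seconds extrapolation tolerance beyond the track span.
#' @return data frame with `latitude`, `longitude`, `depth`,
#'   `uncertainty_meters`, `ok` (logical) and `message`.
#' @export
interpolate_to <- function(track, timestamps,
                           sensor_uncertainty_meters = 0,
                           tolerance_seconds = 5) {
  if (is.character(timestamps)) timestamps <- parse_ifdo_datetime(timestamps)
  tq <- as.numeric(timestamps)
  tt <- as.numeric(track$datetime)
  n <- length(tq)
  out <- data.frame(latitude = rep(NA_real_, n), longitude = NA_real_,
                    depth = NA_real_, uncertainty_meters = NA_real_,
                    ok = FALSE, message = "", stringsAsFactors = FALSE)
  lon_u <- unwrap_longitude(track$longitude)
  xy <- track_local_xy(track$latitude, track$longitude)
  seg_disp <- sqrt(diff(xy$x)^2 + diff(xy$y)^2)
  for (i in seq_len(n)) {
    q <- tq[i]
    if (is.na(q)) { out$message[i] <- "unparseable timestamp"; next }
    if (q < tt[1] - tolerance_seconds || q > tt[length(tt)] + tolerance_seconds) {
      out$message[i] <- sprintf(
        "timestamp outside track span by %.1f s (tolerance %g s)",
        max(tt[1] - q, q - tt[length(tt)]), tolerance_seconds)
      next
    }
    qc <- min(max(q, tt[1]), tt[length(tt)])
    j <- findInterval(qc, tt, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(tt) - 1L)
    w <- if (tt[j + 1] == tt[j]) 0 else (qc - tt[j]) / (tt[j + 1] - tt[j])
    out$latitude[i] <- track$latitude[j] * (1 - w) + track$latitude[j + 1] * w
    out$longitude[i] <- wrap_longitude(lon_u[j] * (1 - w) + lon_u[j + 1] * w)
    out$depth[i] <- track$depth[j] * (1 - w) + track$depth[j + 1] * w
    out$uncertainty_meters[i] <- sensor_uncertainty_meters + seg_disp[j] / 2
    out$ok[i] <- TRUE
  }
  out
}
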