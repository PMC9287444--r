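# iFDO document model: one header (set-level fields + defaults for all items)
# plus a map of item records. A photo item is a single metadata object; a
# video item is a list whose first entry holds video-wide defaults and whose
# subsequent entries override them per timepoint.

#' Construct an iFDO document
#'
#' An iFDO bundles all metadata of one image set: a header carrying the three
#' set-level identity fields plus default values for every item, and an
#' ordered map of per-image (or per-video) item records that supersede those
#' defaults field by field.
#'
#' @param set_name free-text name of the image set.
#' @param set_uuid version-4 UUID identifying the set.
#' @param set_handle absolute handle URL resolving to this metadata record.
#' @param defaults named list of item-level fields (in-memory names, e.g.
#'   `sensor`, `license`) used as defaults for all items.
#' @param items named list of item records. A photo record is a named list of
#'   fields; a video record is an unnamed list of named lists (entry 1 =
#'   video-wide defaults, entries 2..n = per-timepoint overrides).
#' @param format_version version of the iFDO vocabulary the document follows.
#' @return an object of class `ifdo`.
#' @export
#' @examples
#' doc <- ifdo_document("demo set", generate_uuid(),
#'                      "https://hdl.handle.net/20.500.12085/x",
#'                      defaults = list(sensor = "camA"))
ifdo_document <- function(set_name, set_uuid, set_handle,
                          defaults = list(), items = list(),
                          format_version = "1.0.0") {
  doc <- structure(list(
    header = list(set_name = set_name, set_uuid = set_uuid,
                  set_handle = set_handle,
                  format_version = format_version,
                  defaults = defaults),
    items = items
  ), class = "ifdo")
  doc
}

is_video_record <- function(item) {
  is.list(item) && length(item) > 0L && is.null(names(item))
}

#' @export
print.ifdo <- function(x, ...) {
  cat("iFDO document\n")
  cat("  set name  :", x$header$set_name, "\n")
  cat("  set uuid  :", x$header$set_uuid, "\n")
  cat("  set handle:", x$header$set_handle, "\n")
  cat("  version   :", x$header$format_version, "\n")
  cat("  defaults  :", length(x$header$defaults), "field(s)\n")
  nvid <- sum(vapply(x$items, is_video_record, logical(1)))
  cat("  items     :", length(x$items), "record(s),", nvid, "video\n")
  invisible(x)
}

# ---- structural invariants ------------------------------------------------

check_ifdo <- function(doc) {
  h <- doc$header
  if (is.null(h$set_name) || !nzchar(h$set_name))
    stop("iFDO invariant violated: header field 'image-set-name' is missing",
         call. = FALSE)
  if (is.null(h$set_uuid) || !is_uuid4(h$set_uuid))
    stop("iFDO invariant violated: 'image-set-uuid' is not a valid version-4 UUID",
         call. = FALSE)
  if (is.null(h$set_handle) || !is_absolute_url(h$set_handle))
    stop("iFDO invariant violated: 'image-set-handle' is not an absolute URL",
         call. = FALSE)
  nm <- names(doc$items)
  if (length(doc$items) > 0L && (is.null(nm) || anyDuplicated(nm) ||
                                 any(!nzchar(nm))))
    stop("iFDO invariant violated: item names must be unique and non-empty",
         call. = FALSE)
  for (item_name in nm) {
    item <- doc$items[[item_name]]
    entries <- if (is_video_record(item)) item else list(item)
    for (e in entries) {
      bad <- intersect(names(e), c(.ifdo_set_fields, names(.ifdo_set_fields)))
      if (length(bad))
        stop("iFDO invariant violated: set-level field '", bad[1],
             "' inside item '", item_name, "'", call. = FALSE)
    }
    if (is_video_record(item) && length(item) > 1L) {
      dts <- vapply(item[-1], function(e)
        if (is.null(e$datetime)) NA_character_ else e$datetime, character(1))
      if (anyNA(dts))
        stop("iFDO invariant violated: video timepoint entry without ",
             "'image-datetime' in item '", item_name, "'", call. = FALSE)
      tt <- parse_ifdo_datetime(dts)
      if (anyNA(tt) || is.unsorted(tt))
        stop("iFDO invariant violated: video timepoint datetimes must be ",
             "valid and non-decreasing in item '", item_name, "'",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

is_absolute_url <- function(x) {
  is.character(x) && length(x) == 1L && grepl("^[A-Za-z][A-Za-z0-9+.-]*://.+", x)
}

#' Parse/format iFDO datetimes
#'
#' iFDO datetimes are ISO 8601 UTC strings, `YYYY-MM-DDTHH:MM:SS.sssZ`.
#'
#' @param x character vector of datetime strings.
#' @return `parse_ifdo_datetime`: POSIXct (UTC), NA where unparseable.
#' @keywords internal
parse_ifdo_datetime <- function(x) {
  x2 <- sub("Z$", "", sub("\\+00:00$", "", x))
  out <- as.POSIXct(x2, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS"),
                    optional = TRUE)
  out
}

#' @rdname parse_ifdo_datetime
#' @param t POSIXct vector.
#' @return `format_ifdo_datetime`: character in canonical lexical form.
#' @keywords internal
format_ifdo_datetime <- function(t) {
  ms <- round(as.numeric(t) * 1000)
  base <- strftime(.POSIXct(floor(ms / 1000), tz = "UTC"),
                   "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  paste0(base, sprintf(".%03dZ", as.integer(ms %% 1000)))
}

# ---- parsing --------------------------------------------------------------

map_keys_in <- function(x) {
  if (is.null(x) || length(x) == 0L) return(list())
  out <- as.list(x)
  names(out) <- ifdo_field_name(names(out))
  out
}

#' Parse an iFDO YAML document
#'
#' Reads the two-part iFDO structure (`image-set-header`, `image-set-items`)
#' into an [ifdo_document()]. Hyphenated file keys become underscored
#' in-memory names; unknown keys are preserved verbatim so that arbitrary
#' extension metadata survives a round trip. A photo item given as a
#' one-element list is normalized to a single metadata object.
#'
#' @param text a single string of YAML, or a character vector of lines.
#' @return an object of class `ifdo`.
#' @seealso [read_ifdo()], [write_ifdo()]
#' @export
parse_ifdo <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  raw <- tryCatch(yaml::yaml.load(text),
                  error = function(e)
                    stop("iFDO parse error: ", conditionMessage(e),
                         call. = FALSE))
  if (!is.list(raw) || !all(c("image-set-header", "image-set-items") %in%
                            c(names(raw))))
    stop("iFDO structure error: top-level keys 'image-set-header' and ",
         "'image-set-items' are both required", call. = FALSE)
  hr <- raw[["image-set-header"]]
  if (!is.list(hr) || is.null(names(hr)))
    stop("iFDO structure error: 'image-set-header' must be a mapping",
         call. = FALSE)
  setk <- .ifdo_set_fields
  header_rest <- hr[setdiff(names(hr), setk)]
  defaults <- map_keys_in(header_rest)
  items_raw <- raw[["image-set-items"]]
  items <- list()
  if (!is.null(items_raw) && length(items_raw) > 0L) {
    if (is.null(names(items_raw)))
      stop("iFDO structure error: 'image-set-items' must be a mapping",
           call. = FALSE)
    items <- lapply(items_raw, function(v) {
      if (is.list(v) && is.null(names(v))) {
        entries <- lapply(v, map_keys_in)
        if (length(entries) == 1L) entries[[1]] else entries
      } else {
        map_keys_in(v)
      }
    })
  }
  ifdo_document(
    set_name = hr[[setk[["set_name"]]]],
    set_uuid = hr[[setk[["set_uuid"]]]],
    set_handle = hr[[setk[["set_handle"]]]],
    defaults = defaults,
    items = items,
    format_version = hr[[setk[["format_version"]]]] %||% "1.0.0"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an iFDO file
#'
#' @param path path to a UTF-8 YAML iFDO file.
#' @return an object of class `ifdo`.
#' @export
read_ifdo <- function(path) {
  parse_ifdo(readChar(path, file.size(path), useBytes = TRUE))
}

# ---- serialization --------------------------------------------------------

map_keys_out <- function(fields) {
  if (length(fields) == 0L) return(structure(list(), names = character(0)))
  keys <- ifdo_field_key(names(fields))
  out <- fields[order(keys, method = "radix")]
  names(out) <- sort(keys, method = "radix")
  out
}

#' Serialize an iFDO document to YAML
#'
#' Emits UTF-8 YAML with two-space indentation and canonical key order: the
#' set-level fields first, remaining header defaults and per-item fields
#' alphabetically by file key, items alphabetically by name. Output is
#' stable: serializing the same document twice yields identical bytes.
#' Documents violating a structural invariant are refused with the violated
#' invariant named.
#'
#' @param doc an `ifdo` object.
#' @param path optional path; when given the YAML is also written there.
#' @return the YAML text, invisibly when `path` is given.
#' @export
write_ifdo <- function(doc, path = NULL) {
  check_ifdo(doc)
  h <- doc$header
  header_out <- c(
    list(`image-set-name` = h$set_name,
         `image-set-uuid` = h$set_uuid,
         `image-set-handle` = h$set_handle,
         `image-set-ifdo-version` = h$format_version),
    map_keys_out(h$defaults)
  )
  items <- doc$items
  if (length(items) > 0L) items <- items[order(names(items), method = "radix")]
  items_out <- lapply(items, function(item) {
    if (is_video_record(item)) lapply(item, map_keys_out)
    else map_keys_out(item)
  })
  txt <- yaml::as.yaml(
    list(`image-set-header` = header_out, `image-set-items` = items_out),
    indent = 2, precision = 15L, indent.mapping.sequence = TRUE
  )
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(txt)), con)
    return(invisible(txt))
  }
  txt
}

# ---- semantic equality ----------------------------------------------------

sort_named_recursive <- function(x) {
  if (!is.list(x)) return(x)
  if (!is.null(names(x)) && length(x))
    x <- x[order(names(x), method = "radix")]
  lapply(x, sort_named_recursive)
}

#' Semantic equality of two iFDO documents
#'
#' Two documents are semantically identical when they carry the same fields
#' with the same values, regardless of field order. This is the identity
#' the round trip [parse_ifdo()] / [write_ifdo()] preserves.
#'
#' @param a,b `ifdo` objects.
#' @return TRUE or FALSE.
#' @export
ifdo_equal <- function(a, b) {
  isTRUE(all.equal(sort_named_recursive(unclass(a)),
                   sort_named_recursive(unclass(b)),
                   check.attributes = FALSE, tolerance = 1e-12))
}

# ---- default resolution ---------------------------------------------------

overlay_fields <- function(base, ...) {
  for (layer in list(...)) {
    for (nm in names(layer)) base[[nm]] <- layer[[nm]]
  }
  base
}

#' Resolve an item against the header defaults
#'
#' Returns the complete metadata of one item: the header defaults overlaid
#' by the item's own values, the item winning field by field. For a video
#' record only the video-wide defaults (entry 1) are applied; use
#' [resolve_timepoint()] for individual timepoints. The three set-level
#' identity fields are never copied into the result.
#'
#' @param doc an `ifdo` object.
#' @param item_name name of the item to resolve.
#' @return named list of resolved fields (in-memory names).
#' @export
resolve_item <- function(doc, item_name) {
  if (!item_name %in% names(doc$items))
    stop("unknown item: '", item_name, "'", call. = FALSE)
  item <- doc$items[[item_name]]
  top <- if (is_video_record(item)) item[[1L]] else item
  overlay_fields(doc$header$defaults, top)
}

#' Resolve one video timepoint
#'
#' Layers header defaults, the video-wide defaults (entry 1 of the record)
#' and the requested timepoint entry, later layers winning field by field.
#' Timepoints are numbered 1..n over the entries after the defaults entry.
#'
#' @param doc an `ifdo` object.
#' @param item_name name of a video item.
#' @param index timepoint number, 1-based; 0 (the defaults entry) is refused.
#' @return named list of resolved fields.
#' @export
resolve_timepoint <- function(doc, item_name, index) {
  if (!item_name %in% names(doc$items))
    stop("unknown item: '", item_name, "'", call. = FALSE)
  item <- doc$items[[item_name]]
  if (!is_video_record(item))
    stop("item '", item_name, "' is not a video record", call. = FALSE)
  if (index == 0L)
    stop("timepoint index 0 is the video defaults entry, not a timepoint",
         call. = FALSE)
  n <- length(item) - 1L
  if (index < 1L || index > n)
    stop("timepoint index ", index, " out of range (video has ", n,
         " timepoints)", call. = FALSE)
  overlay_fields(doc$header$defaults, item[[1L]], item[[index + 1L]])
}
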