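# Persistent identification and integrity. UUIDs are drawn from R's RNG so
# that document creation is reproducible under set.seed(); the UUID must be
# minted into the image file *before* the SHA-256 hash is computed, because
# the hash fingerprints the final byte content.

#' Generate random version-4 UUIDs
#'
#' Draws 16 random bytes per UUID from R's random number stream (hence
#' reproducible under [set.seed()]) and forces the RFC 4122 version nibble
#' (4) and variant bits (10). The space of version-4 UUIDs holds 2^122
#' (about 5e36) values, which makes collisions practically impossible.
#'
#' @param n number of UUIDs to generate.
#' @return character vector of canonical lowercase 36-character UUIDs.
#' @export
#' @examples
#' set.seed(1); generate_uuid(2)
generate_uuid <- function(n = 1L) {
  vapply(seq_len(n), function(i) {
    b <- sample.int(256L, 16L, replace = TRUE) - 1L
    b[7L] <- bitwOr(bitwAnd(b[7L], 0x0FL), 0x40L)  # version = 4
    b[9L] <- bitwOr(bitwAnd(b[9L], 0x3FL), 0x80L)  # variant = 10xx
    hx <- paste(sprintf("%02x", b), collapse = "")
    paste(substring(hx, c(1, 9, 13, 17, 21), c(8, 12, 16, 20, 32)),
          collapse = "-")
  }, character(1))
}

#' Test for a canonical version-4 UUID
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_uuid4 <- function(x) {
  is.character(x) &
    grepl("^[0-9a-f]{8}-[0-9a-f]{4}-4[0-9a-f]{3}-[89ab][0-9a-f]{3}-[0-9a-f]{12}$",
          x)
}

#' Test for a SHA-256 hex digest
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_sha256 <- function(x) {
  is.character(x) & grepl("^[0-9a-f]{64}$", x)
}

# ---- handle URLs ----------------------------------------------------------

#' Build a handle URL for an image or image set
#'
#' Handle URLs are `<server>/<prefix>/<uuid>`, suffixed `@ifdo` when they
#' resolve to the metadata record; the data view (the image bytes) renders
#' without a suffix.
#'
#' @param server handle resolver base URL (e.g. `"https://hdl.handle.net"`).
#' @param prefix handle prefix (e.g. `"20.500.12085"`).
#' @param uuid a version-4 UUID.
#' @param view `"ifdo"` (metadata view) or `"data"`.
#' @return object of class `handle_url` (renders via `format()`/`print()`).
#' @export
#' @examples
#' h <- build_handle_url("https://hdl.handle.net", "20.500.12085",
#'                       "9a1f8a29-2552-4c11-895b-051f7424d2d2", "ifdo")
#' format(h)
build_handle_url <- function(server, prefix, uuid, view = c("ifdo", "data")) {
  view <- match.arg(view)
  if (!nzchar(prefix)) stop("handle prefix must be non-empty", call. = FALSE)
  if (!is_uuid4(uuid)) stop("invalid version-4 UUID: ", uuid, call. = FALSE)
  structure(list(server = sub("/+$", "", server), prefix = prefix,
                 uuid = uuid, view = view),
            class = "handle_url")
}

#' @export
format.handle_url <- function(x, ...) {
  paste0(x$server, "/", x$prefix, "/", x$uuid,
         if (x$view == "ifdo") "@ifdo" else "")
}

#' @export
print.handle_url <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a rendered handle URL
#'
#' Inverse of [build_handle_url()]: recovers server, prefix, UUID and view.
#'
#' @param url a rendered handle URL string.
#' @return object of class `handle_url`.
#' @export
parse_handle_url <- function(url) {
  m <- regexec(paste0("^(.*)/([^/]+)/([0-9a-f-]{36})(@ifdo|@data)?$"), url)
  g <- regmatches(url, m)[[1]]
  if (length(g) == 0L || !is_uuid4(g[4]))
    stop("not a handle URL with a version-4 UUID: ", url, call. = FALSE)
  build_handle_url(g[2], g[3], g[4],
                   view = if (identical(g[5], "@ifdo")) "ifdo" else "data")
}

# ---- hashing --------------------------------------------------------------

#' SHA-256 hash of a file
#'
#' Streams the exact byte content of the file through SHA-256 (no whole-file
#' memory requirement). The digest fingerprints the file: any byte change,
#' including a re-minted UUID, changes the hash.
#'
#' @param path file path.
#' @return 64-character lowercase hex digest.
#' @export
compute_hash <- function(path) {
  if (!file.exists(path)) stop("cannot hash, no such file: ", path,
                               call. = FALSE)
  digest::digest(file = path, algo = "sha256")
}

# ---- PNG chunk plumbing ---------------------------------------------------

.png_sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))

u32be <- function(x) {
  as.raw(c(x %/% 16777216L, (x %/% 65536L) %% 256L,
           (x %/% 256L) %% 256L, x %% 256L))
}

read_u32be <- function(b) {
  sum(as.integer(b) * c(16777216, 65536, 256, 1))
}

png_chunks <- function(bytes) {
  if (length(bytes) < 8L || !identical(bytes[1:8], .png_sig))
    stop("not a PNG file", call. = FALSE)
  pos <- 9L
  chunks <- list()
  while (pos + 7L <= length(bytes)) {
    len <- read_u32be(bytes[pos:(pos + 3L)])
    type <- rawToChar(bytes[(pos + 4L):(pos + 7L)])
    data <- if (len > 0) bytes[(pos + 8L):(pos + 7L + len)] else raw(0)
    chunks[[length(chunks) + 1L]] <- list(type = type, data = data)
    pos <- pos + 12L + len
  }
  chunks
}

png_build_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc_hex <- digest::digest(body, algo = "crc32", serialize = FALSE)
  crc <- as.raw(strtoi(substring(formatC(crc_hex, width = 8, flag = "0"),
                                 c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L))
  c(u32be(length(data)), body, crc)
}

# read value of a tEXt chunk by keyword, NULL if absent
png_text_read <- function(bytes, keyword) {
  for (ch in png_chunks(bytes)) {
    if (ch$type != "tEXt") next
    nul <- which(ch$data == as.raw(0))[1]
    if (is.na(nul)) next
    kw <- rawToChar(ch$data[seq_len(nul - 1L)])
    if (kw == keyword)
      return(rawToChar(ch$data[seq(nul + 1L, length(ch$data))]))
  }
  NULL
}

# insert a tEXt chunk immediately after IHDR (deterministic position)
png_text_insert <- function(bytes, keyword, value) {
  ihdr_end <- 8L + 12L + read_u32be(bytes[9:12])
  chunk <- png_build_chunk("tEXt",
                           c(charToRaw(keyword), as.raw(0), charToRaw(value)))
  c(bytes[1:ihdr_end], chunk, bytes[seq(ihdr_end + 1L, length(bytes))])
}

# ---- JPEG EXIF plumbing ---------------------------------------------------

# Minimal EXIF APP1 segment: little-endian TIFF, IFD0 with one entry
# pointing to the Exif IFD, which holds ImageUniqueID (0xA420, ASCII,
# 32 hex chars + NUL, hyphen-stripped per EXIF convention).
jpeg_build_exif_uuid <- function(uuid) {
  hex32 <- gsub("-", "", uuid, fixed = TRUE)
  u16le <- function(x) as.raw(c(x %% 256L, x %/% 256L))
  u32le <- function(x) as.raw(c(x %% 256L, (x %/% 256L) %% 256L,
                                (x %/% 65536L) %% 256L, x %/% 16777216L))
  # offsets are from the start of the TIFF header
  # TIFF header (8) | IFD0: count(2) + 1 entry(12) + next(4) = 18 -> ExifIFD at 26
  # ExifIFD: count(2) + 1 entry(12) + next(4) = 18 -> value at 44
  tiff <- c(
    charToRaw("II"), u16le(42L), u32le(8L),
    u16le(1L),                                    # IFD0: one entry
    u16le(0x8769L), u16le(4L), u32le(1L), u32le(26L),
    u32le(0L),                                    # no next IFD
    u16le(1L),                                    # Exif IFD: one entry
    u16le(0xA420L), u16le(2L), u32le(33L), u32le(44L),
    u32le(0L),
    charToRaw(hex32), as.raw(0)
  )
  payload <- c(charToRaw("Exif"), as.raw(c(0, 0)), tiff)
  c(as.raw(c(0xFF, 0xE1)), u16le_be(length(payload) + 2L), payload)
}

u16le_be <- function(x) as.raw(c(x %/% 256L, x %% 256L))

# iterate JPEG marker segments; returns list of (marker, start, length) where
# start is the 0xFF byte position and length covers the whole segment
jpeg_segments <- function(bytes) {
  if (length(bytes) < 4L || bytes[1] != as.raw(0xFF) || bytes[2] != as.raw(0xD8))
    stop("not a JPEG file", call. = FALSE)
  pos <- 3L
  segs <- list()
  while (pos + 3L <= length(bytes)) {
    if (bytes[pos] != as.raw(0xFF)) break
    marker <- as.integer(bytes[pos + 1L])
    if (marker == 0xDA) break                     # start of scan: entropy data
    len <- as.integer(bytes[pos + 2L]) * 256L + as.integer(bytes[pos + 3L])
    segs[[length(segs) + 1L]] <- list(marker = marker, start = pos,
                                      length = len + 2L)
    pos <- pos + 2L + len
  }
  segs
}

jpeg_exif_uuid_read <- function(bytes) {
  for (s in jpeg_segments(bytes)) {
    if (s$marker != 0xE1) next
    seg <- bytes[(s$start + 4L):(s$start + s$length - 1L)]
    if (length(seg) < 6L || !identical(rawToChar(seg[1:4]), "Exif")) next
    tiff <- seg[7:length(seg)]
    le <- identical(rawToChar(tiff[1:2]), "II")
    rd16 <- function(off) {
      b <- as.integer(tiff[(off + 1L):(off + 2L)])
      if (le) b[1] + 256L * b[2] else b[2] + 256L * b[1]
    }
    rd32 <- function(off) {
      b <- as.integer(tiff[(off + 1L):(off + 4L)])
      if (le) sum(b * c(1, 256, 65536, 16777216))
      else sum(rev(b) * c(1, 256, 65536, 16777216))
    }
    find_tag <- function(ifd_off, tag) {
      n <- rd16(ifd_off)
      for (i in seq_len(n)) {
        eoff <- ifd_off + 2L + (i - 1L) * 12L
        if (rd16(eoff) == tag) return(eoff)
      }
      NULL
    }
    exif_ptr <- find_tag(rd32(4L), 0x8769L)
    if (is.null(exif_ptr)) next
    uid_entry <- find_tag(rd32(exif_ptr + 8L), 0xA420L)
    if (is.null(uid_entry)) next
    count <- rd32(uid_entry + 4L)
    voff <- rd32(uid_entry + 8L)
    val <- rawToChar(tiff[(voff + 1L):(voff + count - 1L)])  # drop NUL
    hex <- tolower(val)
    if (grepl("^[0-9a-f]{32}$", hex))
      return(paste(substring(hex, c(1, 9, 13, 17, 21), c(8, 12, 16, 20, 32)),
                   collapse = "-"))
    return(val)
  }
  NULL
}

jpeg_has_exif <- function(bytes) {
  for (s in jpeg_segments(bytes)) {
    if (s$marker != 0xE1) next
    seg <- bytes[(s$start + 4L):min(s$start + 9L, length(bytes))]
    if (length(seg) >= 4L && identical(rawToChar(seg[1:4]), "Exif"))
      return(TRUE)
  }
  FALSE
}

# ---- minting --------------------------------------------------------------

file_format <- function(path) {
  head <- readBin(path, "raw", n = 8L)
  if (length(head) >= 8L && identical(head, .png_sig)) return("png")
  if (length(head) >= 2L && identical(head[1:2], as.raw(c(0xFF, 0xD8))))
    return("jpeg")
  "other"
}

#' Mint a UUID into an image file's metadata header
#'
#' Writes the UUID into the file itself so it is covered by the file hash:
#' JPEG files receive an EXIF `ImageUniqueID` tag, PNG files a `tEXt` chunk
#' keyed `image-uuid`. Other formats fall back, when permitted, to a sidecar
#' file `<path>.uuid` (with a warning). Minting is idempotent: re-minting
#' the same UUID leaves the bytes untouched. A file already carrying a
#' *different* UUID is refused — persistent identity is immutable. Pixel
#' data is never altered.
#'
#' @param path image file path.
#' @param uuid version-4 UUID to mint.
#' @param allow_sidecar permit the sidecar fallback for unsupported formats.
#' @return `path`, invisibly.
#' @export
mint_uuid <- function(path, uuid, allow_sidecar = FALSE) {
  if (!is_uuid4(uuid)) stop("invalid version-4 UUID: ", uuid, call. = FALSE)
  existing <- read_image_uuid(path)
  if (!is.null(existing)) {
    if (identical(existing, uuid)) return(invisible(path))
    stop("file '", basename(path), "' already minted with UUID ", existing,
         "; identity is immutable", call. = FALSE)
  }
  fmt <- file_format(path)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (fmt == "png") {
    writeBin(png_text_insert(bytes, "image-uuid", uuid), path)
  } else if (fmt == "jpeg" && !jpeg_has_exif(bytes)) {
    out <- c(bytes[1:2], jpeg_build_exif_uuid(uuid),
             bytes[seq(3L, length(bytes))])
    writeBin(out, path)
  } else {
    # unsupported format, or a JPEG whose existing EXIF we will not rewrite
    if (!allow_sidecar)
      stop("cannot mint UUID into '", basename(path),
           "' (format not writable) and sidecar fallback not permitted",
           call. = FALSE)
    warning("minting UUID for '", basename(path), "' via sidecar file",
            call. = FALSE)
    writeLines(uuid, paste0(path, ".uuid"))
  }
  invisible(path)
}

#' Read the UUID minted into an image file
#'
#' @param path image file path.
#' @return canonical UUID string, or NULL when none is embedded.
#' @export
read_image_uuid <- function(path) {
  fmt <- file_format(path)
  bytes <- readBin(path, "raw", n = file.size(path))
  found <- switch(fmt,
    png = png_text_read(bytes, "image-uuid"),
    jpeg = jpeg_exif_uuid_read(bytes),
    NULL)
  if (is.null(found) && file.exists(paste0(path, ".uuid")))
    found <- readLines(paste0(path, ".uuid"), n = 1L)
  found
}

#' Verify an image file against its iFDO metadata
#'
#' Checks (a) that the UUID embedded in the file matches the metadata's
#' `uuid` and (b) that the SHA-256 hash of the file's bytes matches the
#' metadata's `hash_sha256`. Both must hold for the item to be verified.
#' Mismatches are reported as results, not errors.
#'
#' @param path image file path.
#' @param meta resolved item metadata (named list with `uuid` and
#'   `hash_sha256`), e.g. from [resolve_item()].
#' @return list with `uuid_match`, `hash_match`, `verified` and `details`.
#' @export
verify_item <- function(path, meta) {
  if (is.null(meta$uuid) || is.null(meta$hash_sha256))
    stop("metadata must carry both 'uuid' and 'hash_sha256'", call. = FALSE)
  embedded <- read_image_uuid(path)
  uuid_match <- identical(embedded, meta$uuid)
  actual <- compute_hash(path)
  hash_match <- identical(actual, meta$hash_sha256)
  details <- character(0)
  if (!uuid_match)
    details <- c(details, paste0("embedded UUID ",
                                 embedded %||% "<none>",
                                 " != metadata UUID ", meta$uuid))
  if (!hash_match)
    details <- c(details, paste0("file hash ", actual,
                                 " != metadata hash ", meta$hash_sha256))
  list(uuid_match = uuid_match, hash_match = hash_match,
       verified = uuid_match && hash_match, details = details)
}
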