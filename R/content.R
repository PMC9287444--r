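# Image content descriptors and annotation encoding. Descriptors operate on
# decoded rasters (as returned by png::readPNG / jpeg::readJPEG: arrays in
# [0, 1], either a grayscale matrix or an H x W x C array) or on file paths.

read_raster <- function(image) {
  if (is.character(image)) {
    fmt <- file_format(image)
    image <- switch(fmt,
      png = png::readPNG(image),
      jpeg = jpeg::readJPEG(image),
      stop("unsupported raster format: ", image, call. = FALSE))
  }
  image
}

# 8-bit grayscale via BT.601 luma, rounded half-up
raster_gray255 <- function(img) {
  img <- read_raster(img)
  if (length(dim(img)) == 3L) {
    ch <- dim(img)[3]
    img <- if (ch >= 3L)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  if (length(img) == 0L) stop("zero-pixel image", call. = FALSE)
  floor(img * 255 + 0.5)
}

#' Shannon entropy of an image
#'
#' Converts the image to 8-bit grayscale (BT.601 luma, 0.299 R + 0.587 G +
#' 0.114 B, rounded half-up) and returns the Shannon entropy
#' \eqn{-\sum p_i \log_2 p_i} of the 256-bin intensity histogram. A uniform
#' image has entropy 0; the maximum over 256 bins is 8 bits.
#'
#' @param image file path or decoded raster (values in \[0, 1\]).
#' @return entropy in bits, in \[0, 8\].
#' @export
image_entropy <- function(image) {
  g <- raster_gray255(image)
  p <- tabulate(g + 1L, nbins = 256L) / length(g)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Average colour of an image
#'
#' Per-channel arithmetic mean on the 0–255 scale, reported to two decimal
#' places. Grayscale inputs yield an equal-valued triple.
#'
#' @param image file path or decoded raster (values in \[0, 1\]).
#' @return numeric RGB triple in \[0, 255\].
#' @export
average_colour <- function(image) {
  img <- read_raster(image)
  if (length(img) == 0L) stop("zero-pixel image", call. = FALSE)
  if (length(dim(img)) == 3L) {
    ch <- min(dim(img)[3], 3L)
    means <- vapply(seq_len(ch), function(k) mean(img[, , k]), numeric(1))
    if (ch < 3L) means <- rep(means[1], 3L)
  } else {
    means <- rep(mean(img), 3L)
  }
  round(means * 255, 2)
}

# 8-connected component labeling (union-find over foreground runs). Written
# here because the installed labeling routines are 4-connected only.
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nxt <- 0L
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      if (!mask[r, c]) next
      neigh <- integer(0)
      if (c > 1L && labels[r, c - 1L]) neigh <- c(neigh, labels[r, c - 1L])
      if (r > 1L) {
        if (labels[r - 1L, c]) neigh <- c(neigh, labels[r - 1L, c])
        if (c > 1L && labels[r - 1L, c - 1L])
          neigh <- c(neigh, labels[r - 1L, c - 1L])
        if (c < nc && labels[r - 1L, c + 1L])
          neigh <- c(neigh, labels[r - 1L, c + 1L])
      }
      if (length(neigh) == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[r, c] <- nxt
      } else {
        m <- min(neigh)
        labels[r, c] <- m
        for (o in neigh) unite(m, o)
      }
    }
  }
  if (nxt == 0L) return(labels)
  roots <- vapply(seq_len(nxt), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  idx <- labels > 0L
  labels[idx] <- remap[labels[idx]]
  labels
}

#' Count bright particles in an image
#'
#' Binarizes the grayscale image (Otsu's threshold by default, or a fixed
#' threshold on the 0–255 scale), labels 8-connected foreground components
#' and counts those of at least `min_area` pixels. Foreground means brighter
#' than the threshold — the dark-field convention of plankton and particle
#' imaging; set `invert = TRUE` for dark particles on a bright background.
#'
#' @param image file path or decoded raster.
#' @param min_area minimum component area in pixels.
#' @param threshold `"otsu"` or a fixed numeric threshold in \[0, 255\].
#' @param invert count dark components instead of bright ones.
#' @return integer particle count.
#' @export
particle_count <- function(image, min_area = 10L, threshold = "otsu",
                           invert = FALSE) {
  g <- raster_gray255(image)
  if (invert) g <- 255 - g
  if (length(unique(as.vector(g))) < 2L) return(0L)
  th <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(g / 255), range = c(0, 1), levels = 256) * 255
  } else as.numeric(threshold)
  mask <- g > th
  labels <- label_components8(mask)
  if (max(labels) == 0L) return(0L)
  sizes <- tabulate(labels[labels > 0L])
  sum(sizes >= min_area)
}

# ---- annotations ----------------------------------------------------------

#' Construct an image annotation
#'
#' An annotation is a pixel region plus one or more label IDs, one or more
#' annotator IDs and an optional confidence. The geometry class follows
#' from the coordinates: an empty coordinate list annotates the whole
#' image, a single point is a point annotation, two points declared as
#' `kind = "bbox"` are an axis-aligned bounding box
#' (`[xmin, ymin], [xmax, ymax]`), and three or more points whose first and
#' last coincide form a closed polygon. Pixel coordinates are 0-based with
#' the origin at the top-left corner, x growing right and y growing down.
#'
#' @param coordinates list of numeric `c(x, y)` pixel points (may be empty).
#' @param labels character vector of label IDs (at least one).
#' @param annotators character vector of annotator IDs (at least one).
#' @param confidence optional confidence in \[0, 1\] (per annotation).
#' @param frames optional video timestamp this annotation belongs to.
#' @param kind optional geometry hint, required (`"bbox"`) for the two-point
#'   bounding-box form.
#' @return object of class `ifdo_annotation`.
#' @export
ifdo_annotation <- function(coordinates, labels, annotators,
                            confidence = NULL, frames = NULL, kind = NULL) {
  coordinates <- lapply(coordinates, as.numeric)
  if (length(labels) < 1L || length(annotators) < 1L)
    stop("an annotation needs at least one label and one annotator",
         call. = FALSE)
  if (!is.null(confidence) && (confidence < 0 || confidence > 1))
    stop("confidence must be in [0, 1]", call. = FALSE)
  a <- structure(list(coordinates = coordinates,
                      labels = as.character(labels),
                      annotators = as.character(annotators),
                      confidence = confidence, frames = frames,
                      kind = kind),
                 class = "ifdo_annotation")
  annotation_geometry(a)  # errors on unclassifiable coordinate sets
  a
}

#' Geometry class of an annotation
#'
#' @param annotation an `ifdo_annotation` (or a compatible list).
#' @return one of `"whole-image"`, `"point"`, `"bounding-box"`, `"polygon"`.
#' @export
annotation_geometry <- function(annotation) {
  co <- annotation$coordinates
  n <- length(co)
  if (n == 0L) return("whole-image")
  if (n == 1L) return("point")
  if (n == 2L) {
    if (identical(annotation$kind, "bbox") &&
        co[[1]][1] <= co[[2]][1] && co[[1]][2] <= co[[2]][2])
      return("bounding-box")
    stop("two-point annotation must declare kind 'bbox' with ",
         "[xmin,ymin],[xmax,ymax] ordering", call. = FALSE)
  }
  if (isTRUE(all.equal(co[[1]], co[[n]]))) return("polygon")
  stop("polygon annotations must be closed (first point == last point)",
       call. = FALSE)
}

#' Encode annotations into iFDO content-section fields
#'
#' Produces the three content fields of the standard: the label
#' definitions, the annotator definitions and the annotation list, each
#' annotation carrying its pixel coordinates, label IDs, annotator IDs and
#' optional confidence. Referential integrity is enforced: every ID used by
#' an annotation must be defined.
#'
#' @param labels list of label definitions, each `list(id, name)`.
#' @param creators list of annotator definitions, each
#'   `list(id, name, kind)` with kind `"human"` or `"machine"`.
#' @param annotations list of [ifdo_annotation()] objects.
#' @return named list with fields `annotation_labels`,
#'   `annotation_creators`, `annotations` ready to place in item metadata.
#' @export
encode_annotations <- function(labels, creators, annotations) {
  label_ids <- vapply(labels, function(l) as.character(l$id), character(1))
  creator_ids <- vapply(creators, function(c_) as.character(c_$id),
                        character(1))
  if (anyDuplicated(label_ids) || anyDuplicated(creator_ids))
    stop("label and annotator ids must be unique", call. = FALSE)
  enc <- lapply(annotations, function(a) {
    dang <- setdiff(a$labels, label_ids)
    if (length(dang)) stop("dangling label id: '", dang[1], "'",
                           call. = FALSE)
    dang <- setdiff(a$annotators, creator_ids)
    if (length(dang)) stop("dangling annotator id: '", dang[1], "'",
                           call. = FALSE)
    if (!is.null(a$confidence) && (a$confidence < 0 || a$confidence > 1))
      stop("confidence outside [0, 1]", call. = FALSE)
    out <- list(coordinates = a$coordinates, labels = as.list(a$labels),
                annotators = as.list(a$annotators))
    if (!is.null(a$kind)) out$kind <- a$kind
    if (!is.null(a$confidence)) out$confidence <- a$confidence
    if (!is.null(a$frames)) out$frames <- a$frames
    out
  })
  list(annotation_labels = labels, annotation_creators = creators,
       annotations = enc)
}

#' Decode iFDO content-section annotation fields
#'
#' Inverse of [encode_annotations()]: `decode(encode(x))` recovers `x`.
#'
#' @param fields named list with `annotation_labels`, `annotation_creators`
#'   and `annotations` (as stored in item metadata).
#' @return list with `labels`, `creators` and `annotations` (a list of
#'   [ifdo_annotation()] objects).
#' @export
decode_annotations <- function(fields) {
  anns <- lapply(fields$annotations %||% list(), function(o) {
    ifdo_annotation(
      coordinates = o$coordinates %||% list(),
      labels = unlist(o$labels),
      annotators = unlist(o$annotators),
      confidence = o$confidence,
      frames = o$frames,
      kind = o$kind
    )
  })
  list(labels = fields$annotation_labels %||% list(),
       creators = fields$annotation_creators %||% list(),
       annotations = anns)
}
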