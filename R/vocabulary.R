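# Controlled vocabulary, tiered validation and the RDA FAIR maturity report.
# Severity tiers follow the section tiers of the standard: a missing required
# (core) field is an error, a missing recommended (capture) field a warning,
# optional (content) fields and unknown extension fields are informational.

#' Load a built-in iFDO vocabulary
#'
#' The vocabulary lists the required (core), recommended (capture) and
#' optional (content) fields of one version of the standard, plus the
#' restricted value sets of the enumerated capture fields. Vocabularies are
#' shipped as versioned YAML files inside the package.
#'
#' @param version vocabulary version string; `"1.0.0"` is shipped.
#' @return object of class `ifdo_vocabulary`.
#' @export
builtin_vocabulary <- function(version = "1.0.0") {
  path <- system.file("extdata", paste0("vocabulary-", version, ".yaml"),
                      package = "ifdo")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown vocabulary version: '", version, "'", call. = FALSE)
  raw <- yaml::read_yaml(path)
  structure(list(
    version = raw$version,
    required_fields = raw[["required-fields"]],
    recommended_fields = raw[["recommended-fields"]],
    optional_fields = raw[["optional-fields"]],
    restricted_values = raw[["restricted-values"]],
    open_ended_fields = raw[["open-ended-fields"]] %||% character(0)
  ), class = "ifdo_vocabulary")
}

#' @export
print.ifdo_vocabulary <- function(x, ...) {
  cat("iFDO vocabulary", x$version, "-", length(x$required_fields),
      "required,", length(x$recommended_fields), "recommended,",
      length(x$optional_fields), "optional fields\n")
  invisible(x)
}

#' Validate an ORCID identifier
#'
#' Checks the 16-digit hyphenated pattern and the ISO 7064 mod 11-2 check
#' digit (final character, may be `X`).
#'
#' @param x character vector of ORCID strings.
#' @return logical vector.
#' @export
is_orcid <- function(x) {
  vapply(x, function(o) {
    if (!is.character(o) ||
        !grepl("^\\d{4}-\\d{4}-\\d{4}-\\d{3}[0-9X]$", o)) return(FALSE)
    digits <- strsplit(gsub("-", "", o), "")[[1]]
    total <- 0
    for (d in digits[1:15]) total <- (total + as.integer(d)) * 2
    result <- (12 - total %% 11) %% 11
    expected <- if (result == 10) "X" else as.character(result)
    identical(digits[16], expected)
  }, logical(1), USE.NAMES = FALSE)
}

finding <- function(field, item, severity, message) {
  data.frame(field = field, item = item, severity = severity,
             message = message, stringsAsFactors = FALSE)
}

# value-level checks for a single resolved field; returns a findings df
check_field_value <- function(name, value, item, vocab, meta = NULL) {
  key <- ifdo_field_key(name)
  err <- function(msg) finding(key, item, "error", msg)
  ok <- finding(character(0), character(0), character(0), character(0))
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  if (!is.null(vocab$restricted_values[[key]])) {
    allowed <- vocab$restricted_values[[key]]
    if (!is.character(value) || length(value) != 1L || !value %in% allowed) {
      sev <- if (key %in% vocab$open_ended_fields) "warning" else "error"
      return(finding(key, item, sev,
                     paste0("value '", paste(value, collapse = ","),
                            "' not in allowed set {",
                            paste(allowed, collapse = ", "), "}")))
    }
    return(ok)
  }
  switch(name,
    datetime = {
      if (!is.character(value) || is.na(parse_ifdo_datetime(value)))
        return(err("datetime is not a parseable ISO 8601 timestamp"))
      if (!grepl("(Z|\\+00:00)$", value))
        return(err("datetime lacks an explicit UTC designator"))
    },
    latitude = if (!num1(value) || value < -90 || value > 90)
      return(err("latitude must be in [-90, 90] degrees")),
    longitude = if (!num1(value) || value < -180 || value > 180)
      return(err("longitude must be in [-180, 180] degrees")),
    depth = if (!num1(value))
      return(err("depth must be a single number (meters, positive down)")),
    coordinate_uncertainty_meters = if (!num1(value) || value < 0)
      return(err("coordinate uncertainty must be >= 0 meters")),
    uuid = if (!isTRUE(is_uuid4(value)))
      return(err("not a valid version-4 UUID")),
    hash_sha256 = if (!isTRUE(is_sha256(value)))
      return(err("not a 64-character lowercase SHA-256 hex digest")),
    pi = {
      if (!is.list(value) || is.null(value$name))
        return(err("image-pi must carry a 'name'"))
      if (!is.null(value$orcid) && !is_orcid(value$orcid))
        return(err(paste0("invalid ORCID: ", value$orcid)))
    },
    creators = {
      if (!is.list(value))
        return(err("image-creators must be a list of persons"))
      for (p in value) {
        if (!is.list(p) || is.null(p$name))
          return(err("each creator must carry a 'name'"))
        if (!is.null(p$orcid) && !is_orcid(p$orcid))
          return(err(paste0("invalid ORCID: ", p$orcid)))
      }
    },
    area_square_meter = if (!num1(value) || value <= 0)
      return(err("image area must be > 0 square meters")),
    meters_above_ground = if (!num1(value) || value < 0)
      return(err("meters above ground must be >= 0")),
    overlap_fraction = if (!num1(value) || value < 0 || value > 1)
      return(err("overlap fraction must be in [0, 1]")),
    entropy = if (!num1(value) || value < 0 || value > 8)
      return(err("entropy must be in [0, 8] bits")),
    particle_count = if (!num1(value) || value < 0 ||
                         value != as.integer(value))
      return(err("particle count must be a non-negative integer")),
    average_colour = if (!is.numeric(value) || length(value) != 3L ||
                         any(value < 0 | value > 255))
      return(err("average colour must be an RGB triple in [0, 255]")),
    mpeg7_colorstructure = if (!is.numeric(value) ||
                               !length(value) %in% c(32L, 64L, 128L, 256L))
      return(err("MPEG-7 colorstructure must be numeric of length 32/64/128/256")),
    annotation_labels = {
      ids <- vapply(value, function(l) as.character(l$id %||% NA_character_),
                    character(1))
      if (anyNA(ids) || anyDuplicated(ids))
        return(err("annotation labels must carry unique 'id' values"))
    },
    annotation_creators = {
      for (cr in value) {
        if (is.null(cr$id))
          return(err("annotation creators must carry an 'id'"))
        if (!is.null(cr$kind) && !cr$kind %in% c("human", "machine"))
          return(err("annotation creator kind must be 'human' or 'machine'"))
      }
    },
    annotations = {
      label_ids <- vapply(meta$annotation_labels %||% list(),
                          function(l) as.character(l$id), character(1))
      creator_ids <- vapply(meta$annotation_creators %||% list(),
                            function(l) as.character(l$id), character(1))
      for (a in value) {
        dang <- setdiff(as.character(unlist(a$labels)), label_ids)
        if (length(dang))
          return(err(paste0("annotation references unknown label id '",
                            dang[1], "'")))
        dang <- setdiff(as.character(unlist(a$annotators)), creator_ids)
        if (length(dang))
          return(err(paste0("annotation references unknown annotator id '",
                            dang[1], "'")))
        if (!is.null(a$confidence) &&
            (a$confidence < 0 || a$confidence > 1))
          return(err("annotation confidence must be in [0, 1]"))
      }
    }
  )
  ok
}

#' Validate an iFDO document against a vocabulary
#'
#' Resolves every item against the header defaults and checks, per item:
#' missing required core fields (errors), missing recommended capture fields
#' (warnings), restricted capture fields with out-of-set values (errors;
#' open-ended fields such as deployment warn instead), range and format
#' violations (latitude/longitude/depth bounds, fraction and entropy ranges,
#' UUID / SHA-256 / ORCID formats, non-UTC datetimes — all errors), unknown
#' extension fields (info) and set-level fields inside an item (error).
#' Finding order is deterministic: header first, then items in document
#' order, fields alphabetically.
#'
#' A document is FAIR exactly when it produces zero error findings.
#'
#' @param doc an `ifdo` object.
#' @param vocab an `ifdo_vocabulary`; defaults to the shipped 1.0.0.
#' @return object of class `ifdo_validation`: list with `findings` (data
#'   frame: field, item, severity, message) and `is_fair`.
#' @export
validate_ifdo <- function(doc, vocab = builtin_vocabulary()) {
  findings <- list()
  add <- function(f) if (nrow(f)) findings[[length(findings) + 1L]] <<- f
  h <- doc$header
  if (is.null(h$set_name) || !nzchar(h$set_name %||% ""))
    add(finding("image-set-name", "header", "error",
                "set name is missing"))
  if (is.null(h$set_uuid) || !isTRUE(is_uuid4(h$set_uuid)))
    add(finding("image-set-uuid", "header", "error",
                "set UUID is missing or not a valid version-4 UUID"))
  if (is.null(h$set_handle) || !is_absolute_url(h$set_handle))
    add(finding("image-set-handle", "header", "error",
                "set handle is missing or not an absolute URL"))
  for (nm in sort(names(h$defaults) %||% character(0), method = "radix")) {
    if (!ifdo_known_field(nm)) {
      add(finding(nm, "header", "info",
                  "unknown field (carried as extension metadata)"))
    } else {
      add(check_field_value(nm, h$defaults[[nm]], "header", vocab,
                            meta = h$defaults))
    }
  }
  req_names <- ifdo_field_name(vocab$required_fields)
  rec_names <- ifdo_field_name(vocab$recommended_fields)
  for (item_name in names(doc$items)) {
    item <- doc$items[[item_name]]
    entries <- if (is_video_record(item)) item else list(item)
    own <- unique(unlist(lapply(entries, names)))
    bad_set <- intersect(own, c(.ifdo_set_fields, names(.ifdo_set_fields)))
    for (b in sort(bad_set))
      add(finding(b, item_name, "error",
                  "set-level field must not appear in an item record"))
    meta <- resolve_item(doc, item_name)
    for (nm in sort(setdiff(req_names, names(meta)), method = "radix"))
      add(finding(ifdo_field_key(nm), item_name, "error",
                  "required core field is missing"))
    for (nm in sort(setdiff(rec_names, names(meta)), method = "radix"))
      add(finding(ifdo_field_key(nm), item_name, "warning",
                  "recommended capture field is missing"))
    # value checks apply to the item's own fields only: inherited defaults
    # were already checked once at header level
    own_top <- names(if (is_video_record(item)) item[[1L]] else item)
    check_names <- sort(setdiff(own_top, bad_set), method = "radix")
    for (nm in check_names) {
      if (!ifdo_known_field(nm)) {
        add(finding(nm, item_name, "info",
                    "unknown field (carried as extension metadata)"))
      } else {
        add(check_field_value(nm, meta[[nm]], item_name, vocab, meta = meta))
      }
    }
    if (is_video_record(item)) {
      for (i in seq_along(entries)[-1]) {
        tp <- resolve_timepoint(doc, item_name, i - 1L)
        for (nm in sort(intersect(names(entries[[i]]), .ifdo_item_fields)))
          add(check_field_value(nm, tp[[nm]],
                                paste0(item_name, ":", i - 1L), vocab,
                                meta = tp))
      }
    }
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    finding(character(0), character(0), character(0), character(0))
  structure(list(findings = findings,
                 is_fair = !any(findings$severity == "error")),
            class = "ifdo_validation")
}

#' @export
print.ifdo_validation <- function(x, ...) {
  tab <- table(factor(x$findings$severity,
                      levels = c("error", "warning", "info")))
  cat("iFDO validation:", tab[["error"]], "error(s),",
      tab[["warning"]], "warning(s),", tab[["info"]], "info\n")
  cat("  FAIR:", if (x$is_fair) "yes" else "no", "\n")
  if (nrow(x$findings)) {
    show <- utils::head(x$findings, 20L)
    for (i in seq_len(nrow(show)))
      cat(sprintf("  [%s] %s / %s: %s\n", show$severity[i], show$item[i],
                  show$field[i], show$message[i]))
    if (nrow(x$findings) > 20L)
      cat("  ... and", nrow(x$findings) - 20L, "more\n")
  }
  invisible(x)
}
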