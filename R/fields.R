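# Field registry: maps in-memory (underscored) field names to the hyphenated
# keys used inside iFDO files. Unknown keys are carried verbatim in both
# directions, which is what keeps the format extensible.

.ifdo_core_fields <- c(
  "datetime", "latitude", "longitude", "depth",
  "coordinate_reference_system", "coordinate_uncertainty_meters",
  "uuid", "hash_sha256",
  "context", "project", "event", "platform", "sensor", "abstract",
  "pi", "creators", "license", "copyright"
)

.ifdo_capture_fields <- c(
  "acquisition", "deployment", "illumination", "capture_mode",
  "area_square_meter", "meters_above_ground", "overlap_fraction",
  "camera_housing_viewport", "camera_calibration_model",
  "objective", "target_environment", "fauna_attraction",
  "temporal_constraints"
)

.ifdo_content_fields <- c(
  "entropy", "particle_count", "average_colour", "mpeg7_colorstructure",
  "annotation_labels", "annotation_creators", "annotations"
)

.ifdo_item_fields <- c(.ifdo_core_fields, .ifdo_capture_fields,
                       .ifdo_content_fields)

# set-level fields: live only in the header, never in items
.ifdo_set_fields <- c(
  set_name       = "image-set-name",
  set_uuid       = "image-set-uuid",
  set_handle     = "image-set-handle",
  format_version = "image-set-ifdo-version"
)

#' File key for an in-memory item field name
#'
#' Known item-level fields map to the hyphenated `image-...` spelling used in
#' iFDO files; unknown names pass through verbatim.
#'
#' @param name character vector of in-memory field names.
#' @return character vector of file keys.
#' @keywords internal
ifdo_field_key <- function(name) {
  ifelse(name %in% .ifdo_item_fields,
         paste0("image-", gsub("_", "-", name, fixed = TRUE)),
         name)
}

#' In-memory name for an iFDO file key
#'
#' @param key character vector of file keys.
#' @return character vector of in-memory names (unknown keys verbatim).
#' @keywords internal
ifdo_field_name <- function(key) {
  cand <- gsub("-", "_", sub("^image-", "", key))
  ifelse(grepl("^image-", key) & cand %in% .ifdo_item_fields, cand, key)
}

ifdo_known_field <- function(name) name %in% .ifdo_item_fields

# section lookup for validation tiers
ifdo_field_section <- function(name) {
  ifelse(name %in% .ifdo_core_fields, "core",
  ifelse(name %in% .ifdo_capture_fields, "capture",
  ifelse(name %in% .ifdo_content_fields, "content", "unknown")))
}
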