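# Shared test helpers: generated iFDO documents, a brute-force field-merge
# oracle, and mutation fixtures for the validator.

# a complete, valid item metadata list (all core fields populated)
full_item_meta <- function(uuid = generate_uuid(),
                           datetime = "2022-07-15T10:00:00.000Z",
                           latitude = 54.33, longitude = 10.18,
                           depth = 2000.5) {
  list(
    datetime = datetime, latitude = latitude, longitude = longitude,
    depth = depth,
    coordinate_reference_system = "EPSG:4326",
    coordinate_uncertainty_meters = 2.5,
    uuid = uuid,
    hash_sha256 = paste(rep("ab", 32), collapse = ""),
    context = "test context", project = "TST", event = "TST-1",
    platform = "ROV", sensor = "camA", abstract = "a test item",
    pi = list(name = "Josiah Carberry", orcid = "0000-0002-1825-0097"),
    creators = list(list(name = "Josiah Carberry")),
    license = "CC-BY-4.0", copyright = "(c) test"
  )
}

# minimal valid document: all core fields as header defaults, one item
# carrying only its per-image values
minimal_valid_doc <- function(n_items = 1L) {
  defaults <- full_item_meta()
  per_item <- c("datetime", "latitude", "longitude", "depth", "uuid",
                "hash_sha256", "coordinate_uncertainty_meters")
  items <- list()
  for (i in seq_len(n_items)) {
    m <- full_item_meta(
      datetime = sprintf("2022-07-15T10:%02d:00.000Z", i),
      latitude = 54.33 + i * 1e-4, longitude = 10.18 + i * 1e-4,
      depth = 2000 + i)
    items[[sprintf("img_%03d.png", i)]] <- m[per_item]
  }
  ifdo_document(
    set_name = "test set",
    set_uuid = generate_uuid(),
    set_handle = paste0("https://hdl.handle.net/20.500.12085/",
                        generate_uuid(), "@ifdo"),
    defaults = defaults[setdiff(names(defaults), per_item)],
    items = items
  )
}

# randomized document for round-trip property tests; pure function of the
# current RNG state
random_doc <- function() {
  n_items <- sample(0:5, 1)
  items <- list()
  pool_fields <- function() {
    m <- full_item_meta(
      datetime = format(
        as.POSIXct("2022-07-15 10:00:00", tz = "UTC") +
          round(stats::runif(1, 0, 86400), 3),
        "%Y-%m-%dT%H:%M:%OS3"),
      latitude = round(stats::runif(1, -90, 90), 7),
      longitude = round(stats::runif(1, -180, 180), 7),
      depth = round(stats::runif(1, 0, 6000), 3))
    m$datetime <- paste0(m$datetime, "Z")
    extra <- list(
      entropy = round(stats::runif(1, 0, 8), 6),
      particle_count = sample(0:50, 1),
      average_colour = round(stats::runif(3, 0, 255), 2),
      acquisition = sample(c("photo", "video", "slide"), 1),
      `x-custom-field` = paste0("v", sample(1000, 1))
    )
    c(m, extra[sample(names(extra), sample(0:5, 1))])
  }
  for (i in seq_len(n_items)) {
    nm <- sprintf("item_%03d_%04d.png", i, sample(9999, 1))
    if (stats::runif(1) < 0.25) {
      # video record: defaults entry + ordered timepoints
      base <- pool_fields()
      k <- sample(1:3, 1)
      tps <- lapply(seq_len(k), function(j)
        list(datetime = sprintf("2022-07-15T11:00:%02d.000Z", j),
             depth = round(stats::runif(1, 0, 6000), 3)))
      items[[nm]] <- c(list(base), tps)
    } else {
      items[[nm]] <- pool_fields()
    }
  }
  defaults <- full_item_meta()[sample(names(full_item_meta()),
                                      sample(3:10, 1))]
  ifdo_document(
    set_name = paste0("set-", sample(1000, 1)),
    set_uuid = generate_uuid(),
    set_handle = paste0("https://hdl.handle.net/20.500.12085/",
                        generate_uuid(), "@ifdo"),
    defaults = defaults, items = items
  )
}

# brute-force merge oracle, independent of the package's overlay: for each
# key in the union, take the value from the rightmost layer that carries it
naive_merge <- function(...) {
  layers <- list(...)
  keys <- unique(unlist(lapply(layers, names)))
  out <- list()
  for (k in keys) {
    for (layer in rev(layers)) {
      if (k %in% names(layer)) { out[[k]] <- layer[[k]]; break }
    }
  }
  out
}

# mutation fixtures: each entry breaks one thing in the minimal document
# and states the single expected finding (field + severity)
mutation_fixtures <- function() {
  mut <- function(desc, apply, field, severity) {
    list(desc = desc, apply = apply, field = field, severity = severity)
  }
  drop_field <- function(name) function(doc) {
    doc$header$defaults[[name]] <- NULL
    for (nm in names(doc$items)) doc$items[[nm]][[name]] <- NULL
    doc
  }
  set_item_field <- function(name, value) function(doc) {
    doc$items[[1]][[name]] <- value
    doc
  }
  list(
    mut("missing license", drop_field("license"), "image-license", "error"),
    mut("missing copyright", drop_field("copyright"), "image-copyright", "error"),
    mut("missing abstract", drop_field("abstract"), "image-abstract", "error"),
    mut("missing pi", drop_field("pi"), "image-pi", "error"),
    mut("missing creators", drop_field("creators"), "image-creators", "error"),
    mut("missing context", drop_field("context"), "image-context", "error"),
    mut("missing platform", drop_field("platform"), "image-platform", "error"),
    mut("missing sensor", drop_field("sensor"), "image-sensor", "error"),
    mut("missing datetime", drop_field("datetime"), "image-datetime", "error"),
    mut("missing uuid", drop_field("uuid"), "image-uuid", "error"),
    mut("missing hash", drop_field("hash_sha256"), "image-hash-sha256", "error"),
    mut("latitude out of range", set_item_field("latitude", 91.0),
        "image-latitude", "error"),
    mut("longitude out of range", set_item_field("longitude", -190.0),
        "image-longitude", "error"),
    mut("negative uncertainty",
        set_item_field("coordinate_uncertainty_meters", -1),
        "image-coordinate-uncertainty-meters", "error"),
    mut("bad uuid", set_item_field("uuid", "not-a-uuid"),
        "image-uuid", "error"),
    mut("bad hash", set_item_field("hash_sha256", "zz"),
        "image-hash-sha256", "error"),
    mut("naive datetime",
        set_item_field("datetime", "2022-07-15T10:00:00.000"),
        "image-datetime", "error"),
    mut("restricted acquisition value",
        function(doc) { doc$header$defaults$acquisition <- "drawing"; doc },
        "image-acquisition", "error"),
    mut("bad orcid",
        function(doc) {
          doc$header$defaults$pi <- list(name = "X",
                                         orcid = "0000-0002-1825-0098")
          doc
        },
        "image-pi", "error"),
    mut("set-level field inside item",
        set_item_field("set_uuid", "abc"),
        "set_uuid", "error")
  )
}
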