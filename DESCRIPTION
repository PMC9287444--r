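Package: ifdo
Title: Image FAIR Digital Objects for Marine Imagery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Create, validate, resolve and publish iFDO (image FAIR Digital
    Object) metadata files for marine image datasets. Implements the iFDO
    YAML document model with header/item default resolution, persistent
    identification (random version-4 UUIDs minted into image file headers,
    SHA-256 file integrity hashes, handle URLs), controlled-vocabulary
    validation with an RDA FAIR maturity report, curation of underwater
    navigation tracks (robust outlier rejection, smoothing, interpolation
    to image capture times), image content descriptors (entropy, average
    colour, particle counts) and annotation encoding, plus an iFDO factory
    that assembles a complete document from an image directory, a
    navigation track and a project configuration. A deterministic
    synthetic-data generator produces fully ground-truthed test datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    yaml,
    digest,
    png,
    jpeg,
    EBImage,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    openssl,
    optparse
Config/testthat/edition: 3
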