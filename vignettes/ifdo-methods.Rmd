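---
title: "Marine image FAIR Digital Objects: the model and methods behind ifdo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marine image FAIR Digital Objects: the model and methods behind ifdo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifdo)
```

## The problem

Marine imaging produces petabyte-scale datasets from AUVs, ROVs, towed
platforms and moorings, with no universally adopted metadata standard. The
iFDO (image FAIR Digital Object) format addresses this: one YAML file per
image set that carries everything needed to make the set Findable,
Accessible, Interoperable and Reusable — persistent identifiers, capture
conditions, and image-derived semantic content. This package implements the
format end to end: the document model, identification and integrity, the
controlled vocabulary and validation, navigation curation, content
descriptors, and a factory that assembles complete documents from raw
acquisition products.

## The document model

An iFDO consists of two parts. The `image-set-header` carries the three
set-level identity fields (`image-set-name`, `image-set-uuid`,
`image-set-handle`) plus *default values* for any item-level field. The
`image-set-items` part maps item names (curated file names) to the values
that *deviate* from those defaults; item values supersede header values
field by field. A video record is a list whose first entry carries
video-wide defaults and whose later entries override them per timepoint, so
resolving timepoint *i* layers header &#8852; entry 0 &#8852; entry *i*,
later layers winning. Resolution is an associative overlay with
right-precedence; overlaying an empty layer is the identity. The test suite
checks this algebra against a brute-force merge oracle that scans layers
right-to-left, a deliberately independent code path.

Item-level fields fall into three tiers: the *core* section (identity,
position, time, ownership and licensing) is required for FAIRness; the
*capture* section (acquisition technique) is recommended; the *content*
section (entropy, particle counts, average colour, annotations) is
optional. Field requiredness is a validation concern, not a type
constraint, so partially populated documents can be represented, inspected
and repaired.

Design choices the format description leaves open, decided here once:

* **Field naming.** Files use the hyphenated `image-...` spelling; in
  memory the prefix is stripped and hyphens become underscores
  (`image-hash-sha256` &#8596; `hash_sha256`), because hyphens are not legal
  in R names. Unknown keys pass through verbatim in both directions — the
  format is extensible, and extension metadata must survive a round trip
  (it is reported at *info* severity, never an error).
* **Datetimes** are `YYYY-MM-DDTHH:MM:SS.sssZ`, UTC only. The standard
  requires UTC but no lexical form; one canonical form keeps output
  byte-stable. Milliseconds are rounded, not truncated.
* **Depth** is positive meters below the sea surface; altitude above the
  seabed is the separate `meters_above_ground`.
* **Photos vs one-element lists.** A photo may legally be written as a
  one-element list; this implementation normalizes it to a single mapping
  on parse. Round-trip identity is therefore *semantic* (same fields, same
  values — see `ifdo_equal()`), and the canonical writer is a fixed point:
  `write(parse(write(doc)))` is byte-identical to `write(doc)`.
* **Serialization order** is canonical (set fields first, then keys
  alphabetically; items alphabetically), so the same document always
  serializes to the same bytes — a prerequisite for hashing and caching
  metadata files themselves.

## Identity and integrity

Each image and each set gets a random version-4 UUID: 122 free bits, about
5&#215;10^36 possible values, so collisions are not a practical concern.
UUIDs are drawn from R's own RNG (`generate_uuid()`), which makes document
assembly reproducible under `set.seed()` — important both for testing and
for re-running a factory deterministically.

The ordering contract matters: the UUID is written into the image file's
metadata header *first*, and the SHA-256 hash is computed over the
already-minted bytes. The hash therefore covers the identifier, and
`verify_item()` can check both at once. Minting targets:

* **JPEG**: an EXIF `ImageUniqueID` tag (hyphen-stripped 32-hex form per
  EXIF convention, reconstructed on read). If a file already carries an
  EXIF segment without that tag, the implementation does not rewrite
  third-party IFD layouts; it falls back to the sidecar when permitted.
* **PNG**: a `tEXt` chunk keyed `image-uuid`, inserted immediately after
  `IHDR`. The fixed position makes re-minting the same UUID a byte-level
  no-op.
* **Anything else**: a sidecar `<file>.uuid`, only with explicit
  permission, and always with a warning.

Minting never touches pixel data, and a file already carrying a
*different* UUID is refused — persistent identity is immutable.

## Vocabulary and validation

The shipped vocabulary (version 1.0.0, a YAML data file inside the
package) lists the three field tiers and the restricted value sets:
acquisition &#8712; {photo, video, slide}, illumination &#8712; {sunlight,
artificial light, mixed light}, capture mode &#8712; {timer, manual,
mixed}, and deployment &#8839; {mapping, stationary, survey}. Deployment is
open-ended in the standard, so unknown deployment values produce a warning
rather than an error. Severities map the tiers directly: missing required
&#8594; error, missing recommended &#8594; warning, unknown fields &#8594;
info. Range and format checks (latitude/longitude bounds, fractions,
entropy in [0, 8], UUID/SHA-256/ORCID formats with the ISO 7064 mod 11-2
ORCID checksum, UTC designators) are errors. A document is FAIR exactly
when validation yields zero errors. Finding order is deterministic —
header first, then items in document order, fields alphabetically — so
reports diff cleanly. Inherited header defaults are value-checked once, at
the header, not re-reported per item.

The RDA FAIR maturity matrix is encoded as data: 41 recommendations, of
which 2 are not applicable to image data, 3 are deferred to a future
standard version, and the remaining 36 are achieved. Two vocabulary rows
are marked "in preparation" but count toward the achieved set so the three
categories partition all 41 rows; `fair_report()` records this counting
convention in its notes and additionally checks, per document, which
achieved recommendations the document itself satisfies (handle, UUIDs,
license, ORCID, clean validation).

## Navigation curation

Raw underwater position data carries spikes (acoustic positioning
dropouts) and noise. Curation runs in three stages, each with an explicit
contract:

1. **Outlier rejection** is a two-dimensional Hampel screen: positions are
   projected to a local equirectangular meter frame, and a sample is an
   outlier when its distance to the running-median track (centered window,
   default 11 samples) exceeds *k* (default 5) times the MAD of the
   distances of all window members to that same median point. Computing
   the MAD over the window's distances means the scale reflects the
   platform's own motion, so the small median shift a 100 m spike causes
   does not drag its neighbours over the threshold. The MAD is floored at
   1 cm so static tracks cannot divide by zero. Depth is screened the same
   way, independently. If more than half the samples would go, the track
   is returned unchanged with a warning — wholesale deletion is never
   silent.
2. **Smoothing** is a centered moving average with symmetric shrinking
   windows at the ends (endpoints pass through unchanged). It is exact on
   constant-velocity tracks and reduces white noise by about
   &#8730;window; both properties are tested, the latter by Monte Carlo.
3. **Interpolation** to image capture times is piecewise linear per
   coordinate, exact at the track's own samples. Longitudes are unwrapped
   across the antimeridian first. Extrapolation beyond a 5 s tolerance is
   refused per timestamp. The reported `coordinate_uncertainty_meters` is
   the configured sensor uncertainty plus half the horizontal displacement
   of the bracketing pair — the honest statement that the position could
   be anywhere along that segment. This derivation is this package's
   choice; the standard names the field but not the method.

The equirectangular approximation and per-coordinate linear interpolation
are valid at survey scales (meter-level spacing); they degrade for tracks
spanning degrees of latitude or running very near the poles. Kalman/IMU
fusion and layback models are out of scope.

## Content descriptors and annotations

Descriptors are deterministic functions of the decoded raster. Grayscale
conversion uses BT.601 luma (0.299 R + 0.587 G + 0.114 B, rounded
half-up). `image_entropy()` is Shannon entropy over the 256-bin histogram
(0 for uniform images, at most 8 bits); `average_colour()` is the
per-channel mean on the 0–255 scale to two decimals; `particle_count()`
binarizes (Otsu by default; foreground = brighter, the dark-field
plankton convention, invertible), labels 8-connected components and
discards those below `min_area`. The labeling pass is implemented in the
package because the installed morphology routines label 4-connected
components only, which splits diagonally-touching particles. The MPEG-7
ColorStructure descriptor is carried and length-validated (32/64/128/256)
but never computed.

Annotations are pixel regions plus label IDs, annotator IDs and an
optional confidence. The geometry class is a function of the coordinates:
empty &#8594; whole image, one point &#8594; point, two points declared
`bbox` &#8594; bounding box, &#8805; 3 points with first = last &#8594;
closed polygon. Coordinates are 0-based, origin top-left — the raster file
convention; the standard leaves the coordinate format flexible, so this is
this package's concretization. Confidence applies per annotation (not per
label). Encoding and decoding are exact inverses, and referential
integrity of IDs is enforced at encode time and re-checked by validation.

## The factory

`create_ifdo()` runs the pipeline in the order the identity contract
demands: verify UTC timing &#8594; curate navigation &#8594; generate
UUIDs &#8594; mint &#8594; rename (canonical
`<project>_<event>_<sensor>_<date>_<time>` scheme) &#8594; hash &#8594;
interpolate positions &#8594; derive footprint fields &#8594; assemble
&#8594; validate. Capture datetimes come from embedded metadata (the PNG
`image-datetime` text chunk) or a filename pattern; a conflict between the
two is an error, never a silent preference. All file work happens in a
staging directory, and nothing is committed unless every stage succeeds
and validation is clean (or `force = TRUE`) — partial outputs are never
left behind.

Assembly factors every field whose value is identical across all items
into the header, so nothing shared is duplicated; with fixed UUID seeds
the output is byte-identical across runs, and shuffling file discovery
order does not change the document (files are processed in capture-time
order).

The footprint model is a nadir pinhole: imaged width `2 h tan(hfov/2)`,
area = width &#215; height, scale = pixel width / footprint width.
Oblique viewing, housing refraction and lens distortion are out of scope;
the housing and calibration fields are carried as text.

## The synthetic-data generator

`make_dataset()` produces a complete, fully ground-truthed acquisition:
images, navigation and configuration. Its defaults are fixed study
conditions, chosen once as a realistic deep-sea photo survey:

* **Track**: 600 s at 1 Hz, ~1 m/s transect with very gentle curvature at
  ~2000 m depth; Gaussian position noise &#963; = 1 m (good ship-GPS /
  USBL at that scale); 5 spikes of 100 m (typical acoustic-positioning
  dropouts), placed at least 25 samples apart and away from the track
  ends so a centered window never contains two spikes.
* **Images**: 256&#215;256 px, 8-bit grayscale PNG; bright disks
  (intensity 230) of radius 5 px on a level-64 background, placed
  non-overlapping by rejection sampling with bounded retries; 0–10
  particles per image. The manifest records the exact per-image count,
  mean and histogram, computed from the written pixel array itself.
* **Configuration**: a complete core section (including a checksummed
  ORCID), `artificial light` / `survey` / `timer` capture defaults, a
  90&#176;&#215;70&#176; camera at 2 m altitude.

What the generator emulates: timing, geometry, identity, integrity and the
statistical structure of navigation error. What it does not emulate:
photorealistic seafloor texture, JPEG compression artefacts, lighting
gradients, overlapping or low-contrast particles, or multi-sensor clock
drift. Passing the recovery tests therefore demonstrates the pipeline's
bookkeeping and its robustness to the modeled error structure — not
detector performance on real seafloor imagery.

## Numerical choices and degenerate inputs

* Curation windows default to 11 samples with k = 5 — conservative for
  1 Hz survey tracks; both are configuration parameters.
* The outlier MAD floor is 1 cm; the extrapolation tolerance 5 s.
* Duplicate track timestamps collapse to their mean position (flagged);
  out-of-order rows are sorted (flagged); a non-UTC offset is a hard
  error, a zone-less timestamp a flag.
* Zero-pixel images are errors for all descriptors; a constant image has
  entropy 0 and particle count 0 (no threshold separates one level).
* Empty datasets are valid: the factory emits a header-only document.
* Test problem sizes (100 round-trip documents, 50 particle images, a
  20-image end-to-end dataset, 600-sample tracks) are the package's
  standard verification sizes; all regenerate deterministically from
  seeds.

## Known limitations

Video containers are not minted (sidecar only); handle URLs are
constructed but never registered (no live handle server); there is no
vocabulary server, no publication to long-term repositories, and no
provenance metadata — the standard itself defers provenance to a future
version. The equirectangular distance approximation is documented above.
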