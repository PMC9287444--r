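version: 1.0.0
required-fields:
  - image-datetime
  - image-latitude
  - image-longitude
  - image-depth
  - image-coordinate-reference-system
  - image-coordinate-uncertainty-meters
  - image-uuid
  - image-hash-sha256
  - image-context
  - image-project
  - image-event
  - image-platform
  - image-sensor
  - image-abstract
  - image-pi
  - image-creators
  - image-license
  - image-copyright
recommended-fields:
  - image-acquisition
  - image-deployment
  - image-illumination
  - image-capture-mode
  - image-area-square-meter
  - image-meters-above-ground
  - image-overlap-fraction
  - image-camera-housing-viewport
  - image-camera-calibration-model
  - image-objective
  - image-target-environment
  - image-fauna-attraction
  - image-temporal-constraints
optional-fields:
  - image-entropy
  - image-particle-count
  - image-average-colour
  - image-mpeg7-colorstructure
  - image-annotation-labels
  - image-annotation-creators
  - image-annotations
restricted-values:
  image-acquisition: [photo, video, slide]
  image-deployment: [mapping, stationary, survey]
  image-illumination: [sunlight, artificial light, mixed light]
  image-capture-mode: [timer, manual, mixed]
open-ended-fields: [image-deployment]
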