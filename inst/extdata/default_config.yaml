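partition:
  f_root: 0.25
  f_tip: 0.2
  f_margin: 0.2
  orientation: root-top
detector:
  root_center:
    min_threshold: 60.0
    max_threshold: 100.0
    threshold_step: 2.0
    min_repeatability: 8.0
    min_area: 4.0
    max_area: 25.0
    min_circularity: 0.8
    min_convexity: 0.8
    min_inertia_ratio: 0.5
    max_aberration: 85.0
    min_dist_between_blobs: 10.0
    polarity: dark
  tip:
    min_threshold: 60.0
    max_threshold: 100.0
    threshold_step: 2.0
    min_repeatability: 4.0
    min_area: 2.0
    max_area: 40.0
    min_circularity: 0.4
    min_convexity: 0.4
    min_inertia_ratio: 0.4
    max_aberration: 100.0
    min_dist_between_blobs: 10.0
    polarity: dark
  margin:
    min_threshold: 60.0
    max_threshold: 100.0
    threshold_step: 2.0
    min_repeatability: 4.0
    min_area: 2.0
    max_area: 40.0
    min_circularity: 0.4
    min_convexity: 0.4
    min_inertia_ratio: 0.4
    max_aberration: 100.0
    min_dist_between_blobs: 10.0
    polarity: dark
reference_colors:
  root_center:
  - - 120
    - 30
    - 45
  - - 140
    - 60
    - 70
  - - 165
    - 95
    - 95
  tip:
  - - 120
    - 30
    - 45
  - - 140
    - 60
    - 70
  - - 165
    - 95
    - 95
  margin:
  - - 120
    - 30
    - 45
  - - 140
    - 60
    - 70
  - - 165
    - 95
    - 95
pipeline:
  pad: 1.0
  iou_threshold: 0.5
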