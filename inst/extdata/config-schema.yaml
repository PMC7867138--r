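# Configuration schema for the mfce pipeline.
# Every key is optional; omitted keys keep the defaults shown here.

laser:                          # laser-dot detection
  brightness_quantile: 0.999    # intensity quantile used as threshold
  min_area: 3                   # px^2, minimum blob area
  max_area: 400                 # px^2, maximum blob area
  min_circularity: 0.6          # 4*pi*A/P^2, perimeter = boundary pixels
  max_column_offset: 12         # px, max horizontal offset of the dot pair
  expected_separation_range: [30, 600]  # px, admissible dot separation
  min_peak_margin: 30           # blob peak must exceed threshold by this

detection:                      # classical background-subtraction backend
  min_diff: 40                  # intensity units, foreground threshold
  min_area: 150                 # px^2, minimum component area

occlusion:                      # swing-foot recovery on overlap frames
  rotation_range_deg: 20        # search +/- this rotation
  rotation_step_deg: 5          # in these steps
  translation_window_px: [40, 15]   # +/- columns, +/- rows
  edge_gradient_threshold: null # null = Otsu on gradient magnitude

trajectory:                     # stride segmentation and MFC extraction
  stationary_speed: 0.5         # px/frame, stationarity threshold
  sustain: 3                    # frames of stationarity that cut a stride
  min_points: 8                 # minimum points per stride
  method: fitted_curve          # or raw_series

D: 164                          # physical inter-laser distance, mm
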