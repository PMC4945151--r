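# Calibration constants for the experiment presets: published per-line
# group means (crossings per measurement line) that the synthetic generator
# is calibrated to reproduce, plus the placement parameters that define each
# measurement. Versioned here so targets are auditable and changeable
# without code edits. All lengths in micrometres.
version: 1
barrel_layer4:
  note: >
    Mouse barrel field, layer IV, 375 um lines on septum centerlines and at
    core centroids; astrocyte and capillary group means per line.
  line_length: 375
  core_span_window: [350, 450]
  astro: {septal: 3.78, core: 11.02}
  capillary: {septal: 2.64, core: 2.97}
  ratio_astro: 0.36
  ratio_capillary: 1.05
barrel_layer3:
  note: >
    Supra-granular layer III, same line matrix transferred from layer IV by
    landmark alignment. Published prose lists the two group means in
    core-first order here (ratio < 1 fixes the reading).
  line_length: 375
  astro: {septal: 11.2, core: 16.2}
  capillary: {septal: 1.66, core: 1.69}
  ratio_astro: 0.79
barrel_layer5:
  note: >
    Infra-granular layer V, septa-first order in the published prose.
  line_length: 375
  astro: {septal: 9.4, core: 14.3}
  capillary: {septal: 2.46, core: 1.73}
  ratio_astro: 0.68
auditory_A1A2:
  note: >
    Rat auditory cortex: 50 um lines at 50 and 200 um from the A1/A2 border
    on both sides; ten 25 x 100 um density bands centered on the border.
    Each side's fiber density is calibrated to its 50 um-offset mean.
  line_length: 50
  offsets: [50, 200]
  astro: {A1_50: 14.1, A1_200: 13.96, A2_50: 7.4, A2_200: 7.18}
  band: {width: 25, length: 100, count: 10}
  density_drop_pct: 37
human_IIIaIIIb:
  note: >
    Human V1 sublayers IIIa/IIIb: 375 um lines at 50 and 200 um from the
    border on both sides; ten 30 um wide perpendicular density bands.
  line_length: 375
  offsets: [50, 200]
  astro: {IIIa_50: 27.2, IIIa_200: 28.5, IIIb_50: 13.3, IIIb_200: 12.4}
  band: {width: 30, length: 100, count: 10}
  density_drop_pct: 66
human_blobs:
  note: >
    Human V1 CO blobs: 500 um vertical lines at blob centers, inter-blob
    centers and inter-blob left margins; ~1 mm blob period.
  line_length: 500
  period: 1000
  astro: {blob_center: 5.25, interblob_center: 11.25, interblob_margin: 12.1}
thickness_4v8:
  note: >
    Section-thickness control: thin (4 um) sections retain ~65% of the
    8 um-section crossings; the septa/core ratio is unchanged
    (0.37 vs 0.36).
  retention: 0.65
  ratio_4um: 0.37
  ratio_8um: 0.36
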