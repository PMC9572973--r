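# Worked-example band observations: three test compounds spiked into artificial
# honey (A = syringic acid and B = kaempferol, both present in the reference
# library; C = acetylsalicylic acid, a negative control absent from it).
# Each entry carries the measured band attributes for one database view and the
# codes of the standards that passed the Rf +/-0.05 primary filter on that run.
# Run-specific Rf values drift slightly between plates, so the Rf-stage
# survivor list is part of the recorded observation rather than something the
# packaged library (which stores reference-run Rf values) can regenerate.
compound_a:
  mpa_np:
    view: "1A"
    band:
      rf: 0.608
      hue_dev254: 139.3
      hue_dev366: 180.0
      hue_np366: 209.2
      fl_pre_max: 225
      fl_pre_min: 258
      uv_pre: [276]
      fl_np_max: 239
      uv_np_max: 288
    rf_candidates: [36, 43, 48, 58, 67, 103, 12, 14, 55, 59, 70, 39, 45, 50,
                    52, 54, 56, 61, 62, 65, 66, 71, 31, 32, 74, 79, 82, 84,
                    87, 98, 99, 3, 4, 15, 16, 25, 37, 72, 73, 94, 7, 8]
  mpa_vsa:
    view: "1B"
    band:
      rf: 0.580
      hue_dev254: 137.0
      hue_dev366: 180.0
      hue_vsa366: 204.0
      hue_vsa_white: 14.0
      fl_pre_max: 224
      fl_pre_min: 257
      uv_pre: [277]
      fl_vs_max: 251
      uv_vs_max: 354
    rf_candidates: [48, 58, 36, 43, 4, 10, 59, 15, 16, 31, 37, 39, 45, 52,
                    55, 56, 61, 65, 71, 73, 74, 25, 78, 84, 87, 98, 62, 66,
                    77, 82, 103, 8]
compound_b:
  mpa_np:
    view: "1A"
    band:
      rf: 0.685
      hue_dev254: 121.0
      hue_dev366: 152.0
      hue_np366: 147.0
      fl_pre_max: 224
      fl_pre_min: 255
      uv_pre: [269, 369]
      fl_np_max: 245
      uv_np_max: 288
# Final survivor lists per view for the negative control, and the
# within-mobile-phase consolidation they imply.
compound_c:
  final_1a: [18, 20, 40, 43, 51, 53, 67, 79, 82, 85]
  final_1b: [18, 20, 25, 40, 51, 67, 85]
  final_2a: [43, 67, 82, 84, 85, 87]
  final_2b: [67, 85]
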