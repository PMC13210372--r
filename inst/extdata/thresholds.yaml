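C1:
  default: 0.7
  strata:
    lt28: 0.6
    s28to32: 0.65
    s32to37: 0.7
    ge37: 0.75
C2:
  default: 0.7
  strata:
    lt28: 0.6
    s28to32: 0.65
    s32to37: 0.7
    ge37: 0.75
C3:
  default: 0.7
  strata:
    lt28: 0.6
    s28to32: 0.65
    s32to37: 0.7
    ge37: 0.75
C4:
  default: 0.7
  strata:
    lt28: 0.6
    s28to32: 0.65
    s32to37: 0.7
    ge37: 0.75
C5:
  rms: 0.3
  sustained_s: 0.5
C6:
  f0_hz:
    lt28: 450.0
    s28to32: 450.0
    s32to37: 450.0
    ge37: 500.0
C7:
  hnr: 0.5
  irregularity: 0.3
C8:
  pause_s: 0.2
C9:
  rel_increase: 0.15
  abs_bpm: 180.0
C10:
  drop_points: 4.0
  window_s: 30.0
  abs_pct: 92.0
C11:
  cv: 0.25
  window_s: 60.0
C12:
  increase_mmhg: 10.0
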