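{
  "name": "chlorophyll-b (synthetic line list)",
  "stage": "early",
  "lines": [
    {"mode": 101, "wavenumber_cm1": 702.4, "activity_A4_AMU": 12.1},
    {"mode": 118, "wavenumber_cm1": 986.3, "activity_A4_AMU": 27.9},
    {"mode": 131, "wavenumber_cm1": 1396.0, "activity_A4_AMU": 188.4},
    {"mode": 137, "wavenumber_cm1": 1430.0, "activity_A4_AMU": 96.2},
    {"mode": 142, "wavenumber_cm1": 1489.0, "activity_A4_AMU": 311.7},
    {"mode": 144, "wavenumber_cm1": 1501.0, "activity_A4_AMU": 154.0},
    {"mode": 151, "wavenumber_cm1": 1572.0, "activity_A4_AMU": 82.5},
    {"mode": 156, "wavenumber_cm1": 1629.0, "activity_A4_AMU": 246.3},
    {"mode": 168, "wavenumber_cm1": 1711.8, "activity_A4_AMU": 401.0}
  ]
}
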