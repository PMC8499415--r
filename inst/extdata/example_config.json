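{
  "out_dir": "out",
  "sites": [
    {
      "site_id": "demo",
      "stl": "synthetic_tooth_ribbon.stl",
      "plane_offset": 0
    }
  ],
  "smoothing": 0.005,
  "h": 0.01
}
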