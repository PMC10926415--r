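{
  "night_0003.jpg99152": {
    "filename": "night_0003.jpg",
    "size": 99152,
    "regions": [
      {
        "shape_attributes": {"name": "circle", "cx": 120.5, "cy": 80.25, "r": 14},
        "region_attributes": {"score": "0.91"}
      },
      {
        "shape_attributes": {"name": "point", "cx": 40, "cy": 60},
        "region_attributes": {}
      },
      {
        "shape_attributes": {"name": "polyline", "all_points_x": [3.5, 20, 41.25], "all_points_y": [10, 12, 18]},
        "region_attributes": {"score": "not-a-number", "species": "bogong"}
      }
    ],
    "file_attributes": {}
  }
}
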