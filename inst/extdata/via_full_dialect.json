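{
  "_via_settings": {"ui": {}, "core": {}, "project": {"name": "hand-written fixture"}},
  "_via_img_metadata": {
    "night_0001.jpg162690": {
      "filename": "night_0001.jpg",
      "size": 162690,
      "regions": [
        {
          "shape_attributes": {"name": "polyline", "all_points_x": [0, 10], "all_points_y": [0, 0]},
          "region_attributes": {"score": "0.875"}
        },
        {
          "shape_attributes": {"name": "rect", "x": 5, "y": 5, "width": 10, "height": 10},
          "region_attributes": {}
        }
      ],
      "file_attributes": {"exposure_time": "0.1111111111111111"}
    },
    "night_0002.jpg0": {
      "filename": "night_0002.jpg",
      "size": 0,
      "regions": [],
      "file_attributes": {}
    }
  },
  "_via_attributes": {"region": {}, "file": {}}
}
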