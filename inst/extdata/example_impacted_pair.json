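{
  "schema": "supradent3d-landmarks-1",
  "coordinate_frame": "right-handed mm; +x patient left; +y anterior; +z cranial",
  "case_id": "example-pair",
  "metadata": {
    "note": "synthetic example of one impacted pair"
  },
  "volume_bounds": {
    "min": [9.4000000000000004, 22.899999999999999, -23.800000000000001],
    "max": [28.5, 42.799999999999997, 6.5999999999999996]
  },
  "teeth": [
    {
      "tooth_id": "33",
      "jaw": "mandible",
      "region": "canine",
      "status": "impacted_unresolved",
      "apex_in_volume": true,
      "landmarks": {
        "occlusal_center": [18.199999999999999, 32, -1.5],
        "apex": [20.100000000000001, 30.5, -17.800000000000001],
        "cej_labial": [16.5, 29.199999999999999, -9.5999999999999996],
        "cej_lingual": [20.899999999999999, 33.799999999999997, -9.4000000000000004],
        "crown_mesial": [15.4, 33.899999999999999, -4.0999999999999996],
        "crown_distal": [21.300000000000001, 30.399999999999999, -4.2999999999999998],
        "crown_buccal": [15.9, 28.899999999999999, -4.4000000000000004],
        "crown_lingual": [20.600000000000001, 34.600000000000001, -4]
      },
      "cusp_tips": [
        [18.199999999999999, 32, -1.5]
      ]
    },
    {
      "tooth_id": "33,",
      "jaw": "mandible",
      "region": "canine",
      "status": "impacted_unresolved",
      "apex_in_volume": true,
      "landmarks": {
        "occlusal_center": [20.399999999999999, 34.899999999999999, 0.59999999999999998],
        "apex": [21.699999999999999, 33.799999999999997, -10.9],
        "cej_labial": [19.199999999999999, 32.899999999999999, -6.2999999999999998],
        "cej_lingual": [22.300000000000001, 36.200000000000003, -6.0999999999999996],
        "crown_mesial": [18.399999999999999, 36.200000000000003, -1.2],
        "crown_distal": [22.5, 33.799999999999997, -1.3999999999999999],
        "crown_buccal": [18.800000000000001, 32.700000000000003, -1.5],
        "crown_lingual": [22.100000000000001, 36.799999999999997, -1.1000000000000001]
      },
      "cusp_tips": [
        [20.399999999999999, 34.899999999999999, 0.59999999999999998]
      ]
    }
  ]
}
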