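{
  "label": "breadfruit_final",
  "criteria": {
    "temperature": {"abs_min": 17, "opt_min": 21, "opt_max": 33, "abs_max": 40, "units": "degC"},
    "rainfall": {"abs_min": 750, "opt_min": 1500, "opt_max": 4000, "abs_max": 8000, "units": "mm/yr"},
    "solar_radiation": {"abs_min": 20, "opt_min": 50, "opt_max": 197, "abs_max": 295, "units": "W/m2"},
    "soil_ph": {"abs_min": 4, "opt_min": 5, "opt_max": 6.5, "abs_max": 8.7, "units": "pH"},
    "drainage_class": {"abs_min": 2, "opt_min": 4, "opt_max": 6, "abs_max": 7, "units": "class 1-7"}
  }
}
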