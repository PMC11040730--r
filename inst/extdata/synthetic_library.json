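[
  {
    "name": "olefin_E",
    "shift_sigma": 0.1,
    "resonances": [
      {
        "shift_ppm": 7.68,
        "weight": 1,
        "fwhm_hz": 2,
        "couplings": [
          {
            "j_hz": 16,
            "n": 1
          }
        ]
      },
      {
        "shift_ppm": 6.44,
        "weight": 1,
        "fwhm_hz": 2,
        "couplings": [
          {
            "j_hz": 16,
            "n": 1
          }
        ]
      },
      {
        "shift_ppm": 3.8,
        "weight": 3,
        "fwhm_hz": 2
      },
      {
        "shift_ppm": 7.45,
        "weight": 2,
        "fwhm_hz": 2
      },
      {
        "shift_ppm": 7.38,
        "weight": 3,
        "fwhm_hz": 2
      }
    ]
  },
  {
    "name": "olefin_Z",
    "shift_sigma": 0.1,
    "resonances": [
      {
        "shift_ppm": 6.95,
        "weight": 1,
        "fwhm_hz": 2,
        "couplings": [
          {
            "j_hz": 12,
            "n": 1
          }
        ]
      },
      {
        "shift_ppm": 5.95,
        "weight": 1,
        "fwhm_hz": 2,
        "couplings": [
          {
            "j_hz": 12,
            "n": 1
          }
        ]
      },
      {
        "shift_ppm": 3.7,
        "weight": 3,
        "fwhm_hz": 2
      },
      {
        "shift_ppm": 7.6,
        "weight": 2,
        "fwhm_hz": 2
      },
      {
        "shift_ppm": 7.35,
        "weight": 3,
        "fwhm_hz": 2
      }
    ]
  },
  {
    "name": "aldehyde",
    "shift_sigma": 0.1,
    "resonances": [
      {
        "shift_ppm": 10.02,
        "weight": 1,
        "fwhm_hz": 2
      },
      {
        "shift_ppm": 7.88,
        "weight": 2,
        "fwhm_hz": 2
      },
      {
        "shift_ppm": 7.52,
        "weight": 2,
        "fwhm_hz": 2
      },
      {
        "shift_ppm": 7.6,
        "weight": 1,
        "fwhm_hz": 2
      }
    ]
  }
]
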