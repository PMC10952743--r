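[
  {
    "name": "edu",
    "peaks": [
      {
        "center": 2120,
        "fwhm": 25,
        "amplitude": 1,
        "shape": "gaussian"
      }
    ],
    "band_window": [2090, 2150],
    "rie_height": 1
  },
  {
    "name": "metallacarborane",
    "peaks": [
      {
        "center": 2520,
        "fwhm": 60,
        "amplitude": 1.9146967031803,
        "shape": "gaussian"
      },
      {
        "center": 2565,
        "fwhm": 55,
        "amplitude": 2.55292893757374,
        "shape": "gaussian"
      },
      {
        "center": 2605,
        "fwhm": 50,
        "amplitude": 2.16998959693768,
        "shape": "gaussian"
      },
      {
        "center": 635,
        "fwhm": 15,
        "amplitude": 0.765878681272121,
        "shape": "gaussian"
      },
      {
        "center": 250,
        "fwhm": 25,
        "amplitude": 0.510585787514747,
        "shape": "gaussian"
      },
      {
        "center": 200,
        "fwhm": 20,
        "amplitude": 0.638232234393434,
        "shape": "gaussian"
      }
    ],
    "band_window": [2480, 2650],
    "rie_height": 3
  },
  {
    "name": "ortho_carborane",
    "peaks": [
      {
        "center": 2575,
        "fwhm": 45,
        "amplitude": 1.80325410774522,
        "shape": "gaussian"
      },
      {
        "center": 2610,
        "fwhm": 40,
        "amplitude": 1.26227787542166,
        "shape": "gaussian"
      },
      {
        "center": 635,
        "fwhm": 15,
        "amplitude": 0.450813526936306,
        "shape": "gaussian"
      }
    ],
    "band_window": [2480, 2650],
    "rie_height": 2
  },
  {
    "name": "am_ester",
    "peaks": [
      {
        "center": 2220,
        "fwhm": 22,
        "amplitude": 11.8468823238684,
        "shape": "gaussian"
      }
    ],
    "band_window": [2190, 2250],
    "rie_height": 12
  },
  {
    "name": "imidazole",
    "peaks": [
      {
        "center": 2220,
        "fwhm": 22,
        "amplitude": 10.8596421302127,
        "shape": "gaussian"
      }
    ],
    "band_window": [2190, 2250],
    "rie_height": 11
  },
  {
    "name": "stearic_d35",
    "peaks": [
      {
        "center": 2102,
        "fwhm": 20,
        "amplitude": 1.50462917980723,
        "shape": "gaussian"
      },
      {
        "center": 2195,
        "fwhm": 24,
        "amplitude": 0.451388753942168,
        "shape": "gaussian"
      }
    ],
    "band_window": [2080, 2130],
    "rie_height": 1.5
  },
  {
    "name": "cosan_d2",
    "peaks": [
      {
        "center": 2260.4,
        "fwhm": 10,
        "amplitude": 0.781597081162112,
        "shape": "gaussian"
      },
      {
        "center": 2273.4,
        "fwhm": 10,
        "amplitude": 0.97699635145264,
        "shape": "gaussian"
      },
      {
        "center": 2520,
        "fwhm": 60,
        "amplitude": 1.9146967031803,
        "shape": "gaussian"
      },
      {
        "center": 2565,
        "fwhm": 55,
        "amplitude": 2.55292893757374,
        "shape": "gaussian"
      },
      {
        "center": 2605,
        "fwhm": 50,
        "amplitude": 2.16998959693768,
        "shape": "gaussian"
      },
      {
        "center": 635,
        "fwhm": 15,
        "amplitude": 0.765878681272121,
        "shape": "gaussian"
      },
      {
        "center": 250,
        "fwhm": 25,
        "amplitude": 0.510585787514747,
        "shape": "gaussian"
      },
      {
        "center": 200,
        "fwhm": 20,
        "amplitude": 0.638232234393434,
        "shape": "gaussian"
      }
    ],
    "band_window": [2245, 2290],
    "rie_height": 1
  },
  {
    "name": "protein_ch3",
    "peaks": [
      {
        "center": 2930,
        "fwhm": 55,
        "amplitude": 1,
        "shape": "gaussian"
      },
      {
        "center": 2875,
        "fwhm": 50,
        "amplitude": 0.35,
        "shape": "gaussian"
      }
    ],
    "band_window": [2900, 2960],
    "rie_height": null
  },
  {
    "name": "lipid_ch2",
    "peaks": [
      {
        "center": 2851,
        "fwhm": 40,
        "amplitude": 1,
        "shape": "gaussian"
      },
      {
        "center": 2885,
        "fwhm": 45,
        "amplitude": 0.45,
        "shape": "gaussian"
      }
    ],
    "band_window": [2830, 2875],
    "rie_height": null
  }
]
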