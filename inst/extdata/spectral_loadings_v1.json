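{
  "version": "1",
  "description": "Frozen trait-to-spectrum loading calibration for the greenhouse imaging simulator. Each trait perturbs the species baseline by sum_k amplitude_k * exp(-(lambda - center_nm_k)^2 / (2 * sigma_nm_k^2)) per unit of (trait - reference). Amplitudes are reflectance units per trait unit. Water content deepens the NIR/SWIR water absorption troughs; nitrogen deepens visible chlorophyll absorption; sodium and boron carry zero loading by construction (spectrally silent traits).",
  "traits": {
    "wc": {
      "unit": "percent",
      "reference": 80,
      "components": [
        {"center_nm": 970,  "sigma_nm": 25, "amplitude": -0.0016},
        {"center_nm": 1240, "sigma_nm": 35, "amplitude": -0.0028},
        {"center_nm": 1450, "sigma_nm": 60, "amplitude": -0.0040}
      ]
    },
    "n": {
      "unit": "percent",
      "reference": 3.0,
      "components": [
        {"center_nm": 660,  "sigma_nm": 45, "amplitude": -0.0120},
        {"center_nm": 1510, "sigma_nm": 35, "amplitude": -0.0040}
      ]
    },
    "p": {
      "unit": "percent",
      "reference": 0.30,
      "components": [
        {"center_nm": 1680, "sigma_nm": 30, "amplitude": -0.1200}
      ]
    },
    "k": {
      "unit": "percent",
      "reference": 2.2,
      "components": [
        {"center_nm": 810, "sigma_nm": 55, "amplitude": -0.0100}
      ]
    },
    "mg": {
      "unit": "percent",
      "reference": 0.40,
      "components": [
        {"center_nm": 590, "sigma_nm": 30, "amplitude": -0.0800}
      ]
    },
    "ca": {
      "unit": "percent",
      "reference": 1.3,
      "components": [
        {"center_nm": 1540, "sigma_nm": 45, "amplitude": -0.0300}
      ]
    },
    "s": {
      "unit": "percent",
      "reference": 0.22,
      "components": [
        {"center_nm": 1060, "sigma_nm": 40, "amplitude": -0.1500}
      ]
    },
    "na": {
      "unit": "percent",
      "reference": 0.008,
      "components": []
    },
    "fe": {
      "unit": "ppm",
      "reference": 100,
      "components": [
        {"center_nm": 720, "sigma_nm": 28, "amplitude": -0.00030}
      ]
    },
    "mn": {
      "unit": "ppm",
      "reference": 65,
      "components": [
        {"center_nm": 930, "sigma_nm": 40, "amplitude": -0.00025}
      ]
    },
    "b": {
      "unit": "ppm",
      "reference": 40,
      "components": []
    },
    "cu": {
      "unit": "ppm",
      "reference": 12,
      "components": [
        {"center_nm": 1620, "sigma_nm": 40, "amplitude": -0.00200}
      ]
    },
    "zn": {
      "unit": "ppm",
      "reference": 40,
      "components": [
        {"center_nm": 860, "sigma_nm": 40, "amplitude": -0.00060}
      ]
    }
  }
}
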