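{
  "root": {
    "type": "split",
    "feature": "peak_slur_angle",
    "threshold": 26.5486532584675,
    "left": {
      "type": "leaf",
      "class": "relevant"
    },
    "right": {
      "type": "split",
      "feature": "amp_ratio_peak_slur",
      "threshold": 1.64613860384693,
      "left": {
        "type": "leaf",
        "class": "relevant"
      },
      "right": {
        "type": "leaf",
        "class": "irrelevant"
      }
    }
  },
  "features": ["slur_limb_angle", "peak_slur_angle", "amp_ratio_peak_slur"],
  "version": {
    "package": "0.1.0",
    "trained_on": "synthetic-slur-corpus-n500",
    "seed": 7,
    "n_examples": 500,
    "training_accuracy": 0.988
  }
}
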