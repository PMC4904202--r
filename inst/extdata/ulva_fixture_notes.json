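{
  "source": "printed duplicate-summary tables packaged with this analysis",
  "suspect_cells": [
    {
      "run": 2,
      "column": "xylose_sd",
      "printed": "0.125.0 (garbled)",
      "carried_as": 0.1,
      "note": "with sd 0.1 the reconstructed duplicates reproduce the printed S/N 14.80 within 0.01 dB"
    },
    {
      "run": 1,
      "column": "glucuronic_acid_sd",
      "printed": 163.6,
      "carried_as": 163.6,
      "note": "duplicates the total_sd of the same run and is inconsistent with the printed S/N 47.21; excluded from exact-reproduction tests"
    }
  ]
}
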