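{
  "name": "mc2_vs_rest_v1",
  "description": "Five-feature linear radiomic signature discriminating the MC-II molecular subtype from the other subtypes; pyradiomics feature names, raw (unscaled) feature values.",
  "intercept": -1.9203568703,
  "terms": {
    "original_firstorder_Maximum": 0.0010095229,
    "original_firstorder_RootMeanSquared": -0.0004598256,
    "original_glcm_MaximumProbability": 7.4677789388,
    "original_glrlm_GrayLevelNonUniformityNormalized": 4.5385695277,
    "original_ngtdm_Busyness": 0.0234377968
  }
}
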