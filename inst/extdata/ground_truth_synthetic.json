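{
  "cytokine": {
    "planted_positive": ["GCSF_like", "IL9_like", "MIP2_like"],
    "planted_negative": ["IL12_like", "TNFa_like"],
    "null_analytes": ["MCP1_like", "CYT01_null", "CYT02_null", "CYT03_null", "CYT04_null", "CYT05_null", "CYT06_null", "CYT07_null", "CYT08_null", "CYT09_null", "CYT10_null", "CYT11_null", "CYT12_null", "CYT13_null", "CYT14_null", "CYT15_null", "CYT16_null", "CYT17_null", "CYT18_null", "CYT19_null", "CYT20_null", "CYT21_null", "CYT22_null", "CYT23_null", "CYT24_null", "CYT25_null", "CYT26_null"],
    "target_condition": "hypoxia_bFGF"
  },
  "phospho": {
    "planted_positive": ["pcJun_like", "pMek1_like", "pAtf2_like"],
    "planted_negative": ["pp38_like", "pJnk_like"],
    "null_analytes": ["pStat1_like", "PP01_null", "PP02_null"],
    "target_condition": "hypoxia_bFGF"
  },
  "seed": 101
}
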