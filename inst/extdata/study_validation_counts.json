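{
  "sites_initial": 2221,
  "attempted": 1104,
  "tripleton_sites": 91,
  "doubleton_sites": 207,
  "tripleton_validated": 91,
  "doubleton_validated": 205,
  "wga_only_singletons": 336,
  "refuted": 49,
  "not_covered": 20,
  "wga_artifact": 35,
  "homalt_reclassified": 11,
  "reincluded_dbsnp": 72,
  "retained_total_printed": 663
}
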