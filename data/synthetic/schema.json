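{
  "id": "id",
  "group": "group",
  "covariate": ["age", "sex", "tiv"],
  "gm": ["gm_001", "gm_002", "gm_003", "gm_004", "gm_005", "gm_006", "gm_007", "gm_008", "gm_009", "gm_010", "gm_011", "gm_012", "gm_013", "gm_014", "gm_015", "gm_016", "gm_017", "gm_018", "gm_019", "gm_020", "gm_021", "gm_022", "gm_023", "gm_024", "gm_025", "gm_026", "gm_027", "gm_028", "gm_029", "gm_030", "gm_031", "gm_032", "gm_033", "gm_034", "gm_035", "gm_036", "gm_037", "gm_038", "gm_039", "gm_040", "gm_041", "gm_042", "gm_043", "gm_044", "gm_045", "gm_046", "gm_047", "gm_048", "gm_049", "gm_050", "gm_051", "gm_052", "gm_053", "gm_054", "gm_055", "gm_056", "gm_057", "gm_058", "gm_059", "gm_060", "gm_061", "gm_062", "gm_063", "gm_064", "gm_065", "gm_066", "gm_067", "gm_068"],
  "wm": ["wm_001", "wm_002", "wm_003", "wm_004", "wm_005", "wm_006", "wm_007", "wm_008", "wm_009", "wm_010", "wm_011", "wm_012", "wm_013", "wm_014", "wm_015", "wm_016", "wm_017", "wm_018", "wm_019", "wm_020", "wm_021", "wm_022", "wm_023", "wm_024", "wm_025", "wm_026", "wm_027", "wm_028", "wm_029", "wm_030", "wm_031", "wm_032", "wm_033", "wm_034", "wm_035", "wm_036", "wm_037", "wm_038", "wm_039", "wm_040", "wm_041", "wm_042", "wm_043", "wm_044", "wm_045", "wm_046", "wm_047", "wm_048"],
  "cognition": ["processing_speed", "working_memory", "episodic_memory", "executive_function"]
}
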