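{
  "catalog": "Brenk",
  "comment": "Curated minimal structural alerts for unwanted groups in pattern-graph form. Not the full published catalog.",
  "patterns": [
    {"name": "nitro",
     "atoms": [{"elem": ["N"], "maxH": 0}, {"elem": ["O"], "maxH": 0}, {"elem": ["O"]}],
     "bonds": [[1, 2, 2], [1, 3, 0]]},
    {"name": "thiocarbonyl",
     "atoms": [{"elem": ["C"]}, {"elem": ["S"], "maxH": 0}],
     "bonds": [[1, 2, 2]]},
    {"name": "hydrazine",
     "atoms": [{"elem": ["N"], "minH": 1}, {"elem": ["N"], "minH": 1}],
     "bonds": [[1, 2, 1]]},
    {"name": "trihalomethyl",
     "atoms": [{"elem": ["C"]}, {"elem": ["F", "Cl", "Br", "I"]}, {"elem": ["F", "Cl", "Br", "I"]}, {"elem": ["F", "Cl", "Br", "I"]}],
     "bonds": [[1, 2, 1], [1, 3, 1], [1, 4, 1]]},
    {"name": "aldehyde",
     "atoms": [{"elem": ["C"], "minH": 1}, {"elem": ["O"], "maxH": 0}],
     "bonds": [[1, 2, 2]]},
    {"name": "azide",
     "atoms": [{"elem": ["N"]}, {"elem": ["N"], "maxH": 0}, {"elem": ["N"]}],
     "bonds": [[1, 2, 2], [2, 3, 2]]}
  ]
}
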