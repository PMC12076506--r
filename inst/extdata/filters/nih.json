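{
  "catalog": "NIH",
  "comment": "Curated minimal reactive/undesirable-functionality alerts in pattern-graph form (atoms: allowed elements, min/max attached hydrogens; bonds: [i, j, order] with order 0 = any, 4 = aromatic). Not the full published catalog.",
  "patterns": [
    {"name": "aldehyde",
     "atoms": [{"elem": ["C"], "minH": 1}, {"elem": ["O"], "maxH": 0}],
     "bonds": [[1, 2, 2]]},
    {"name": "acyl_halide",
     "atoms": [{"elem": ["C"]}, {"elem": ["O"], "maxH": 0}, {"elem": ["F", "Cl", "Br", "I"]}],
     "bonds": [[1, 2, 2], [1, 3, 1]]},
    {"name": "michael_acceptor",
     "atoms": [{"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["O"], "maxH": 0}],
     "bonds": [[1, 2, 2], [2, 3, 1], [3, 4, 2]],
     "nonring_bonds": [[1, 2]]},
    {"name": "quinone",
     "atoms": [{"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["C"]},
               {"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["O"], "maxH": 0}, {"elem": ["O"], "maxH": 0}],
     "bonds": [[1, 2, 1], [2, 3, 2], [3, 4, 1], [4, 5, 1], [5, 6, 2], [6, 1, 1],
               [1, 7, 2], [4, 8, 2]]},
    {"name": "epoxide",
     "atoms": [{"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["O"], "maxH": 0}],
     "bonds": [[1, 2, 1], [2, 3, 1], [1, 3, 1]]},
    {"name": "isocyanate",
     "atoms": [{"elem": ["N"]}, {"elem": ["C"]}, {"elem": ["O"], "maxH": 0}],
     "bonds": [[1, 2, 2], [2, 3, 2]]},
    {"name": "hydrazine",
     "atoms": [{"elem": ["N"], "minH": 1}, {"elem": ["N"], "minH": 1}],
     "bonds": [[1, 2, 1]]},
    {"name": "thiol",
     "atoms": [{"elem": ["S"], "minH": 1}, {"elem": ["C"]}],
     "bonds": [[1, 2, 1]]}
  ]
}
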