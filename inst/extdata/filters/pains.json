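{
  "catalog": "PAINS",
  "comment": "Curated minimal pan-assay-interference alerts in pattern-graph form. Not the full published catalog.",
  "patterns": [
    {"name": "quinone",
     "atoms": [{"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["C"]},
               {"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["O"], "maxH": 0}, {"elem": ["O"], "maxH": 0}],
     "bonds": [[1, 2, 1], [2, 3, 2], [3, 4, 1], [4, 5, 1], [5, 6, 2], [6, 1, 1],
               [1, 7, 2], [4, 8, 2]]},
    {"name": "catechol",
     "atoms": [{"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["C"]},
               {"elem": ["C"]}, {"elem": ["C"]}, {"elem": ["O"], "minH": 1}, {"elem": ["O"], "minH": 1}],
     "bonds": [[1, 2, 0], [2, 3, 0], [3, 4, 0], [4, 5, 0], [5, 6, 0], [6, 1, 0],
               [1, 7, 1], [2, 8, 1]]},
    {"name": "rhodanine",
     "atoms": [{"elem": ["S"]}, {"elem": ["C"]}, {"elem": ["N"]}, {"elem": ["C"]},
               {"elem": ["C"]}, {"elem": ["S"], "maxH": 0}, {"elem": ["O"], "maxH": 0}],
     "bonds": [[1, 2, 1], [2, 3, 1], [3, 4, 1], [4, 5, 1], [5, 1, 1],
               [2, 6, 2], [4, 7, 2]]},
    {"name": "azo_aryl",
     "atoms": [{"elem": ["C"]}, {"elem": ["N"], "maxH": 0}, {"elem": ["N"], "maxH": 0}, {"elem": ["C"]}],
     "bonds": [[1, 2, 1], [2, 3, 2], [3, 4, 1]]}
  ]
}
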