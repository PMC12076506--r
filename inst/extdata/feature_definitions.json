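{
 "comment": "Hydrogen-bond donor/acceptor feature definitions, version 1. The SMARTS mirror the default feature-factory definitions of the standard cheminformatics toolkit; the package's rule-based typer implements the same chemistry on its bond-matrix graphs (rules field).",
 "families": {
  "donor": {
   "smarts": [
    "[$([N;!H0;v3]),$([N;!H0;+1;v4]),$([O,S;H1;+0]),$([n;H1;+0])]"
   ],
   "rules": "N or O carrying at least one explicit or implicit hydrogen; S with exactly one hydrogen."
  },
  "acceptor": {
   "smarts": [
    "[$([O,S;H1;v2]-[!$(*=[O,N,P,S])]),$([O,S;H0;v2]),$([O;-]),$([N;v3;!$(N-*=[O,N,P,S])]),$([nH0]),$([o,s;+0])]"
   ],
   "rules": "O without hydrogens; hydroxyl O (or S-H) whose neighbour has no double bond to O/N/P/S; hydrogen-free divalent or aromatic S; trivalent N not adjacent to an atom double-bonded to O/N/P/S and (if aromatic) hydrogen-free."
  }
 }
}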