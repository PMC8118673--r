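{
 "engine": "minihf (restricted Hartree-Fock, McMurchie-Davidson integrals)",
 "basis": "6-31+G*",
 "charge": 0,
 "multiplicity": 1,
 "symbols": [
  "C",
  "O",
  "N",
  "N",
  "H",
  "H",
  "H",
  "H"
 ],
 "coords_angstrom": [
  [
   -0.00927786,
   0.0045374,
   -0.50992007
  ],
  [
   -0.01805462,
   0.02714522,
   -1.71219328
  ],
  [
   -1.15214635,
   -0.07694299,
   0.24549984
  ],
  [
   1.14938084,
   0.06085785,
   0.22577881
  ],
  [
   -1.12100942,
   0.29746988,
   1.17087597
  ],
  [
   -1.99391395,
   0.10554267,
   -0.25614389
  ],
  [
   1.15894733,
   -0.3471501,
   1.13643128
  ],
  [
   1.98607404,
   -0.07145993,
   -0.30032865
  ]
 ],
 "e_hf_hartree": -223.99425654822318,
 "eps_occ_hartree": [
  -20.52933281061726,
  -15.592283252073196,
  -15.591964670809023,
  -11.385863929715967,
  -1.408744732524684,
  -1.244970646174998,
  -1.1895995182072783,
  -0.8348296804473927,
  -0.7493879800664222,
  -0.7364148636150647,
  -0.6502919393408504,
  -0.6145430647577663,
  -0.6085390325289631,
  -0.4487397394191286,
  -0.43860275140962546,
  -0.4220920484115443
 ],
 "n_occ": 16,
 "n_basis": 84,
 "ao_atom": [
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  1,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  2,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  3,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  4,
  5,
  5,
  6,
  6,
  7,
  7,
  8,
  8
 ],
 "core_dipoles_note": "core_dipoles.txt rows: (core MO, occ MO) pairs in row-major order, columns x y z (a.u.)"
}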