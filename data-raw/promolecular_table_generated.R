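promolecular_shells <- tibble::tribble(
  ~element, ~c, ~zeta,
  "H", 0.31830989, 0.5,
  "He", 3.0592253, 0.2962963,
  "Li", 12.400167, 0.18583216,
  "Li", 0.026914302, 1.1775637,
  "Be", 31.850913, 0.13569257,
  "Be", 0.22711748, 0.74028431,
  "B", 65.234671, 0.10684902,
  "B", 0.87203785, 0.54677674,
  "C", 116.21162, 0.088141449,
  "C", 2.6001514, 0.42432449,
  "N", 188.49513, 0.075017629,
  "N", 6.7125792, 0.34279033,
  "O", 285.89673, 0.065292051,
  "O", 20.460807, 0.27989278,
  "F", 412.04392, 0.0578028,
  "F", 44.229312, 0.23955357,
  "Ne", 570.68311, 0.051855924,
  "Ne", 84.144633, 0.20951281,
  "Na", 763.79585, 0.047054838,
  "Na", 153.95572, 0.17594095,
  "Na", 0.026667636, 1.1996339,
  "Mg", 995.98623, 0.043070403,
  "Mg", 242.61376, 0.15424245,
  "Mg", 0.17094878, 0.83273265,
  "Al", 1270.752, 0.039710905,
  "Al", 360.16653, 0.13601341,
  "Al", 0.5918544, 0.64230706,
  "Si", 1592.3981, 0.036833769,
  "Si", 493.89974, 0.12297293,
  "Si", 1.0609551, 0.57668199,
  "P", 1964.1171, 0.034345849,
  "P", 659.49588, 0.11208631,
  "P", 2.0366097, 0.50299645,
  "S", 2389.5087, 0.032173169,
  "S", 844.38333, 0.10312708,
  "S", 3.6042985, 0.44519057,
  "Cl", 2872.2206, 0.0302592,
  "Cl", 1058.6642, 0.0955395,
  "Cl", 6.1469239, 0.39606334,
  "Ar", 3416.2727, 0.028559189,
  "Ar", 1290.1776, 0.089101816,
  "Ar", 8.8757022, 0.3545091
)
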