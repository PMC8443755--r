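# Amino-acid naming constants shared across modules.

STANDARD_AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

AA3_TO_1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

AA1 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")
AA1_TO_3 <- setNames(names(AA3_TO_1), AA3_TO_1)

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")
BACKBONE_NAMES <- c("N", "CA", "C", "O", "OXT")
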