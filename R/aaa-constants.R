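# Amino-acid code tables (20 standard residues). Kept in an
# early-sorting file because other files use them at load time.

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

AA_ONE_TO_THREE <- stats::setNames(names(AA_THREE_TO_ONE),
                                   unname(AA_THREE_TO_ONE))

AA_CODES <- unname(AA_THREE_TO_ONE)

aa_three_to_one <- function(x) {
  out <- AA_THREE_TO_ONE[toupper(x)]
  out[is.na(out)] <- "X"
  unname(out)
}

aa_one_to_three <- function(x) {
  out <- AA_ONE_TO_THREE[toupper(x)]
  out[is.na(out)] <- "UNK"
  unname(out)
}
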