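# Static mapping from chemical-component codes to one-letter amino-acid
# codes. Standard residues map to themselves; common modified residues map
# to their parent standard residue; anything unknown falls back to 'X'.
# The mapping is embedded so no network lookup is ever needed.

.standard_aa <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# frequent nonstandard / modified components and their parent residues
.modified_aa <- c(
  MSE = "M", FME = "M", MHO = "M",                    # methionine variants
  SEC = "C", CSO = "C", CSD = "C", CSX = "C", CME = "C",
  OCS = "C", SMC = "C", SCY = "C", CAS = "C", YCM = "C",
  SEP = "S", TPO = "T", PTR = "Y", TYS = "Y",         # phosphorylated / sulfated
  MLY = "K", M3L = "K", ALY = "K", KCX = "K", LLP = "K",
  MLZ = "K", PYL = "K",
  HYP = "P", PCA = "Q", CGU = "E", NEP = "H", HIC = "H",
  AGM = "R", `2MR` = "R", DA2 = "R",
  NLE = "L", ABA = "A", AIB = "A", DHA = "S", SAR = "G",
  # D-amino acids map to the parent residue
  DAL = "A", DAR = "R", DSG = "N", DAS = "D", DCY = "C",
  DGN = "Q", DGL = "E", DHI = "H", DIL = "I", DLE = "L",
  DLY = "K", MED = "M", DPN = "F", DPR = "P", DSN = "S",
  DTH = "T", DTR = "W", DTY = "Y", DVA = "V"
)

#' Map a three-letter residue code to a one-letter code
#'
#' The 20 standard amino acids map to their one-letter codes; known modified
#' residues (e.g. selenomethionine `"MSE"`) map to the one-letter code of
#' their parent standard residue via an embedded static table; any unknown
#' code maps to `"X"`. This is a total function: it never errors.
#'
#' @param three_letter Character vector of chemical-component codes
#'   (case-insensitive).
#' @param table Optional named character vector of extra mappings, consulted
#'   before the embedded table.
#' @return Character vector of one-letter codes (20 standard letters or
#'   `"X"`).
#' @examples
#' map_residue(c("MSE", "ALA", "ZZZ")) # "M" "A" "X"
#' @export
map_residue <- function(three_letter, table = NULL) {
  code <- toupper(trimws(three_letter))
  out <- rep("X", length(code))
  if (!is.null(table) && length(table)) {
    hit <- match(code, toupper(names(table)))
    out[!is.na(hit)] <- unname(table[hit[!is.na(hit)]])
  }
  miss <- out == "X"
  hit <- match(code[miss], names(.standard_aa))
  out[miss][!is.na(hit)] <- unname(.standard_aa[hit[!is.na(hit)]])
  miss <- out == "X"
  hit <- match(code[miss], names(.modified_aa))
  out[miss][!is.na(hit)] <- unname(.modified_aa[hit[!is.na(hit)]])
  out
}

# the closed sequence alphabet used throughout the package
.seq_alphabet <- c(unname(.standard_aa), "X")

sanitize_sequence <- function(seq) {
  s <- toupper(gsub("[ \t\n]", "", seq))
  chars <- strsplit(s, "", fixed = TRUE)
  vapply(chars, function(ch) {
    ch[!(ch %in% .seq_alphabet)] <- "X"
    paste(ch, collapse = "")
  }, character(1))
}
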