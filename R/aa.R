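#' Amino-acid alphabets and residue-name tables
#'
#' All per-class quantities in profnet (labels, profiles, class weights,
#' confusion matrices) use the 20 canonical amino acids in alphabetical
#' one-letter order, `ACDEFGHIKLMNPQRSTVWY`. Index 1 is Ala.
#'
#' @return `aa_alphabet()` returns the 20 one-letter codes in alphabetical
#'   order; `aa_three_letter()` returns the matching three-letter PDB residue
#'   names.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() AA1

#' @rdname aa_alphabet
#' @export
aa_three_letter <- function() AA3

AA1 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA3 <- c("ALA", "CYS", "ASP", "GLU", "PHE", "GLY", "HIS", "ILE", "LYS", "LEU",
         "MET", "ASN", "PRO", "GLN", "ARG", "SER", "THR", "VAL", "TRP", "TYR")

names(AA1) <- AA3
names(AA3) <- AA1

# PDB chemical-component names for D-amino acids (annotation-based detection;
# no chirality computation).
D_AMINO_NAMES <- c("DAL", "DAR", "DSG", "DAS", "DCY", "DGL", "DGN", "DHI",
                   "DIL", "DLE", "DLY", "MED", "DPN", "DPR", "DSN", "DTH",
                   "DTR", "DTY", "DVA")

# Nucleic-acid residue names (ribo + deoxy) used for the DNA/RNA filter.
NUCLEIC_NAMES <- c("A", "C", "G", "U", "I", "N",
                   "DA", "DC", "DG", "DT", "DU", "DI", "DN")

# Water and common monoatomic ions; everything else non-protein arriving as
# HETATM is treated as ligand.
WATER_NAMES <- c("HOH", "DOD", "WAT")

aa1_from_resname <- function(resname) {
  out <- AA1[resname]
  out[is.na(out)] <- "X"
  unname(out)
}
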