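# Residue-name tables shared across the package.

# Standard amino acids plus the modified residues commonly seen as HETATM
# records inside polymer chains. Unknowns map to "X" downstream.
.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V",
  # modified residues treated as polymer members
  MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C", PCA = "Q",
  HYP = "P", MLY = "K", KCX = "K", CME = "C", ASX = "B", GLX = "Z",
  UNK = "X"
)

.MODIFIED_AA <- c("MSE", "SEP", "TPO", "PTR", "CSO", "PCA", "HYP",
                  "MLY", "KCX", "CME")

.NUCLEIC_RES <- c("DA", "DT", "DG", "DC", "DU", "DI", "A", "U", "G", "C", "I")

.WATER_RES <- c("HOH", "DOD", "WAT")

aa3to1 <- function(res_name) {
  out <- .AA3TO1[res_name]
  out[is.na(out)] <- "X"
  unname(out)
}

is_water <- function(res_name) res_name %in% .WATER_RES

is_nucleic_res <- function(res_name) res_name %in% .NUCLEIC_RES

is_polymer_aa <- function(res_name) res_name %in% names(.AA3TO1)
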