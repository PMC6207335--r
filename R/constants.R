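# Fixed tables used across the package. All values are plain-text constants so
# that results are reproducible without external data files.

#' @keywords internal
AA_STANDARD <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

# Common non-standard residues mapped to their standard parent amino acid.
AA_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS", CSO = "CYS",
               HYP = "PRO", SEP = "SER", TPO = "THR", PTR = "TYR",
               MLY = "LYS", KCX = "LYS", CME = "CYS", FME = "MET")

# Residue names treated as solvent and always dropped on input.
WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

# van der Waals radii (Angstrom) for the heavy elements of proteins.
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_DEFAULT <- 1.70

# Maximum accessible surface area (Angstrom^2) per amino acid, used to
# normalize residue ASA into relative accessibility (RASA). Theoretical
# Gly-X-Gly maxima (Tien et al. 2013 scale).
MAX_ASA <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
             GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
             LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
             SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

# Apolar side-chain carbons considered by the hydrophobic-interaction
# detector. Only aliphatic/aromatic carbons count; polar side chains have
# no entry and therefore never form hydrophobic interactions.
HYDROPHOBIC_ATOMS <- list(
  ALA = c("CB"),
  VAL = c("CB", "CG1", "CG2"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  MET = c("CB", "CG", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  PRO = c("CB", "CG", "CD"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2")
)

# Side-chain hydroxyl oxygens that can act as hydrogen-bond donors in
# addition to backbone/side-chain nitrogens.
HYDROXYL_DONORS <- list(SER = "OG", THR = "OG1", TYR = "OH")

# Histidine ring nitrogens carrying a lone pair (possible acceptors).
HIS_ACCEPTOR_N <- c("ND1", "NE2")

# Backbone heavy-atom names (used to exclude sequential backbone-backbone
# hydrogen bonds, which are covalent-neighbor artifacts).
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# Hydrophobicity index used by the synthetic generator to bias segment
# composition (Kyte-Doolittle).
KD_HYDROPATHY <- c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5,
                   MET = 1.9, ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
                   TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2,
                   GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
                   LYS = -3.9, ARG = -4.5)
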