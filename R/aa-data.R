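# Amino-acid level constants used by the descriptor blocks. Everything here
# is either a well-known published table (transcribed, with origin noted) or
# is rebuilt at load time from AAindex / BLOSUM62 data (see scales.R).

#: the 20 canonical residues, alphabetical; all descriptors index into this
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#: canonical compartment codes, fixed order (also the class order of models)
COMPARTMENTS <- c("plastid", "cytoplasm", "extracellular", "nucleus",
                  "mitochondrion", "cell_membrane", "golgi", "er",
                  "vacuole", "peroxisome", "cell_wall")

#: the three dual-location classes supported (pairs of canonical codes)
DUAL_CLASSES <- list(
  mito_plastid = c("plastid", "mitochondrion"),
  cyto_nucleus = c("cytoplasm", "nucleus"),
  cyto_golgi   = c("cytoplasm", "golgi")
)

# Chou's canonical pseudo-amino-acid-composition property triplet:
# hydrophobicity (Eisenberg consensus), hydrophilicity (Hopp-Woods),
# side-chain mass (Da).
.pse_hydrophobicity <- c(
  A =  0.62, C =  0.29, D = -0.90, E = -0.74, F = 1.19,
  G =  0.48, H = -0.40, I =  1.38, K = -1.50, L = 1.06,
  M =  0.64, N = -0.78, P =  0.12, Q = -0.85, R = -2.53,
  S = -0.18, T = -0.05, V =  1.08, W =  0.81, Y = 0.26)

.pse_hydrophilicity <- c(
  A = -0.5, C = -1.0, D =  3.0, E =  3.0, F = -2.5,
  G =  0.0, H = -0.5, I = -1.8, K =  3.0, L = -1.8,
  M = -1.3, N =  0.2, P =  0.0, Q =  0.2, R =  3.0,
  S =  0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

.pse_sidechain_mass <- c(
  A =  15.0, C =  47.0, D =  59.0, E =  73.0, F =  91.1,
  G =   1.0, H =  81.1, I =  57.1, K =  72.1, L =  57.1,
  M =  75.1, N =  58.0, P =  41.1, Q =  72.0, R = 100.1,
  S =  31.0, T =  45.0, V =  43.1, W = 130.2, Y = 107.1)

# Kyte-Doolittle hydropathy (also AAindex KYTJ820101); kept inline because
# it is used before the AAindex cache is built.
.kd_hydropathy <- c(
  A =  1.8, C =  2.5, D = -3.5, E = -3.5, F =  2.8,
  G = -0.4, H = -3.2, I =  4.5, K = -3.9, L =  3.8,
  M =  1.9, N = -3.5, P = -1.6, Q = -3.5, R = -4.5,
  S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)

# z-scales of Sandberg et al. (1998): 5 principal property scores per
# residue (lipophilicity, steric bulk/polarizability, polarity, and two
# electronic-effect dimensions).
.zscales <- matrix(c(
   0.24, -2.32,  0.60, -0.14,  1.30,   # A
   0.84, -1.67,  3.71,  0.18, -2.65,   # C
   3.98,  0.93,  1.93, -2.46,  0.75,   # D
   3.11,  0.26, -0.11, -3.04, -0.25,   # E
  -4.22,  1.94,  1.06,  0.54, -0.62,   # F
   2.05, -4.06,  0.36, -0.82, -0.38,   # G
   2.47,  1.95,  0.26,  3.90,  0.09,   # H
  -3.89, -1.73, -1.71, -0.84,  0.26,   # I
   2.29,  0.89, -2.49,  1.49,  0.31,   # K
  -4.28, -1.30, -1.49, -0.72,  0.84,   # L
  -2.85, -0.22,  0.47,  1.94, -0.98,   # M
   3.05,  1.62,  1.04, -1.15,  1.61,   # N
  -1.66,  0.27,  1.84,  0.70,  2.00,   # P
   1.75,  0.50, -1.44, -1.34,  0.66,   # Q
   3.52,  2.50, -3.50,  1.99, -0.17,   # R
   2.39, -1.07,  1.15, -1.39,  0.67,   # S
   0.75, -2.18, -1.12, -1.46, -0.40,   # T
  -2.59, -2.64, -1.54, -0.85, -0.02,   # V
  -4.36,  3.94,  0.59,  3.44, -1.59,   # W
  -2.54,  2.44,  0.43,  0.04, -1.47),  # Y
  nrow = 20, byrow = TRUE,
  dimnames = list(AA, paste0("z", 1:5)))

# EMBOSS pK values for the Henderson-Hasselbalch charge model.
.pka <- c(Nterm = 8.6, Cterm = 3.6,
          C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# CTD three-group partitions of the 20 residues under 7 physicochemical
# properties (Dubchak-style grouped-composition tables).
CTD_GROUPS <- list(
  hydrophobicity = list(
    polar       = c("R", "K", "E", "D", "Q", "N"),
    neutral     = c("G", "A", "S", "T", "P", "H", "Y"),
    hydrophobic = c("C", "L", "V", "I", "M", "F", "W")),
  vdw_volume = list(
    small  = c("G", "A", "S", "C", "T", "P", "D"),
    medium = c("N", "V", "E", "Q", "I", "L"),
    large  = c("M", "H", "K", "F", "R", "Y", "W")),
  polarity = list(
    low    = c("L", "I", "F", "W", "C", "M", "V", "Y"),
    medium = c("P", "A", "T", "G", "S"),
    high   = c("H", "Q", "R", "K", "N", "E", "D")),
  polarizability = list(
    low    = c("G", "A", "S", "D", "T"),
    medium = c("C", "P", "N", "V", "E", "Q", "I", "L"),
    high   = c("K", "M", "H", "F", "R", "Y", "W")),
  charge = list(
    positive = c("K", "R"),
    neutral  = c("A", "N", "C", "Q", "G", "H", "I", "L",
                 "M", "F", "P", "S", "T", "W", "Y", "V"),
    negative = c("D", "E")),
  secondary_structure = list(
    helix  = c("E", "A", "L", "M", "Q", "K", "R", "H"),
    strand = c("V", "I", "Y", "C", "W", "F", "T"),
    coil   = c("G", "N", "P", "S", "D")),
  solvent_accessibility = list(
    buried       = c("A", "L", "F", "C", "G", "I", "V", "W"),
    exposed      = c("R", "K", "Q", "E", "N", "D"),
    intermediate = c("M", "S", "P", "T", "H", "Y"))
)

#: names of the 18 external predictor scores, fixed column order
EXTERNAL_SCORE_NAMES <- c(
  "cTP", "mTP", "SP", "TM", "other", "NLS", "erpred",
  "SVM_mito", "SVM_mem", "SVM_inter", "SVM_matrix", "SVM_outer",
  paste0("Tango", 1:6))
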