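# Multi-dimensional residue property scales and residue distance matrices.
#
# The numeric tables are built once per session from data that ships with
# the imported packages: the AAindex collection (seqinr) and BLOSUM62
# (Biostrings). Each scale family is derived as the leading principal
# components of a thematically curated AAindex subset, mirroring how the
# corresponding published scale families were constructed (z-scales is the
# exception: the published Sandberg table is transcribed in aa-data.R).
# Values are therefore in-package derivations, not the published numbers;
# downstream contracts depend only on the dimensions.

.plantloc_cache <- new.env(parent = emptyenv())

.aaindex_raw <- function() {
  if (is.null(.plantloc_cache$aaindex)) {
    e <- new.env()
    utils::data("aaindex", package = "seqinr", envir = e)
    .plantloc_cache$aaindex <- e$aaindex
  }
  .plantloc_cache$aaindex
}

# 3-letter order used by AAindex entries -> one-letter codes
.AAINDEX_A1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
                 Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
                 Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
                 Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Fetch AAindex single-residue indices as a matrix
#'
#' @param accessions character vector of AAindex accession numbers.
#' @return numeric matrix, 20 rows (alphabetical one-letter order) by one
#'   column per accession.
#' @keywords internal
aaindex_matrix <- function(accessions) {
  idx <- .aaindex_raw()
  miss <- setdiff(accessions, names(idx))
  if (length(miss)) stop("unknown AAindex accession(s): ",
                         paste(miss, collapse = ", "))
  m <- vapply(accessions, function(a) {
    v <- idx[[a]]$I
    names(v) <- .AAINDEX_A1[names(v)]
    v[AA]
  }, numeric(20))
  rownames(m) <- AA
  m
}

# PCA scores of standardized index columns; deterministic sign convention
# (largest-magnitude score of each component is positive).
.pca_scale <- function(m, d, prefix) {
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  s <- pc$x[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) if (s[which.max(abs(s[, j])), j] < 0) s[, j] <- -s[, j]
  colnames(s) <- paste0(prefix, seq_len(d))
  s
}

# curated AAindex subsets per theme (all complete for the 20 residues)
.IDX_HYDROPHOBIC <- c("EISD840101", "KYTJ820101", "FAUJ830101", "ARGP820101",
                      "JOND750101", "RADA880101", "RADA880102", "HOPT810101",
                      "CIDH920105", "GOLD730101", "WOLR810101", "NADH010101")
.IDX_STERIC <- c("GRAR740103", "BIGC670101", "CHAM810101", "FAUJ880103",
                 "ZIMJ680102", "CHOC750101", "TSAJ990101", "KRIW790103",
                 "GOLD730102", "FAUJ880102", "COHE430101", "BULH740102")
.IDX_ELECTRONIC <- c("GRAR740102", "ZIMJ680103", "RADA880108", "CHAM820101",
                     "ZIMJ680104", "FAUJ880111", "FAUJ880112", "KLEP840101",
                     "CHAM830107", "CHAM830108", "FAUJ880109", "FAUJ880110")
.IDX_STRUCTURE <- c("CHOP780201", "CHOP780202", "CHOP780203", "LEVM780101",
                    "LEVM780102", "LEVM780103", "KOEP990101", "KOEP990102",
                    "BHAR880101", "VINM940101", "KARP850101", "KARP850102",
                    "PONP800101", "JANJ780101", "CHOC760102", "ROSG850101",
                    "ROSG850102")

.blosum62_scale <- function(d) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  b <- e$BLOSUM62[AA, AA]
  .pca_scale(b, d, "blosum")
}

#' Residue property scale matrices used by the scale-projection features
#'
#' Returns the nine multi-dimensional scales (Cruciani-style 3, FASGAI-style
#' 6, MS-WHIM-style 3, protFP-style 8, st-scale-style 8, t-scale-style 5,
#' VHSE-style 8, published z-scales 5, BLOSUM62-derived 8). Cached per
#' session; fully deterministic.
#'
#' @return named list of numeric matrices (20 rows each).
#' @export
property_scales <- function() {
  if (!is.null(.plantloc_cache$scales)) return(.plantloc_cache$scales)
  sc <- list(
    cruciani = .pca_scale(
      aaindex_matrix(c("EISD840101", "KYTJ820101", "HOPT810101",
                       "GRAR740102", "ZIMJ680103", "RADA880108",
                       "FAUJ880109", "FAUJ880110")), 3, "crucian"),
    fasgai = .pca_scale(
      aaindex_matrix(c(.IDX_HYDROPHOBIC[1:4], .IDX_STERIC[1:4],
                       .IDX_ELECTRONIC[1:4], .IDX_STRUCTURE[1:6])),
      6, "fasgai"),
    mswhim = .pca_scale(aaindex_matrix(.IDX_ELECTRONIC), 3, "mswhim"),
    protfp = .pca_scale(
      aaindex_matrix(unique(c(.IDX_HYDROPHOBIC, .IDX_STERIC,
                              .IDX_ELECTRONIC, .IDX_STRUCTURE))),
      8, "protFP"),
    stscales = .pca_scale(
      aaindex_matrix(c(.IDX_STRUCTURE, .IDX_STERIC)), 8, "stscale"),
    tscales = .pca_scale(
      aaindex_matrix(c(.IDX_STRUCTURE[1:8], .IDX_ELECTRONIC[1:6])),
      5, "tscale"),
    vhse = {
      v <- cbind(.pca_scale(aaindex_matrix(.IDX_HYDROPHOBIC), 2, "h"),
                 .pca_scale(aaindex_matrix(.IDX_STERIC), 2, "s"),
                 .pca_scale(aaindex_matrix(.IDX_ELECTRONIC), 4, "e"))
      colnames(v) <- paste0("vhse", 1:8)
      v
    },
    zscales = .zscales,
    blosum = .blosum62_scale(8)
  )
  .plantloc_cache$scales <- sc
  sc
}

#' Grantham chemical distance matrix
#'
#' Recomputed from the published formula
#' \eqn{D_{ij} = [1.833 (c_i-c_j)^2 + 0.1018 (p_i-p_j)^2 +
#' 0.000399 (v_i-v_j)^2]^{1/2}} over the Grantham composition, polarity and
#' volume indices, rescaled so the mean pairwise distance is 100 (the
#' published normalization).
#'
#' @return symmetric 20 x 20 numeric matrix with zero diagonal.
#' @export
grantham_distance <- function() {
  if (!is.null(.plantloc_cache$grantham)) return(.plantloc_cache$grantham)
  cpv <- aaindex_matrix(c("GRAR740101", "GRAR740102", "GRAR740103"))
  w <- c(1.833, 0.1018, 0.000399)
  d <- matrix(0, 20, 20, dimnames = list(AA, AA))
  for (i in 1:20) for (j in 1:20)
    d[i, j] <- sqrt(sum(w * (cpv[i, ] - cpv[j, ])^2))
  d <- d * 100 / mean(d[upper.tri(d)])
  .plantloc_cache$grantham <- d
  d
}

#' Physicochemical residue distance matrix (in-package construction)
#'
#' Euclidean distance over standardized hydrophobicity (Kyte-Doolittle),
#' hydrophilicity (Hopp-Woods) and side-chain mass, rescaled to a maximum
#' of 1. This is a synthetic stand-in constructed in-package for the second
#' distance matrix of the quasi-sequence-order descriptors; it follows the
#' same hydrophobicity/hydrophilicity/side-chain design as the classical
#' sequence-order distance tables but its numeric values are this package's
#' own derivation.
#'
#' @return symmetric 20 x 20 numeric matrix with zero diagonal.
#' @export
physchem_distance <- function() {
  if (!is.null(.plantloc_cache$physchem)) return(.plantloc_cache$physchem)
  p <- scale(cbind(.kd_hydropathy[AA], .pse_hydrophilicity[AA],
                   .pse_sidechain_mass[AA]))
  d <- as.matrix(stats::dist(p))
  dimnames(d) <- list(AA, AA)
  d <- d / max(d)
  .plantloc_cache$physchem <- d
  d
}

# Boman residue solubility values: negated Radzicka-Wolfenden octanol->water
# transfer free energies (AAindex RADA880102), so hydrophilic residues score
# positive; the Boman index is the mean of these values over the sequence.
.boman_scale <- function() {
  if (is.null(.plantloc_cache$boman)) {
    v <- -aaindex_matrix("RADA880102")[, 1]
    .plantloc_cache$boman <- v
  }
  .plantloc_cache$boman
}

# scalar properties for the Geary autocorrelation block (4 x nlag features):
# hydrophobicity, hydrophilicity, side-chain mass, polarity
.geary_properties <- function() {
  if (is.null(.plantloc_cache$geary_props)) {
    .plantloc_cache$geary_props <- list(
      hydrophobicity = .kd_hydropathy[AA],
      hydrophilicity = .pse_hydrophilicity[AA],
      sidechain_mass = .pse_sidechain_mass[AA],
      polarity       = aaindex_matrix("GRAR740102")[, 1])
  }
  .plantloc_cache$geary_props
}
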