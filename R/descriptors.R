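# Sequence-derived descriptor blocks making up the 479-feature encoding.
#
# Block layout (fixed schema, see feature_schema()):
#   AAC 20 | APAAC 30 | Blosum 8 | CTDC 21 | CTDD 105 | CTDT 21 | Geary 40 |
#   PAAC 30 | PsePC 22 | PseSC 26 | scalar/scale block 57 | QSO 60 |
#   SOCN 20 | external scores 18 | Homology 1

# integer encoding of a validated sequence into the alphabetical AA order
seq_index <- function(sequence) {
  idx <- match(strsplit(sequence, "", fixed = TRUE)[[1]], AA)
  if (anyNA(idx)) stop("sequence contains non-canonical residues")
  idx
}

#' Descriptor parameter record
#'
#' Lambda values are pinned per pseudo-amino-acid-composition block so the
#' block dimensions come out at 22 (parallel, lambda 2), 26 (serial, lambda
#' 2, 3 properties), 30 (PAAC, lambda 10) and 30 (APAAC, lambda 5); weights
#' are 0.05 for the parallel/serial blocks and 0.1 for PAAC/APAAC; nlag 10
#' drives the Geary, quasi-sequence-order and covariance features.
#'
#' @param lambda_parallel,lambda_serial,lambda_paac,lambda_apaac sequence-order
#'   correlation depths of the four PseAAC blocks.
#' @param weight_pse,weight_paac PseAAC weighting factors.
#' @param nlag maximum lag for autocorrelation/sequence-order blocks.
#' @return list of validated parameters.
#' @export
descriptor_params <- function(lambda_parallel = 2L, lambda_serial = 2L,
                              lambda_paac = 10L, lambda_apaac = 5L,
                              weight_pse = 0.05, weight_paac = 0.1,
                              nlag = 10L) {
  p <- list(lambda_parallel = as.integer(lambda_parallel),
            lambda_serial = as.integer(lambda_serial),
            lambda_paac = as.integer(lambda_paac),
            lambda_apaac = as.integer(lambda_apaac),
            weight_pse = weight_pse, weight_paac = weight_paac,
            nlag = as.integer(nlag))
  stopifnot(p$lambda_parallel >= 1, p$lambda_serial >= 1,
            p$lambda_paac >= 1, p$lambda_apaac >= 1,
            p$weight_pse > 0, p$weight_pse <= 1,
            p$weight_paac > 0, p$weight_paac <= 1, p$nlag >= 1)
  p
}

#' Amino acid composition
#'
#' @param sequence validated amino-acid sequence.
#' @return 20 frequencies in alphabetical residue order (sum 1).
#' @export
aac <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  idx <- seq_index(sequence)
  stats::setNames(tabulate(idx, 20) / length(idx), AA)
}

# standardize a residue property over the 20-letter alphabet
.std20 <- function(p) (p - mean(p)) / stats::sd(p)

#' Pseudo amino acid composition (four variants)
#'
#' Type-I ("parallel"/"paac") correlation factors average squared
#' differences of the three standardized Chou properties (hydrophobicity,
#' hydrophilicity, side-chain mass); type-II ("serial") keeps one
#' product-correlation factor per property and lag; "apaac" is the
#' amphiphilic type-II variant over hydrophobicity and hydrophilicity.
#' The first 20 components reduce to weighted amino acid composition.
#'
#' @param sequence validated sequence, longer than `lambda`.
#' @param lambda sequence-order correlation depth.
#' @param weight weighting factor of the correlation part.
#' @param mode one of `"parallel"`, `"serial"`, `"paac"`, `"apaac"`.
#' @return numeric vector of dimension 20+lambda (type I), 20+3*lambda
#'   (serial) or 20+2*lambda (apaac).
#' @export
pseaac <- function(sequence, lambda, weight,
                   mode = c("parallel", "serial", "paac", "apaac")) {
  mode <- match.arg(mode)
  idx <- seq_index(sequence)
  L <- length(idx)
  if (L <= lambda)
    stop("sequence too short for PseAAC mode '", mode,
         "' (length ", L, " <= lambda ", lambda, ")")
  props <- list(.std20(.pse_hydrophobicity[AA]),
                .std20(.pse_hydrophilicity[AA]),
                .std20(.pse_sidechain_mass[AA]))
  if (mode == "apaac") props <- props[1:2]
  f <- tabulate(idx, 20) / L
  if (mode %in% c("parallel", "paac")) {
    theta <- vapply(seq_len(lambda), function(k) {
      i <- seq_len(L - k)
      mean(vapply(props, function(h) mean((h[idx[i + k]] - h[idx[i]])^2),
                  numeric(1)))
    }, numeric(1))
  } else {
    # serial correlation: one product factor per property per lag,
    # lag-major order (all properties at lag 1, then lag 2, ...)
    theta <- as.vector(vapply(seq_len(lambda), function(k) {
      i <- seq_len(L - k)
      vapply(props, function(h) mean(h[idx[i]] * h[idx[i + k]]), numeric(1))
    }, numeric(length(props))))
  }
  denom <- sum(f) + weight * sum(theta)
  c(f / denom, weight * theta / denom)
}

#' Composition, transition and distribution descriptors
#'
#' Residues are partitioned into 3 groups under 7 physicochemical
#' properties. C gives group frequencies; T the distribution of cross-group
#' adjacent transitions over the three unordered group pairs (normalized by
#' the number of cross-group adjacencies, so the block sums to 1 per
#' property when any transition exists); D the sequence positions, as
#' percent of length, of the first, 25%, 50%, 75% and last residue of each
#' group (ceiling rule; zeros for absent groups).
#'
#' @param sequence validated sequence (length >= 2 for T).
#' @param grouping list of per-property 3-group partitions
#'   (default [CTD_GROUPS]).
#' @return list with numeric vectors `C` (21), `T` (21), `D` (105).
#' @export
ctd <- function(sequence, grouping = CTD_GROUPS) {
  idx <- seq_index(sequence)
  L <- length(idx)
  Cv <- numeric(0); Tv <- numeric(0); Dv <- numeric(0)
  for (prop in names(grouping)) {
    gdef <- grouping[[prop]]
    g <- integer(20)
    for (k in 1:3) g[match(gdef[[k]], AA)] <- k
    gs <- g[idx]
    Cv <- c(Cv, tabulate(gs, 3) / L)
    if (L >= 2) {
      a <- gs[-L]; b <- gs[-1]
      cross <- a != b
      pr <- pmin(a, b)[cross]; ps <- pmax(a, b)[cross]
      cnt <- c(sum(pr == 1 & ps == 2), sum(pr == 1 & ps == 3),
               sum(pr == 2 & ps == 3))
      Tv <- c(Tv, if (sum(cnt) > 0) cnt / sum(cnt) else c(0, 0, 0))
    } else Tv <- c(Tv, c(0, 0, 0))
    for (k in 1:3) {
      pos <- which(gs == k)
      n <- length(pos)
      Dv <- c(Dv, if (n == 0) numeric(5) else
        100 * pos[pmax(1, ceiling(c(0, 0.25, 0.5, 0.75, 1) * n))] / L)
    }
  }
  list(C = stats::setNames(Cv, paste0("CTDC", seq_along(Cv))),
       T = stats::setNames(Tv, paste0("CTDT", seq_along(Tv))),
       D = stats::setNames(Dv, paste0("CTDD", seq_along(Dv))))
}

#' Geary autocorrelation
#'
#' Geary's c statistic along the sequence for each scalar property and lag
#' 1..nlag, on alphabet-standardized property values. A zero-variance
#' sequence yields c = 1 (the no-autocorrelation fixpoint).
#'
#' @param sequence validated sequence, longer than `nlag`.
#' @param properties named list of 20-value scalar property vectors
#'   (default: hydrophobicity, hydrophilicity, side-chain mass, polarity).
#' @param nlag maximum lag.
#' @return numeric vector of length `length(properties) * nlag`.
#' @export
geary <- function(sequence, properties = .geary_properties(), nlag = 10L) {
  idx <- seq_index(sequence)
  L <- length(idx)
  if (L <= nlag) stop("sequence too short for Geary with nlag ", nlag)
  out <- numeric(0)
  for (p in properties) {
    x <- .std20(p[AA])[idx]
    ss <- sum((x - mean(x))^2)
    cs <- vapply(seq_len(nlag), function(k) {
      if (ss == 0) return(1)
      i <- seq_len(L - k)
      ((L - 1) * sum((x[i] - x[i + k])^2)) / (2 * (L - k) * ss)
    }, numeric(1))
    out <- c(out, cs)
  }
  stats::setNames(out, paste0("Geary", seq_along(out)))
}

#' Quasi-sequence-order descriptors and sequence-order-coupling numbers
#'
#' Coupling numbers tau_d are sums of squared residue distances at lag d
#' under two distance matrices: the in-package physicochemical distance
#' ([physchem_distance()]) and the Grantham chemical distance
#' ([grantham_distance()]). QSO holds, per matrix, 20 composition terms and
#' nlag coupling terms, jointly normalized by (sum f + w * sum tau).
#'
#' @param sequence validated sequence, longer than `nlag`.
#' @param nlag maximum lag (default 10).
#' @param weight coupling weight (default 0.1).
#' @return list with `QSO` (2 * (20+nlag) values) and `SOCN` (2 * nlag).
#' @export
qso_socn <- function(sequence, nlag = 10L, weight = 0.1) {
  idx <- seq_index(sequence)
  L <- length(idx)
  if (L <= nlag) stop("sequence too short for QSO/SOCN with nlag ", nlag)
  f <- tabulate(idx, 20) / L
  mats <- list(physchem = physchem_distance(), grantham = grantham_distance())
  qso <- numeric(0); socn <- numeric(0)
  for (dm in mats) {
    tau <- vapply(seq_len(nlag), function(d) {
      i <- seq_len(L - d)
      sum(dm[cbind(idx[i], idx[i + d])]^2)
    }, numeric(1))
    denom <- sum(f) + weight * sum(tau)
    qso <- c(qso, f / denom, weight * tau / denom)
    socn <- c(socn, tau)
  }
  list(QSO = stats::setNames(qso, paste0("QSO", seq_along(qso))),
       SOCN = stats::setNames(socn, paste0("SOCN", seq_along(socn))))
}

#' Mean projection of a sequence onto a residue property scale
#'
#' @param sequence validated sequence.
#' @param scale_matrix 20 x d numeric matrix (rows in alphabetical order).
#' @return d-vector of componentwise means over the residues.
#' @export
scale_projection <- function(sequence, scale_matrix) {
  idx <- seq_index(sequence)
  colMeans(scale_matrix[idx, , drop = FALSE])
}

# Henderson-Hasselbalch net charge of the sequence at a given pH
peptide_charge <- function(sequence, pH = 7) {
  idx <- seq_index(sequence)
  n <- tabulate(idx, 20)
  names(n) <- AA
  pos <- 1 / (1 + 10^(pH - .pka["Nterm"])) +
    sum(n[c("K", "R", "H")] / (1 + 10^(pH - .pka[c("K", "R", "H")])))
  neg <- 1 / (1 + 10^(.pka["Cterm"] - pH)) +
    sum(n[c("D", "E", "C", "Y")] /
          (1 + 10^(.pka[c("D", "E", "C", "Y")] - pH)))
  unname(pos - neg)
}

# isoelectric point by bisection of the monotone charge curve on [0, 14]
isoelectric_point <- function(sequence, tol = 1e-4) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peptide_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# maximum hydrophobic moment over sliding windows (Eisenberg scale)
hydrophobic_moment <- function(sequence, angle_deg, window = 11L) {
  idx <- seq_index(sequence)
  h <- .pse_hydrophobicity[AA][idx]
  L <- length(h)
  w <- min(window, L)
  ang <- angle_deg * pi / 180 * seq_len(w)
  best <- 0
  for (s in seq_len(L - w + 1)) {
    hw <- h[s:(s + w - 1)]
    mu <- sqrt(sum(hw * sin(ang))^2 + sum(hw * cos(ang))^2) / w
    if (mu > best) best <- mu
  }
  best
}

# lag-averaged auto/cross-covariance of standardized property profiles
.lag_cov <- function(x, y, nlag) {
  L <- length(x)
  lags <- seq_len(min(nlag, L - 1))
  mean(vapply(lags, function(l)
    sum(x[seq_len(L - l)] * y[(1 + l):L]) / (L - l), numeric(1)))
}

#' Scalar physicochemical indices
#'
#' Net charge at pH 7, Boman interaction index, aliphatic index,
#' lag-averaged auto/cross-covariance of hydrophobicity and hydrophilicity
#' profiles, maximum hydrophobic moments (helix 100 degrees, sheet 160
#' degrees, 11-residue window), mean hydropathy, instability index
#' (Guruprasad dipeptide weights, 10/L scaling) and isoelectric point.
#'
#' @param sequence validated sequence (length >= 2 for the instability
#'   index).
#' @param nlag covariance lag depth (default 10).
#' @return named numeric vector of 11 scalars.
#' @export
physchem_indices <- function(sequence, nlag = 10L) {
  idx <- seq_index(sequence)
  L <- length(idx)
  if (L < 2) stop("instability index undefined for length < 2")
  f <- tabulate(idx, 20) / L
  names(f) <- AA
  kd <- .std20(.kd_hydropathy[AA])[idx]
  hw <- .std20(.pse_hydrophilicity[AA])[idx]
  diwv_sum <- sum(.diwv[cbind(idx[-L], idx[-1])])
  c(Charge = peptide_charge(sequence, 7),
    Boman = mean(.boman_scale()[idx]),
    aIndex = 100 * f[["A"]] + 2.9 * 100 * f[["V"]] +
      3.9 * (100 * f[["I"]] + 100 * f[["L"]]),
    autocov = .lag_cov(kd, kd, nlag),
    Crosscov1 = .lag_cov(kd, hw, nlag),
    Crosscov2 = .lag_cov(hw, kd, nlag),
    Hmoment1 = hydrophobic_moment(sequence, 100),
    Hmoment2 = hydrophobic_moment(sequence, 160),
    hydrophobicity = mean(.kd_hydropathy[AA][idx]),
    Instaindex = 10 / L * diwv_sum,
    pI = isoelectric_point(sequence))
}

#' The 479-name feature schema
#'
#' @return character vector of the 479 feature names in fixed block order.
#' @export
feature_schema <- function() {
  if (!is.null(.plantloc_cache$schema)) return(.plantloc_cache$schema)
  s <- c(paste0("AAC", 1:20), paste0("APAAC", 1:30), paste0("Blosum", 1:8),
         paste0("CTDC", 1:21), paste0("CTDD", 1:105), paste0("CTDT", 1:21),
         paste0("Geary", 1:40), paste0("PAAC", 1:30), paste0("PsePC", 1:22),
         paste0("PseSC", 1:26),
         "Charge", "Boman", "aIndex", "autocov", "Crosscov1", "Crosscov2",
         paste0("Crucian", 1:3), paste0("fasgai", 1:6),
         "Hmoment1", "Hmoment2", "hydrophobicity", "Instaindex",
         paste0("mswhim", 1:3), "pI", paste0("protFP", 1:8),
         paste0("stscales", 1:8), paste0("tscales", 1:5),
         paste0("vhsescales", 1:8), paste0("zscales", 1:5),
         paste0("QSO", 1:60), paste0("SOCN", 1:20),
         EXTERNAL_SCORE_NAMES, "Homology")
  stopifnot(length(s) == 479, !anyDuplicated(s))
  .plantloc_cache$schema <- s
  s
}

.MIN_EXTRACT_LEN <- 11L  # nlag + 1; QSO/SOCN/Geary undefined below this

#' Extract the full 479-feature vector of one protein
#'
#' @param sequence validated amino-acid sequence (length >= 11).
#' @param external named numeric vector of the 18 external predictor scores
#'   (see [EXTERNAL_SCORE_NAMES]); order-insensitive, matched by name.
#' @param homology the GO-homology categorical code (0 = no evidence,
#'   1..11 = compartment index; see [go_homology_feature()]).
#' @param params a [descriptor_params()] record.
#' @param id record id used in error messages.
#' @return named numeric vector of length 479 in schema order.
#' @export
extract_features <- function(sequence, external, homology = 0,
                             params = descriptor_params(), id = "?") {
  if (nchar(sequence) < .MIN_EXTRACT_LEN)
    stop("record '", id, "': sequence shorter than ", .MIN_EXTRACT_LEN,
         " residues; quasi-sequence-order features are undefined")
  if (!all(EXTERNAL_SCORE_NAMES %in% names(external)))
    stop("record '", id, "': missing external score(s): ",
         paste(setdiff(EXTERNAL_SCORE_NAMES, names(external)),
               collapse = ", "))
  blk0 <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("record '", id, "': block ", name, " failed: ",
           conditionMessage(e), call. = FALSE))
  }
  blk <- function(name, expr) unname(blk0(name, expr))
  sc <- property_scales()
  ctd_v <- blk0("CTD", ctd(sequence))
  qs <- blk0("QSO/SOCN", qso_socn(sequence, params$nlag,
                                  params$weight_paac))
  pc <- blk0("physchem", physchem_indices(sequence, params$nlag))
  v <- c(
    blk("AAC", aac(sequence)),
    blk("APAAC", pseaac(sequence, params$lambda_apaac, params$weight_paac,
                        "apaac")),
    blk("Blosum", scale_projection(sequence, sc$blosum)),
    ctd_v$C, ctd_v$D, ctd_v$T,
    blk("Geary", geary(sequence, nlag = params$nlag)),
    blk("PAAC", pseaac(sequence, params$lambda_paac, params$weight_paac,
                       "paac")),
    blk("PsePC", pseaac(sequence, params$lambda_parallel, params$weight_pse,
                        "parallel")),
    blk("PseSC", pseaac(sequence, params$lambda_serial, params$weight_pse,
                        "serial")),
    pc[["Charge"]], pc[["Boman"]], pc[["aIndex"]], pc[["autocov"]],
    pc[["Crosscov1"]], pc[["Crosscov2"]],
    blk("Cruciani", scale_projection(sequence, sc$cruciani)),
    blk("FASGAI", scale_projection(sequence, sc$fasgai)),
    pc[["Hmoment1"]], pc[["Hmoment2"]], pc[["hydrophobicity"]],
    pc[["Instaindex"]],
    blk("MSWHIM", scale_projection(sequence, sc$mswhim)),
    pc[["pI"]],
    blk("protFP", scale_projection(sequence, sc$protfp)),
    blk("stScales", scale_projection(sequence, sc$stscales)),
    blk("tScales", scale_projection(sequence, sc$tscales)),
    blk("VHSE", scale_projection(sequence, sc$vhse)),
    blk("zScales", scale_projection(sequence, sc$zscales)),
    qs$QSO, qs$SOCN,
    as.numeric(external[EXTERNAL_SCORE_NAMES]),
    as.numeric(homology))
  names(v) <- feature_schema()
  if (!all(is.finite(v)))
    stop("record '", id, "': non-finite feature value(s): ",
         paste(utils::head(names(v)[!is.finite(v)], 5), collapse = ", "))
  v
}

#' Extract the feature table of a dataset
#'
#' @param dataset a `plantloc_dataset`.
#' @param provider an external-score provider: a function
#'   `function(id, labels)` returning a named 18-score vector (see
#'   [table_provider()] and [mock_provider()]).
#' @param params a [descriptor_params()] record.
#' @param homology optional named numeric vector of GO-homology codes per
#'   record id (default: 0 for every record).
#' @return data.frame with column `id` plus the 479 schema columns.
#' @export
extract_table <- function(dataset, provider, params = descriptor_params(),
                          homology = NULL) {
  schema <- feature_schema()
  n <- nrow(dataset)
  m <- matrix(NA_real_, n, length(schema), dimnames = list(NULL, schema))
  sets <- label_sets(dataset)
  for (i in seq_len(n)) {
    hv <- if (is.null(homology)) 0 else homology[[dataset$id[i]]]
    if (is.null(hv) || is.na(hv)) hv <- 0
    m[i, ] <- extract_features(dataset$sequence[i],
                               provider(dataset$id[i], sets[[i]]),
                               homology = hv, params = params,
                               id = dataset$id[i])
  }
  cbind(data.frame(id = dataset$id, stringsAsFactors = FALSE),
        as.data.frame(m))
}

#' Write / read a feature table as TSV
#'
#' Values are serialized with 12 significant digits.
#'
#' @param table feature table from [extract_table()].
#' @param path file path.
#' @name feature_table_io
#' @export
write_feature_table <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 12,
                                                   format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname feature_table_io
#' @export
read_feature_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
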