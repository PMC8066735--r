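params <- descriptor_params()

test_that("amino acid composition matches direct counts", {
  v <- aac("AAAA")
  expect_equal(v[["A"]], 1)
  expect_equal(sum(v), 1)
  u <- aac(paste(sort(AA20), collapse = ""))
  expect_true(all(abs(u - 0.05) < 1e-12))
  w <- aac("AAC")
  expect_equal(w[["A"]], 2 / 3)
  expect_equal(w[["C"]], 1 / 3)
  expect_error(aac(""), "empty")
})

test_that("PseAAC block dimensions match the published schema", {
  s <- random_sequence(60, seed = 2)
  expect_length(pseaac(s, 2, 0.05, "parallel"), 22)
  expect_length(pseaac(s, 2, 0.05, "serial"), 26)
  expect_length(pseaac(s, 10, 0.1, "paac"), 30)
  expect_length(pseaac(s, 5, 0.1, "apaac"), 30)
  expect_error(pseaac("ACD", 10, 0.1, "paac"), "paac")
})

test_that("homopolymer type-I PseAAC reduces to padded composition", {
  v <- pseaac("AAAAA", 2, 0.05, "parallel")
  expect_equal(v[21:22], c(0, 0))
  expect_equal(v[1], 1)  # A is the first residue alphabetically
  expect_equal(sum(v), 1)
})

test_that("type-I and serial PseAAC match the brute-force oracles", {
  for (s in c("ACDKWH", random_sequences(5, 20, 80, seed = 4))) {
    expect_lt(max(rel_err(pseaac(s, 2, 0.05, "parallel"),
                          oracle_pseaac_type1(s, 2, 0.05))), 1e-8)
    expect_lt(max(rel_err(pseaac(s, 2, 0.05, "serial"),
                          oracle_pseaac_serial(s, 2, 0.05))), 1e-8)
  }
})

test_that("PseAAC converges to composition as the weight vanishes", {
  s <- random_sequence(50, seed = 5)
  a <- aac(s)
  for (mode in c("parallel", "serial", "apaac"))
    expect_lt(max(abs(pseaac(s, 2, 1e-9, mode)[1:20] - a)), 1e-6)
})

test_that("CTD blocks follow the grouped-composition definitions", {
  r <- ctd("AAAAAAAAAA")
  expect_length(r$C, 21)
  expect_length(r$T, 21)
  expect_length(r$D, 105)
  # per property: A's group has frequency 1, no transitions, and the
  # percentile positions 10/30/50/80/100 under the ceiling rule
  for (p in 1:7) {
    Cp <- r$C[(3 * p - 2):(3 * p)]
    expect_equal(sort(unname(Cp)), c(0, 0, 1))
    expect_equal(unname(r$T[(3 * p - 2):(3 * p)]), c(0, 0, 0))
    Dp <- matrix(r$D[(15 * p - 14):(15 * p)], 3, 5, byrow = TRUE)
    hit <- which(rowSums(Dp) > 0)
    expect_length(hit, 1)
    expect_equal(unname(Dp[hit, ]), c(10, 30, 50, 80, 100))
  }
  # composition always sums to 1 per property; transition distribution
  # sums to 1 when any cross-group transition exists
  s <- random_sequence(90, seed = 6)
  r2 <- ctd(s)
  for (p in 1:7) {
    expect_equal(sum(r2$C[(3 * p - 2):(3 * p)]), 1, tolerance = 1e-9)
    expect_equal(sum(r2$T[(3 * p - 2):(3 * p)]), 1, tolerance = 1e-9)
  }
  # A and C are in different hydrophobicity groups: all transitions cross
  r3 <- ctd("ACACAC")
  expect_equal(max(r3$T[1:3]), 1)
})

test_that("Geary autocorrelation matches the direct-loop oracle", {
  s <- random_sequence(50, seed = 7)
  v <- geary(s)
  expect_length(v, 40)
  props <- plantloc:::.geary_properties()
  for (j in seq_along(props))
    expect_lt(max(rel_err(v[(10 * j - 9):(10 * j)],
                          oracle_geary(s, props[[j]], 10))), 1e-8)
  # zero-variance input gives the no-autocorrelation fixpoint
  expect_true(all(geary(paste(rep("A", 30), collapse = "")) == 1))
})

test_that("sequence-order coupling numbers match the double-loop oracle", {
  s <- random_sequence(30, seed = 8)
  r <- qso_socn(s)
  expect_length(r$QSO, 60)
  expect_length(r$SOCN, 20)
  expect_lt(max(rel_err(r$SOCN[1:10],
                        oracle_socn(s, physchem_distance(), 10))), 1e-8)
  expect_lt(max(rel_err(r$SOCN[11:20],
                        oracle_socn(s, grantham_distance(), 10))), 1e-8)
  # homopolymer: zero coupling, so QSO reduces to the composition
  h <- paste(rep("K", 20), collapse = "")
  rh <- qso_socn(h)
  expect_true(all(rh$SOCN == 0))
  expect_equal(unname(rh$QSO[1:20]), unname(aac(h)))
})

test_that("scale projections are residue-row means", {
  sc <- property_scales()
  expect_equal(scale_projection("W", sc$zscales),
               sc$zscales["W", ])
  expect_equal(scale_projection("AW", sc$cruciani),
               (sc$cruciani["A", ] + sc$cruciani["W", ]) / 2)
  expect_equal(ncol(sc$zscales), 5)
  expect_equal(ncol(sc$blosum), 8)
  expect_equal(ncol(sc$vhse), 8)
})

test_that("the Grantham matrix reproduces published extreme distances", {
  g <- grantham_distance()
  expect_equal(g["L", "I"], 5, tolerance = 0.05)
  expect_equal(g["C", "W"], 215, tolerance = 0.005)
  expect_equal(g["R", "L"], 102, tolerance = 0.005)
  expect_true(isSymmetric(g))
  expect_true(all(diag(g) == 0))
})

test_that("scalar physicochemical indices match their formulas", {
  p <- physchem_indices("AAAA")
  expect_equal(p[["aIndex"]], 100)
  # Boman value of a single-residue extension: mean of the scale rows
  b <- plantloc:::.boman_scale()
  expect_equal(physchem_indices("WW")[["Boman"]], b[["W"]])
  # instability: hand-summed dipeptide weights
  s <- "APAPAPAPAP"
  expect_equal(physchem_indices(s)[["Instaindex"]],
               oracle_instability(s, plantloc:::.diwv), tolerance = 1e-12)
  expect_error(physchem_indices("A"), "length")
})

test_that("isoelectric point agrees with a fine charge-curve grid scan", {
  for (s in c("K", "DDE", "ACDKWHRRK")) {
    expect_equal(physchem_indices(paste0(s, "A"))[["pI"]],
                 oracle_pi_grid(paste0(s, "A")), tolerance = 0.01)
  }
  # charge curve itself
  s <- "ACDKWHRRK"
  expect_equal(plantloc:::peptide_charge(s, 7), oracle_charge(s, 7),
               tolerance = 1e-10)
})

test_that("full extraction obeys the 479-feature schema contract", {
  schema <- feature_schema()
  expect_length(schema, 479)
  expect_false(anyDuplicated(schema) > 0)
  counts <- c(AAC = 20, APAAC = 30, Blosum = 8, CTDC = 21, CTDD = 105,
              CTDT = 21, Geary = 40, PAAC = 30, PsePC = 22, PseSC = 26,
              QSO = 60, SOCN = 20)
  for (b in names(counts))
    expect_equal(sum(grepl(paste0("^", b, "[0-9]+$"), schema)),
                 unname(counts[b]), info = b)
  s <- random_sequence(50, seed = 9)
  v <- extract_features(s, mock_scores(1), id = "x")
  expect_length(v, 479)
  expect_identical(names(v), schema)
  expect_true(all(is.finite(v)))
  # determinism
  expect_identical(v, extract_features(s, mock_scores(1), id = "x"))
  # short sequences are rejected with a clear message
  expect_error(extract_features("ACDEFGHIKL", mock_scores(1)), "shorter")
})

test_that("the shipped schema JSON pins the exact column order", {
  f <- system.file("extdata", "feature_schema.json", package = "plantloc")
  expect_identical(unlist(jsonlite::read_json(f)), feature_schema())
})

test_that("descriptors are invariant to input case and line wrapping", {
  s <- random_sequence(80, seed = 10)
  f1 <- tmp_file(c(">q", s), ".fasta")
  f2 <- tmp_file(c(">q", tolower(substr(s, 1, 37)),
                   substr(s, 38, 80)), ".fasta")
  d1 <- read_fasta(f1); d2 <- read_fasta(f2)
  expect_identical(
    extract_features(d1$sequence[1], mock_scores(3), id = "q"),
    extract_features(d2$sequence[1], mock_scores(3), id = "q"))
})

test_that("feature tables round-trip through TSV at 12 significant digits", {
  fx <- make_fixture("tiny")
  ds <- fx$dataset[1:3, ]
  class(ds) <- c("plantloc_dataset", "data.frame")
  tab <- extract_table(ds, table_provider(fx$scores))
  expect_equal(dim(tab), c(3, 480))
  f <- tempfile(fileext = ".tsv")
  write_feature_table(tab, f)
  back <- read_feature_table(f)
  expect_identical(names(back), names(tab))
  num <- vapply(tab, is.numeric, logical(1))
  expect_lt(max(rel_err(as.matrix(back[num]), as.matrix(tab[num]))), 1e-11)
})
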