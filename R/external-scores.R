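# The 18 external predictor scores and the GO-homology feature.
#
# The external tools themselves (targeting/signal-peptide predictors,
# transmembrane and NLS detection, ER/mitochondrial sub-location SVMs,
# aggregation propensities) are out of scope: their scores enter the
# pipeline through a TSV table, or through a deterministic mock provider
# for testing and simulation. A provider is any function
# `function(id, labels)` returning a named vector of the 18 scores.

.PROB_SCORES <- c("cTP", "mTP", "SP", "other")

validate_scores <- function(v, id = "?") {
  miss <- setdiff(EXTERNAL_SCORE_NAMES, names(v))
  if (length(miss))
    stop("external scores for '", id, "' missing column(s): ",
         paste(miss, collapse = ", "))
  v <- v[EXTERNAL_SCORE_NAMES]
  if (!all(is.finite(v)))
    stop("non-finite external score(s) for '", id, "'")
  bad <- v[.PROB_SCORES] < 0 | v[.PROB_SCORES] > 1
  if (any(bad))
    stop("external score(s) out of [0,1] for '", id, "': ",
         paste(.PROB_SCORES[bad], collapse = ", "))
  if (v[["TM"]] < 0) stop("negative TM segment count for '", id, "'")
  v
}

#' Load external predictor scores from a TSV file
#'
#' @param path TSV with an `id` column plus the 18 score columns
#'   ([EXTERNAL_SCORE_NAMES]).
#' @param dataset optional `plantloc_dataset`; when given, every dataset id
#'   must be present unless `missing = "zero"`.
#' @param missing `"error"` (default) or `"zero"` (zero-fill absent ids
#'   with a warning).
#' @return validated score table (data.frame, one row per id).
#' @export
load_scores <- function(path, dataset = NULL,
                        missing = c("error", "zero")) {
  missing <- match.arg(missing)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", EXTERNAL_SCORE_NAMES), names(tab))
  if (length(miss))
    stop("score table missing column(s): ", paste(miss, collapse = ", "))
  for (i in seq_len(nrow(tab)))
    validate_scores(unlist(tab[i, EXTERNAL_SCORE_NAMES]), tab$id[i])
  if (!is.null(dataset)) {
    absent <- setdiff(dataset$id, tab$id)
    if (length(absent)) {
      if (missing == "error")
        stop("no external scores for id(s): ",
             paste(utils::head(absent, 5), collapse = ", "))
      warning("zero-filling external scores for ", length(absent), " id(s)")
      fill <- as.data.frame(matrix(0, length(absent),
                                   length(EXTERNAL_SCORE_NAMES),
                                   dimnames = list(NULL,
                                                   EXTERNAL_SCORE_NAMES)))
      tab <- rbind(tab, cbind(data.frame(id = absent), fill))
    }
  }
  tab
}

#' Provider backed by a score table
#'
#' @param score_table table from [load_scores()] (or equivalent).
#' @return provider function `function(id, labels)`.
#' @export
table_provider <- function(score_table) {
  force(score_table)
  function(id, labels = NULL) {
    i <- match(id, score_table$id)
    if (is.na(i)) stop("no external scores for id: ", id)
    validate_scores(unlist(score_table[i, EXTERNAL_SCORE_NAMES]), id)
  }
}

# class-specific latent mean shifts of the mock scores: each compartment
# has one strong marker (+3) and possibly a secondary one (+1.5), so the
# mock emulates informative sorting-signal predictors
.MOCK_BIAS <- local({
  b <- matrix(0, length(COMPARTMENTS), length(EXTERNAL_SCORE_NAMES),
              dimnames = list(COMPARTMENTS, EXTERNAL_SCORE_NAMES))
  b["plastid", "cTP"] <- 3
  b["cytoplasm", "other"] <- 3
  b["extracellular", c("SP", "Tango2")] <- c(3, 1.5)
  b["nucleus", "NLS"] <- 3
  b["mitochondrion", c("mTP", "SVM_mito", "SVM_matrix")] <- c(3, 1.5, 1.5)
  b["cell_membrane", c("TM", "Tango4")] <- c(3, 1.5)
  b["golgi", c("Tango5", "TM")] <- c(3, 1.5)
  b["er", c("erpred", "SP")] <- c(3, 1.5)
  b["vacuole", c("Tango3", "SP")] <- c(3, 1.5)
  b["peroxisome", c("Tango6", "SVM_outer")] <- c(3, 1.5)
  b["cell_wall", c("Tango1", "SP")] <- c(3, 1.5)
  b
})

# stable small integer hash of a string (for per-id sub-seeds)
.str_hash <- function(s) {
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 131 + k) %% 2147483647L
  as.integer(h)
}

#' Draw one deterministic set of mock external scores
#'
#' Scores are pseudo-random given `seed`; when `class_hint` names one or
#' two compartments, the class-marker scores are shifted upward in
#' proportion to `signal` (averaged over the hinted pair), so that mock
#' scores carry learnable class information.
#'
#' @param seed integer seed.
#' @param class_hint NULL, one compartment code, or a pair.
#' @param signal bias strength in `[0, 1]`.
#' @return named numeric vector of the 18 scores.
#' @export
mock_scores <- function(seed, class_hint = NULL, signal = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed) %% 2147483647L)
  z <- stats::rnorm(length(EXTERNAL_SCORE_NAMES), sd = 1)
  names(z) <- EXTERNAL_SCORE_NAMES
  if (!is.null(class_hint) && length(class_hint)) {
    hint <- normalize_compartment(class_hint)
    bias <- colMeans(.MOCK_BIAS[hint, , drop = FALSE])
    z <- z + signal * bias
  }
  v <- z
  v[.PROB_SCORES] <- stats::plogis(z[.PROB_SCORES] - 1)
  v["NLS"] <- stats::plogis(z["NLS"] - 1)
  v["TM"] <- max(0, round(z["TM"]))
  v[paste0("Tango", 1:6)] <- pmax(0, z[paste0("Tango", 1:6)] + 1)
  validate_scores(v)
}

#' Deterministic mock external-score provider
#'
#' @param seed integer master seed; each record draws from a sub-seed
#'   derived from its id, so scores do not depend on extraction order.
#' @param signal bias strength passed to [mock_scores()].
#' @return provider function `function(id, labels)`.
#' @export
mock_provider <- function(seed, signal = 1) {
  seed <- as.integer(seed)
  function(id, labels = NULL)
    mock_scores((seed * 7919 + .str_hash(id)) %% 2147483647L,
                class_hint = labels, signal = signal)
}

#' The shipped GO cellular-component to compartment map
#'
#' 27 cellular-component GO terms mapped to the 11 compartments;
#' sub-location terms (e.g. mitochondrial inner membrane) map to their
#' parent compartment, and the generic membrane term maps to
#' `cell_membrane`.
#'
#' @return named character vector (names = GO ids, values = compartments).
#' @export
go_compartment_map <- function() {
  if (!is.null(.plantloc_cache$gomap)) return(.plantloc_cache$gomap)
  f <- system.file("extdata", "go_compartment_map.json",
                   package = "plantloc", mustWork = TRUE)
  m <- unlist(jsonlite::read_json(f))
  stopifnot(all(grepl("^GO:[0-9]{7}$", names(m))),
            all(m %in% COMPARTMENTS))
  .plantloc_cache$gomap <- m
  m
}

#' Load an annotated GO reference
#'
#' @param fasta_path FASTA of reference sequences.
#' @param annot_path TSV `id<TAB>GO:...,GO:...` (comma-separated terms).
#' @return list with `dataset` and `go` (list of GO id vectors per id).
#' @export
read_annotated_reference <- function(fasta_path, annot_path) {
  ds <- read_fasta(fasta_path)
  lines <- readLines(annot_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  go <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) >= 2)
      go[[f[1]]] <- trimws(strsplit(f[2], ",", fixed = TRUE)[[1]])
  }
  list(dataset = ds, go = go)
}

# default similarity backend: Smith-Waterman local alignment (BLOSUM62,
# gap open 11 / extend 1) with a Karlin-Altschul-style approximate e-value
.alignment_backend <- function(query, reference_dataset) {
  subject <- Biostrings::AAStringSet(reference_dataset$sequence)
  names(subject) <- reference_dataset$id
  s <- Biostrings::score(Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(rep(query, length(subject))),
    subject = subject, type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1))
  m <- nchar(query)
  n <- sum(nchar(reference_dataset$sequence))
  ev <- 0.041 * m * n * exp(-0.267 * s)
  ord <- order(ev, match(reference_dataset$id, reference_dataset$id))
  data.frame(id = reference_dataset$id[ord], evalue = ev[ord],
             stringsAsFactors = FALSE)
}

#' GO-homology feature of one query sequence
#'
#' Searches the annotated reference with the similarity backend, takes the
#' best hit under the e-value cutoff, and maps the hit's first GO term
#' found in the compartment map to its categorical code (position in
#' [compartment_labels()]). Returns the sentinel 0 when there is no hit at
#' the cutoff, no mapped term, or the backend fails (with a warning).
#'
#' @param sequence query amino-acid sequence.
#' @param reference list from [read_annotated_reference()].
#' @param map GO-to-compartment map (default [go_compartment_map()]).
#' @param evalue_cutoff maximum e-value (default 1e-5).
#' @param backend ranked-search function
#'   `function(query, reference_dataset) -> data.frame(id, evalue)`.
#' @return integer code in 0..11.
#' @export
go_homology_feature <- function(sequence, reference,
                                map = go_compartment_map(),
                                evalue_cutoff = 1e-5, backend = NULL) {
  if (is.null(backend)) backend <- .alignment_backend
  hits <- tryCatch(backend(sequence, reference$dataset),
                   error = function(e) {
                     warning("similarity backend unavailable (",
                             conditionMessage(e),
                             "); homology feature set to 0")
                     NULL
                   })
  if (is.null(hits) || !nrow(hits)) return(0L)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    terms <- reference$go[[hits$id[i]]]
    mapped <- map[terms]
    mapped <- mapped[!is.na(mapped)]
    if (length(mapped))
      return(match(mapped[[1]], COMPARTMENTS))
  }
  0L
}

#' Homology codes for a whole dataset
#'
#' @inheritParams go_homology_feature
#' @param dataset a `plantloc_dataset` of queries.
#' @return named integer vector of codes per query id.
#' @export
go_homology_codes <- function(dataset, reference,
                              map = go_compartment_map(),
                              evalue_cutoff = 1e-5, backend = NULL) {
  stats::setNames(vapply(dataset$sequence, function(s)
    go_homology_feature(s, reference, map, evalue_cutoff, backend),
    integer(1)), dataset$id)
}
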