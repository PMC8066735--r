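# FASTA / label-table input and the core dataset container.
#
# A dataset is a plain data.frame (class "plantloc_dataset") with columns
# id, sequence, label1, label2. Labels use the 11 canonical compartment
# codes; label2 is NA except for dual-location records.

#' Canonical compartment codes
#'
#' The 11 plant subcellular compartments supported by the classifier, in
#' canonical order (this is also the class order of every trained model).
#'
#' @return character vector of length 11.
#' @export
compartment_labels <- function() COMPARTMENTS

# case-insensitive validation of compartment codes
normalize_compartment <- function(x) {
  out <- tolower(trimws(x))
  bad <- !is.na(out) & !(out %in% COMPARTMENTS)
  if (any(bad))
    stop("unknown compartment label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         "; valid codes are: ", paste(COMPARTMENTS, collapse = ", "))
  out
}

# ambiguity handling for non-canonical residue letters:
#   map    - U->C, O->K, B->N, Z->Q, J->L, drop X (default)
#   drop   - drop every non-canonical letter
#   reject - error on any non-canonical letter
.AMBIG_MAP <- c(U = "C", O = "K", B = "N", Z = "Q", J = "L")

normalize_sequence <- function(seq, policy = c("map", "drop", "reject"),
                               id = "?") {
  policy <- match.arg(policy)
  s <- toupper(gsub("[ \t*]", "", seq))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  extra <- setdiff(unique(chars), AA)
  if (length(extra)) {
    if (policy == "reject")
      stop("sequence '", id, "' contains non-canonical residue(s): ",
           paste(extra, collapse = ", "))
    if (policy == "map") {
      mapped <- .AMBIG_MAP[chars]
      chars <- ifelse(is.na(mapped), chars, mapped)
    }
    chars <- chars[chars %in% AA]
  }
  if (!length(chars))
    stop("sequence '", id, "' is empty after residue normalization")
  paste(chars, collapse = "")
}

#' Construct a validated dataset
#'
#' @param id character vector of unique record identifiers.
#' @param sequence character vector of amino-acid sequences (already over
#'   the 20-letter alphabet; use [read_fasta()] for ambiguity handling).
#' @param label1,label2 optional compartment codes (NA = unlabeled).
#' @return a `plantloc_dataset` data.frame.
#' @export
plantloc_dataset <- function(id, sequence, label1 = NA_character_,
                             label2 = NA_character_) {
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  sequence <- toupper(as.character(sequence))
  bad <- grepl(paste0("[^", paste(AA, collapse = ""), "]"), sequence) |
    nchar(sequence) < 1
  if (any(bad))
    stop("invalid sequence(s) for record(s): ",
         paste(id[bad], collapse = ", "))
  d <- data.frame(id = id, sequence = sequence,
                  label1 = normalize_compartment(rep_len(label1, length(id))),
                  label2 = normalize_compartment(rep_len(label2, length(id))),
                  stringsAsFactors = FALSE)
  class(d) <- c("plantloc_dataset", "data.frame")
  d
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param policy how to treat non-canonical residue letters (B, J, O, U, X,
#'   Z): `"map"` (default; U>C, O>K, B>N, Z>Q, J>L, drop X), `"drop"`
#'   (remove them), or `"reject"` (error).
#' @return a `plantloc_dataset` with empty labels, in file order.
#' @export
read_fasta <- function(path, policy = c("map", "drop", "reject")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty dataset: no FASTA entries in ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA at line ", nonblank[1],
         ": expected '>' header, got: ", trimws(lines[nonblank[1]]))
  hdr <- nonblank[startsWith(trimws(lines[nonblank]), ">")]
  seqs <- Biostrings::readAAStringSet(path)
  if (!length(seqs)) stop("empty dataset: no FASTA entries in ", path)
  if (any(Biostrings::width(seqs) == 0)) {
    i <- which(Biostrings::width(seqs) == 0)[1]
    stop("malformed FASTA near line ", hdr[i], ": entry '",
         names(seqs)[i], "' has no sequence")
  }
  ids <- sub("\\s.*$", "", names(seqs))
  raw <- as.character(seqs)
  clean <- mapply(normalize_sequence, raw, id = ids,
                  MoreArgs = list(policy = policy), USE.NAMES = FALSE)
  plantloc_dataset(ids, clean)
}

#' Write a dataset to FASTA
#'
#' @param dataset a `plantloc_dataset`.
#' @param path output file path.
#' @export
write_fasta <- function(dataset, path) {
  x <- Biostrings::AAStringSet(dataset$sequence)
  names(x) <- dataset$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Attach compartment labels from a TSV file
#'
#' The label table dialect is `id<TAB>label1[<TAB>label2]`; lines starting
#' with `#` are ignored. Rows whose id is not in the dataset are skipped
#' with a warning; unknown compartment strings are an error.
#'
#' @param path label TSV path.
#' @param dataset a `plantloc_dataset` to attach labels to.
#' @return the dataset with `label1`/`label2` filled in.
#' @export
read_labels <- function(path, dataset) {
  if (!file.exists(path)) stop("label file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed label row (need id<TAB>label): ", ln)
    i <- match(f[1], dataset$id)
    if (is.na(i)) {
      warning("label row skipped, id not in dataset: ", f[1])
      next
    }
    dataset$label1[i] <- normalize_compartment(f[2])
    dataset$label2[i] <- if (length(f) >= 3 && nzchar(f[3]))
      normalize_compartment(f[3]) else NA_character_
    if (!is.na(dataset$label2[i]) && dataset$label2[i] == dataset$label1[i])
      dataset$label2[i] <- NA_character_
  }
  dataset
}

#' Label sets of a dataset
#'
#' @param dataset a `plantloc_dataset`.
#' @return list of per-record label sets (character vectors of length 0,
#'   1 or 2, sorted by canonical compartment order).
#' @export
label_sets <- function(dataset) {
  mapply(function(a, b) {
    s <- c(a, b)
    s <- s[!is.na(s)]
    s[order(match(s, COMPARTMENTS))]
  }, dataset$label1, dataset$label2, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Canonical single-string key of label sets ("cytoplasm+nucleus")
#'
#' @param sets list of label sets as from [label_sets()].
#' @return character vector of keys.
#' @export
label_key <- function(sets) {
  vapply(sets, function(s) paste(s, collapse = "+"), character(1))
}
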