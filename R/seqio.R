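# Sequence containers are plain tibbles with columns id, seq, description.
# DNA is stored uppercase over A,C,G,T,N; proteins over the 20 amino acids
# plus X (unknown) and * (stop).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build a sequence tibble
#'
#' Constructs the tibble representation used for all sequence sets in
#' famscan (columns `id`, `seq`, `description`), validating ids and
#' residues for the given alphabet.
#'
#' @param id Character vector of unique, non-empty sequence ids.
#' @param seq Character vector of residues (same length as `id`).
#' @param description Optional free-text descriptions.
#' @param alphabet `"dna"` or `"protein"`.
#' @return A tibble with columns `id`, `seq`, `description`.
#' @export
seq_tbl <- function(id, seq, description = "", alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(id) != length(seq)) stop("id and seq must have equal length")
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1]])
  if (any(!nzchar(seq))) {
    stop("empty sequence for id: ", id[!nzchar(seq)][[1]])
  }
  seq <- switch(alphabet,
    dna = validate_dna(seq, id),
    protein = validate_protein(seq, id)
  )
  tibble(id = id, seq = seq,
         description = rep_len(as.character(description), length(id)))
}

# Uppercases, maps non-ACGTN IUPAC ambiguity codes to N (with one warning),
# errors on anything else.
validate_dna <- function(seq, id = seq_along(seq)) {
  iupac <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "U")
  has_iupac <- grepl(paste0("[", paste(iupac, collapse = ""), "]"), seq)
  if (any(has_iupac)) {
    warning("non-ACGTN IUPAC codes mapped to N in: ",
            paste(utils::head(id[has_iupac], 3), collapse = ", "),
            call. = FALSE)
    seq <- gsub("[RYSWKMBDHVU]", "N", seq)
  }
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("non-DNA characters in sequence: ", id[bad][[1]])
  }
  seq
}

# "-" is permitted so aligned protein records share the container
validate_protein <- function(seq, id = seq_along(seq)) {
  bad <- grepl(paste0("[^", paste(AA20, collapse = ""), "X*-]"), seq)
  if (any(bad)) stop("non-protein characters in sequence: ", id[bad][[1]])
  seq
}

#' Read a FASTA file into a sequence tibble
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"auto"` (guess from residue content), `"dna"` or
#'   `"protein"`.
#' @return A tibble with columns `id`, `seq`, `description`. The id is the
#'   first whitespace-delimited token of the header; the remainder is kept
#'   as `description`. Record order is preserved.
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- id[duplicated(id)]
  if (length(dup)) stop("duplicate sequence id: ", dup[[1]])
  seq <- toupper(as.character(set))
  if (alphabet == "auto") {
    alphabet <- if (all(!grepl("[^ACGTNRYSWKMBDHVU]", seq))) "dna" else "protein"
  }
  seq_tbl(id, seq, desc, alphabet = alphabet)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq` (and optionally
#'   `description`).
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  desc <- if ("description" %in% names(seqs)) seqs$description else ""
  desc <- rep_len(desc, nrow(seqs))
  header <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  set <- Biostrings::BStringSet(setNames(seqs$seq, header))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Reverse-complement DNA sequences
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements (N maps to N).
#' @export
reverse_complement <- function(x) {
  x <- validate_dna(toupper(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
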