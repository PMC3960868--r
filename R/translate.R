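# Genetic-code translation and six-frame translation with exact coordinate
# maps. All genomic coordinates are 0-based half-open; GFF3 emission converts
# to 1-based closed at the output boundary.

#' Translate coding sequence to protein
#'
#' Translates with the standard genetic code by default. One residue is
#' produced per full codon; a trailing partial codon is ignored; stop codons
#' are rendered `"*"`; any codon containing `N` becomes `"X"`.
#'
#' @param cds Character vector of DNA sequences, each of length >= 3.
#' @param code A named character vector mapping the 64 codons to amino
#'   acids, as returned by [read_genetic_code()]; `NULL` for the standard
#'   code.
#' @return Character vector of protein sequences.
#' @export
translate_cds <- function(cds, code = NULL) {
  cds <- validate_dna(toupper(cds))
  n <- nchar(cds)
  if (any(n < 3L)) stop("coding sequence shorter than one codon")
  trimmed <- substr(cds, 1L, (n %/% 3L) * 3L)
  gc <- if (is.null(code)) Biostrings::GENETIC_CODE else code
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(trimmed),
    genetic.code = gc, if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

#' Read a plain-text genetic-code table
#'
#' The file has two whitespace-separated columns: codon and the single-letter
#' amino acid (or `*` for stop), one row per codon, 64 rows.
#'
#' @param path Path to the table.
#' @return A named character vector usable as the `code` argument of
#'   [translate_cds()].
#' @export
read_genetic_code <- function(path) {
  tab <- utils::read.table(path, header = FALSE, col.names = c("codon", "aa"),
                           colClasses = "character")
  codon <- toupper(tab$codon)
  if (length(codon) != 64L || anyDuplicated(codon)) {
    stop("genetic-code table must list all 64 codons exactly once")
  }
  code <- setNames(toupper(tab$aa), codon)
  code <- code[names(Biostrings::GENETIC_CODE)]
  attributes(code) <- attributes(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  code
}

#' Six-frame translation of genome contigs
#'
#' Translates each contig in all three forward frames and all three frames of
#' the reverse complement. Internal stops are kept as `"*"`; downstream
#' scanning splits on them. The genomic coordinates of any peptide position
#' are recovered with [codon_interval()].
#'
#' @param contigs Sequence tibble of DNA contigs (each of length >= 3).
#' @param code Optional genetic-code table (see [translate_cds()]).
#' @return A tibble with one row per (contig, strand, frame): columns
#'   `contig_id`, `strand` (`"+"`/`"-"`), `frame` (offset 0, 1 or 2),
#'   `peptide`, `contig_length`.
#' @export
six_frame_translate <- function(contigs, code = NULL) {
  stopifnot(all(c("id", "seq") %in% names(contigs)))
  if (any(nchar(contigs$seq) < 3L)) stop("contig shorter than one codon")
  rows <- purrr::map(seq_len(nrow(contigs)), function(i) {
    fwd <- toupper(contigs$seq[[i]])
    rev <- reverse_complement(fwd)
    L <- nchar(fwd)
    frames <- purrr::map(0:2, function(f) {
      keep <- L - f >= 3L
      tibble(
        contig_id = contigs$id[[i]],
        strand = c("+", "-"),
        frame = f,
        peptide = if (keep) {
          translate_cds(c(substr(fwd, f + 1L, L), substr(rev, f + 1L, L)),
                        code = code)
        } else c("", ""),
        contig_length = L
      )
    })
    dplyr::bind_rows(frames)
  })
  out <- dplyr::bind_rows(rows)
  out[nzchar(out$peptide), , drop = FALSE]
}

#' Genomic interval of a translated codon
#'
#' The exact coordinate map of [six_frame_translate()]: peptide position `p`
#' (0-based) of a frame translation maps to a 3-bp genomic interval. On the
#' forward strand with frame offset `f` this is `[f + 3p, f + 3p + 3)`; on
#' the reverse strand of a contig of length `L` it is
#' `[L - f - 3p - 3, L - f - 3p)`.
#'
#' @param strand `"+"` or `"-"` (vectorised).
#' @param frame Frame offset 0, 1 or 2.
#' @param p 0-based peptide position.
#' @param contig_length Contig length in bp.
#' @return A tibble with 0-based half-open columns `start`, `end`.
#' @export
codon_interval <- function(strand, frame, p, contig_length) {
  start <- ifelse(strand == "+",
                  frame + 3 * p,
                  contig_length - frame - 3 * p - 3)
  tibble(start = as.integer(start), end = as.integer(start + 3L))
}
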