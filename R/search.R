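# Log-odds domain search against a profile HMM. The dynamic programming
# kernels live in src/phmm.cpp; these wrappers handle residue encoding,
# log-odds precomputation and hit assembly.

# residue codes 1..20 = AA20, 21 = X (scored at background, i.e. 0 bits)
encode_protein <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  code <- match(chars, AA20)
  code[chars == "X"] <- 21L
  if (anyNA(code)) {
    stop("residue outside alphabet: ", chars[is.na(code)][[1]])
  }
  code
}

# K x 21 match-emission log-odds (bits); column 21 (X) is zero
lodds_table <- function(hmm) {
  lod <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  cbind(lod, X = 0)
}

trans_log2 <- function(hmm) lapply(hmm$trans, log2)

#' Viterbi score of a protein against a profile
#'
#' Maximum-scoring single-domain local alignment: the path enters at any
#' match state (uniform entry, `-log2(K)` bits), traverses
#' match/insert/delete states, and exits after any match state. Match
#' emissions score `log2(e / background)` bits; insert-state residues and
#' residues outside the aligned span are emitted at background and
#' contribute 0 bits. An empty aligned span is not a legal alignment, so the
#' score of an unrelated sequence may be negative. Ties are broken
#' deterministically, preferring Match over Delete over Insert.
#'
#' @param hmm A `profile_hmm`.
#' @param protein Non-empty protein string (`X` allowed, scored 0).
#' @return A list with `bit_score`, `path` (string over `M`/`I`/`D`),
#'   `target_start`/`target_end` (0-based half-open residue interval of the
#'   aligned span), `state_first`/`state_last` (match states used).
#' @export
viterbi_score <- function(hmm, protein) {
  if (!nzchar(protein)) stop("protein must be non-empty")
  obs <- encode_protein(protein)
  res <- phmm_viterbi_cpp(obs, lodds_table(hmm), trans_log2(hmm),
                          -log2(hmm$K))
  consumed <- res$i[!is.na(res$i)]
  list(
    bit_score = res$score,
    path = res$ops,
    target_start = min(consumed) - 1L,
    target_end = max(consumed),
    state_first = res$k[[1]],
    state_last = res$k[[length(res$k)]]
  )
}

#' Forward score of a protein against a profile
#'
#' Total log-odds over the same single-domain local alignment ensemble as
#' [viterbi_score()], computed in log space; always at least the Viterbi
#' score.
#'
#' @inheritParams viterbi_score
#' @return Bit score (numeric scalar).
#' @export
forward_score <- function(hmm, protein) {
  if (!nzchar(protein)) stop("protein must be non-empty")
  phmm_forward_cpp(encode_protein(protein), lodds_table(hmm),
                   trans_log2(hmm), -log2(hmm$K))
}

#' Scan proteins for domain hits
#'
#' Scores every sequence with [viterbi_score()] and keeps the best-scoring
#' span of each protein (at most one hit per protein: the model is
#' single-domain) when it reaches `threshold_bits`.
#'
#' @param hmm A `profile_hmm`.
#' @param proteins Sequence tibble (columns `id`, `seq`).
#' @param threshold_bits Minimum bit score to report. Finite; use the
#'   confirmation threshold for final acceptance.
#' @param keep_path Retain the alignment path string (needed by
#'   [implicit_msa()]).
#' @return A tibble of hits sorted by descending `bit_score` (ties by id):
#'   `target_id`, `target_start`, `target_end` (0-based half-open),
#'   `bit_score`, `state_first`, `state_last`, `path`.
#' @export
scan_proteins <- function(hmm, proteins, threshold_bits, keep_path = TRUE) {
  if (is.na(threshold_bits) || identical(threshold_bits, Inf)) {
    stop("threshold_bits must be finite or -Inf")
  }
  if (nrow(proteins) == 0L) return(empty_hits())
  codes <- lapply(proteins$seq, encode_protein)
  lens <- lengths(codes)
  starts <- cumsum(c(1L, lens[-length(lens)]))
  lod <- lodds_table(hmm)
  tl <- trans_log2(hmm)
  entry <- -log2(hmm$K)
  scores <- phmm_score_many_cpp(unlist(codes), starts, lens, lod, tl, entry)
  keep <- which(scores >= threshold_bits)
  hits <- purrr::map(keep, function(j) {
    v <- phmm_viterbi_cpp(codes[[j]], lod, tl, entry)
    consumed <- v$i[!is.na(v$i)]
    tibble(
      target_id = proteins$id[[j]],
      target_start = min(consumed) - 1L,
      target_end = max(consumed),
      bit_score = v$score,
      state_first = v$k[[1]],
      state_last = v$k[[length(v$k)]],
      path = if (keep_path) v$ops else NA_character_
    )
  })
  out <- dplyr::bind_rows(c(list(empty_hits()), hits))
  dplyr::arrange(out, dplyr::desc(.data$bit_score), .data$target_id)
}

empty_hits <- function() {
  tibble(target_id = character(), target_start = integer(),
         target_end = integer(), bit_score = numeric(),
         state_first = integer(), state_last = integer(),
         path = character())
}

#' Write domain hits to TSV
#'
#' @param hits Hit tibble from [scan_proteins()] or [scan_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  readr::write_tsv(dplyr::select(hits, -dplyr::any_of("path")), path)
  invisible(path)
}

#' Plot domain-hit bit scores
#'
#' @param object Hit tibble from [scan_proteins()] or [scan_genome()].
#' @param threshold Optional horizontal reference line (e.g. the
#'   confirmation threshold).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_hit_scores <- function(object, threshold = NULL, ...) {
  object <- dplyr::mutate(object,
                          rank = rank(-.data$bit_score, ties.method = "first"))
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$rank, y = .data$bit_score)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "hit rank", y = "bit score")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}
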