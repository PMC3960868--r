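# Candidate regions -> gene models. A deliberately naive single-exon caller
# stands in for a trained ab-initio gene finder; multi-exon recovery is
# delegated to the pluggable external-predictor interface. The CDS-track and
# genome-track model sets are merged by reciprocal overlap.

empty_gene_models <- function() {
  tibble(gene_id = character(), contig_id = character(), start = integer(),
         end = integer(), strand = character(),
         cds_intervals = list(), protein = character(), source = character(),
         partial = logical(), confirmation_score = numeric())
}

gene_model_row <- function(contig_id, start, end, strand, cds, protein,
                           source, partial, confirmation_score = NA_real_,
                           gene_id = NA_character_) {
  tibble(gene_id = gene_id, contig_id = contig_id,
         start = as.integer(start), end = as.integer(end), strand = strand,
         cds_intervals = list(cds), protein = protein, source = source,
         partial = partial, confirmation_score = confirmation_score)
}

#' Naive single-exon gene call around a domain hit
#'
#' Extends the reading frame of the hit 5' to the nearest in-frame ATG
#' after the nearest upstream in-frame stop, and 3' to the first in-frame
#' stop (included in the CDS). If the 3' extension runs off the region edge
#' the model ends at the last full codon and is flagged partial; likewise
#' 5' when neither an upstream stop nor a start codon is found before the
#' edge. If an upstream in-frame stop exists but no ATG lies between it and
#' the hit, or the resulting open reading frame is shorter than
#' `min_orf_codons`, no model is returned (with a logged reason).
#'
#' @param region One-row region tibble from [extract_region()] (must carry
#'   the hit's `box_start`/`box_end` columns).
#' @param assembly Sequence tibble of DNA contigs.
#' @param min_orf_codons Minimum ORF length in codons (default 60,
#'   approximately the domain length).
#' @return A one-row gene-model tibble, or an empty one if no acceptable
#'   ORF exists.
#' @export
call_gene_naive <- function(region, assembly, min_orf_codons = 60L) {
  stopifnot(nrow(region) == 1L)
  dna <- region_sequences(region, assembly)$seq
  if (region$strand == "-") {
    dna <- reverse_complement(dna)
    local_box <- region$end - region$box_end
  } else {
    local_box <- region$box_start - region$start
  }
  L <- nchar(dna)
  codon_at <- function(j) substr(dna, j + 1L, j + 3L)
  is_stop <- function(cod) cod %in% c("TAA", "TAG", "TGA")

  # 3': first in-frame stop at or after the box start
  end_local <- NA_integer_; partial3 <- FALSE
  j <- local_box
  while (j + 3L <= L) {
    if (is_stop(codon_at(j))) { end_local <- j + 3L; break }
    j <- j + 3L
  }
  if (is.na(end_local)) { end_local <- j; partial3 <- TRUE }

  # 5': nearest upstream in-frame stop, then first ATG after it
  up_stop <- NA_integer_
  j <- local_box - 3L
  while (j >= 0L) {
    if (is_stop(codon_at(j))) { up_stop <- j; break }
    j <- j - 3L
  }
  scan_from <- if (is.na(up_stop)) local_box %% 3L else up_stop + 3L
  start_local <- NA_integer_; partial5 <- FALSE
  j <- scan_from
  while (j <= local_box) {
    if (codon_at(j) == "ATG") { start_local <- j; break }
    j <- j + 3L
  }
  if (is.na(start_local)) {
    if (!is.na(up_stop)) {
      message("call_gene_naive: no start codon between upstream stop and hit (",
              region$contig_id, ":", region$start, "-", region$end, ")")
      return(empty_gene_models())
    }
    start_local <- scan_from; partial5 <- TRUE
  }

  n_codons <- (end_local - start_local) %/% 3L
  if (n_codons < min_orf_codons) {
    message("call_gene_naive: ORF of ", n_codons, " codons below minimum of ",
            min_orf_codons, " (", region$contig_id, ":", region$start, "-",
            region$end, ")")
    return(empty_gene_models())
  }

  cds <- substr(dna, start_local + 1L, end_local)
  protein <- sub("\\*$", "", translate_cds(cds))
  if (region$strand == "+") {
    gstart <- region$start + start_local
    gend <- region$start + end_local
  } else {
    gstart <- region$end - end_local
    gend <- region$end - start_local
  }
  gene_model_row(region$contig_id, gstart, gend, region$strand,
                 tibble(start = as.integer(gstart), end = as.integer(gend)),
                 protein, "genome_track", partial5 || partial3)
}

#' Run a user-configured external gene predictor on a region
#'
#' Writes the region sequence to a temporary FASTA, substitutes it (and an
#' output path) into `command_template` (`{input}`/`{output}`
#' placeholders), executes the command, parses its GFF3 output, lifts
#' coordinates from region-local to genomic, and drops models whose protein
#' fails the confirmation score. A non-zero exit status or unparseable
#' output yields a warning and an empty result; the pipeline continues.
#'
#' @param region One-row region tibble.
#' @param assembly Sequence tibble of DNA contigs.
#' @param command_template Shell command with `{input}` and `{output}`
#'   placeholders.
#' @param hmm Profile used to confirm predicted proteins.
#' @param confirm_bits Confirmation threshold in bits.
#' @param parser Output format; only `"gff3"` is supported.
#' @return A gene-model tibble (possibly empty).
#' @export
run_external_predictor <- function(region, assembly, command_template, hmm,
                                   confirm_bits = 20, parser = "gff3") {
  parser <- match.arg(parser, "gff3")
  fa <- tempfile(fileext = ".fa")
  out <- tempfile(fileext = ".gff3")
  on.exit(unlink(c(fa, out)), add = TRUE)
  write_fasta(region_sequences(region, assembly, ids = "region"), fa)
  cmd <- gsub("{output}", out, gsub("{input}", fa, command_template,
                                    fixed = TRUE), fixed = TRUE)
  status <- suppressWarnings(system(cmd, ignore.stdout = TRUE))
  if (status != 0L || !file.exists(out)) {
    warning("external predictor failed (exit ", status, ") on ",
            region$contig_id, ":", region$start, "-", region$end,
            call. = FALSE)
    return(empty_gene_models())
  }
  feats <- tryCatch(read_gff3(out), error = function(e) {
    warning("unparseable predictor output: ", conditionMessage(e),
            call. = FALSE)
    NULL
  })
  if (is.null(feats) || nrow(feats) == 0L) return(empty_gene_models())
  cds <- feats[feats$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) return(empty_gene_models())
  region_dna <- region_sequences(region, assembly)$seq
  models <- purrr::map(split(cds, cds$parent), function(ex) {
    ex <- ex[order(ex$start), , drop = FALSE]
    parts <- substr(rep(region_dna, nrow(ex)), ex$start + 1L, ex$end)
    if (ex$strand[[1]] == "-") {
      parts <- rev(vapply(parts, reverse_complement, character(1)))
    }
    cds_seq <- paste(parts, collapse = "")
    if (nchar(cds_seq) < 3L) return(NULL)
    protein <- sub("\\*$", "", translate_cds(cds_seq))
    # a prediction whose CDS translates with internal stops cannot encode
    # the domain; treat it like any model failing confirmation
    if (grepl("*", protein, fixed = TRUE)) return(NULL)
    score <- viterbi_score(hmm, protein)$bit_score
    if (score < confirm_bits) return(NULL)
    gene_model_row(
      region$contig_id,
      region$start + min(ex$start), region$start + max(ex$end),
      ex$strand[[1]],
      tibble(start = as.integer(region$start + ex$start),
             end = as.integer(region$start + ex$end)),
      protein, "external", partial = FALSE, confirmation_score = score
    )
  })
  dplyr::bind_rows(c(list(empty_gene_models()), models))
}

#' Merge CDS-track and genome-track gene sets
#'
#' The two prediction sources are combined into what is presumably the full
#' family complement: a genome-track model is discarded when a CDS-track
#' model on the same contig and strand overlaps it with reciprocal overlap
#' of at least `min_reciprocal_overlap` (overlap length divided by each
#' model's span); CDS-track models are always kept. Output is sorted by
#' (contig, start) and gene ids are assigned deterministically.
#'
#' @param cds_track,genome_track Gene-model tibbles.
#' @param min_reciprocal_overlap Reciprocal-overlap fraction above which the
#'   two tracks are considered the same gene.
#' @param id_prefix Prefix for assigned gene ids.
#' @return Merged gene-model tibble with `gene_id` filled in.
#' @export
merge_gene_sets <- function(cds_track, genome_track,
                            min_reciprocal_overlap = 0.5,
                            id_prefix = "gene") {
  keep <- rep(TRUE, nrow(genome_track))
  for (i in seq_len(nrow(genome_track))) {
    g <- genome_track[i, ]
    cand <- cds_track[cds_track$contig_id == g$contig_id &
                        cds_track$strand == g$strand, , drop = FALSE]
    if (nrow(cand) == 0L) next
    ovl <- pmin(cand$end, g$end) - pmax(cand$start, g$start)
    rec <- pmin(ovl / (g$end - g$start), ovl / (cand$end - cand$start))
    if (any(rec >= min_reciprocal_overlap)) keep[[i]] <- FALSE
  }
  out <- dplyr::bind_rows(cds_track, genome_track[keep, , drop = FALSE])
  out <- dplyr::arrange(out, .data$contig_id, .data$start, .data$end,
                        .data$strand)
  out$gene_id <- sprintf("%s_%04d", id_prefix, seq_len(nrow(out)))
  out
}

#' Machine-readable QC report for a gene-model set
#'
#' Replaces the manual-inspection checkpoint of semi-automatic pipelines:
#' per model, the provenance track, partial flag, confirmation score, exon
#' count and protein length, for human review.
#'
#' @param models Gene-model tibble.
#' @return A tibble, one row per model.
#' @export
qc_report <- function(models) {
  tibble(
    gene_id = models$gene_id,
    contig_id = models$contig_id,
    start = models$start, end = models$end, strand = models$strand,
    source = models$source,
    partial = models$partial,
    confirmation_score = models$confirmation_score,
    n_exons = vapply(models$cds_intervals, nrow, integer(1)),
    protein_length = nchar(models$protein)
  )
}
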