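# Direct domain search in a genome assembly: six-frame translation,
# stop-free segment scanning, coordinate lift-over and window extraction.

#' Scan a genome assembly for domain hits
#'
#' Each contig is translated in all six reading frames; every frame peptide
#' is split at stop codons into stop-free segments; segments of at least
#' `min_peptide` residues are scanned with [scan_proteins()]; retained hits
#' are mapped back to genomic coordinates through the frame coordinate map.
#' Overlapping hits from different frames on the same strand are collapsed
#' to the best-scoring one (ties by lowest frame offset).
#'
#' A domain whose reading frame is interrupted by an intron carrying an
#' in-frame stop can be missed — the known limitation of translated-genome
#' searches. The default `min_peptide = 40` sits below the 56–60 aa domain
#' length so truncated domain halves remain detectable.
#'
#' @param hmm A `profile_hmm`.
#' @param assembly Sequence tibble of DNA contigs.
#' @param threshold_bits Minimum bit score to report.
#' @param min_peptide Minimum stop-free segment length to scan.
#' @return A tibble of genomic domain hits: `contig_id`, `strand`, `frame`,
#'   `box_start`, `box_end` (0-based half-open genomic interval of the
#'   aligned codons), `bit_score`, `target_start`, `target_end` (residue
#'   interval within the scanned segment), `segment_peptide_start` (0-based
#'   position of the segment within the frame translation), `path`.
#' @export
scan_genome <- function(hmm, assembly, threshold_bits, min_peptide = 40L) {
  frames <- six_frame_translate(assembly)
  hits <- purrr::map(seq_len(nrow(frames)), function(r) {
    fr <- frames[r, ]
    segs <- stop_free_segments(fr$peptide)
    segs <- segs[nchar(segs$seq) >= min_peptide, , drop = FALSE]
    if (nrow(segs) == 0L) return(NULL)
    seg_hits <- scan_proteins(
      hmm,
      tibble(id = as.character(seq_len(nrow(segs))), seq = segs$seq),
      threshold_bits
    )
    if (nrow(seg_hits) == 0L) return(NULL)
    seg_off <- segs$offset[as.integer(seg_hits$target_id)]
    p0 <- seg_off + seg_hits$target_start        # 0-based peptide positions
    p1 <- seg_off + seg_hits$target_end          # exclusive
    if (fr$strand == "+") {
      box_start <- fr$frame + 3L * p0
      box_end <- fr$frame + 3L * p1
    } else {
      box_start <- fr$contig_length - fr$frame - 3L * p1
      box_end <- fr$contig_length - fr$frame - 3L * p0
    }
    tibble(
      contig_id = fr$contig_id, strand = fr$strand, frame = fr$frame,
      box_start = as.integer(box_start), box_end = as.integer(box_end),
      bit_score = seg_hits$bit_score,
      target_start = seg_hits$target_start, target_end = seg_hits$target_end,
      segment_peptide_start = seg_off,
      contig_length = fr$contig_length,
      path = seg_hits$path
    )
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) return(empty_genomic_hits())
  collapse_frame_hits(out)
}

empty_genomic_hits <- function() {
  tibble(contig_id = character(), strand = character(), frame = integer(),
         box_start = integer(), box_end = integer(), bit_score = numeric(),
         target_start = integer(), target_end = integer(),
         segment_peptide_start = integer(), contig_length = integer(),
         path = character())
}

# split a frame peptide at '*' into stop-free segments with their 0-based
# peptide offsets
stop_free_segments <- function(peptide) {
  parts <- strsplit(peptide, "*", fixed = TRUE)[[1]]
  lens <- nchar(parts)
  offsets <- cumsum(c(0L, lens + 1L))[seq_along(parts)]
  tibble(seq = parts, offset = as.integer(offsets))[lens > 0L, , drop = FALSE]
}

# keep the best-scoring hit among same-strand overlapping hits from
# different frames; ties broken by lowest frame offset
collapse_frame_hits <- function(hits) {
  hits <- dplyr::arrange(hits, .data$contig_id, .data$strand,
                         dplyr::desc(.data$bit_score), .data$frame,
                         .data$box_start)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!keep[[i]]) next
    if (i == nrow(hits)) break
    js <- seq(i + 1L, nrow(hits))
    same <- hits$contig_id[js] == hits$contig_id[[i]] &
      hits$strand[js] == hits$strand[[i]]
    ovl <- hits$box_start[js] < hits$box_end[[i]] &
      hits$box_end[js] > hits$box_start[[i]]
    keep[js[same & ovl]] <- FALSE
  }
  dplyr::arrange(hits[keep, , drop = FALSE],
                 .data$contig_id, .data$box_start)
}

#' Extract the annotation window around a genomic domain hit
#'
#' Retrieves the candidate locus around the start of the detected domain
#' box: `upstream_bp` before it and `downstream_bp` after it, measured on
#' the coding strand. On the `+` strand the region is
#' `[box_start - upstream_bp, box_start + downstream_bp)`; on the `-`
#' strand it is mirrored about the biological box start (the
#' higher-coordinate end): `[box_end - downstream_bp, box_end +
#' upstream_bp)`. Regions are clipped at contig boundaries and flagged.
#'
#' @param hits Genomic hit tibble from [scan_genome()].
#' @param assembly Sequence tibble of DNA contigs (for contig lengths).
#' @param upstream_bp,downstream_bp Window sizes in bp (defaults 300 and
#'   19,700, giving a 20-kb locus).
#' @return A tibble of regions: `contig_id`, `start`, `end` (0-based
#'   half-open), `strand`, `clipped`, plus the originating hit columns
#'   `box_start`, `box_end`, `bit_score`, `frame`.
#' @export
extract_region <- function(hits, assembly, upstream_bp = 300L,
                           downstream_bp = 19700L) {
  stopifnot(upstream_bp >= 0L, downstream_bp >= 0L)
  clen <- setNames(nchar(assembly$seq), assembly$id)
  L <- unname(clen[hits$contig_id])
  raw_start <- ifelse(hits$strand == "+",
                      hits$box_start - upstream_bp,
                      hits$box_end - downstream_bp)
  raw_end <- ifelse(hits$strand == "+",
                    hits$box_start + downstream_bp,
                    hits$box_end + upstream_bp)
  start <- pmax(raw_start, 0L)
  end <- pmin(raw_end, L)
  tibble(
    contig_id = hits$contig_id,
    start = as.integer(start), end = as.integer(end),
    strand = hits$strand,
    clipped = raw_start < 0L | raw_end > L,
    box_start = hits$box_start, box_end = hits$box_end,
    bit_score = hits$bit_score, frame = hits$frame
  )
}

#' Fetch region sequences from an assembly
#'
#' Returns each region's genomic substring (forward-strand orientation).
#'
#' @param regions Region tibble from [extract_region()].
#' @param assembly Sequence tibble of DNA contigs.
#' @param ids Optional ids for the output records.
#' @return Sequence tibble of the regions.
#' @export
region_sequences <- function(regions, assembly, ids = NULL) {
  contig <- setNames(assembly$seq, assembly$id)
  seqs <- substr(contig[regions$contig_id], regions$start + 1L, regions$end)
  if (is.null(ids)) {
    ids <- sprintf("%s:%d-%d(%s)", regions$contig_id, regions$start,
                   regions$end, regions$strand)
  }
  seq_tbl(ids, unname(seqs), alphabet = "dna")
}

#' Write genomic intervals to BED
#'
#' Six-column BED (0-based half-open, matching the internal convention).
#'
#' @param x Tibble with `contig_id`, and either `start`/`end` or
#'   `box_start`/`box_end`, plus optional `strand` and `bit_score`.
#' @param path Output path.
#' @param name_prefix Feature-name prefix.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, name_prefix = "feature") {
  start <- if ("start" %in% names(x)) x$start else x$box_start
  end <- if ("end" %in% names(x)) x$end else x$box_end
  bed <- tibble(
    chrom = x$contig_id, start = start, end = end,
    name = sprintf("%s_%04d", name_prefix, seq_len(nrow(x))),
    score = if ("bit_score" %in% names(x)) round(x$bit_score, 2) else 0,
    strand = if ("strand" %in% names(x)) x$strand else "."
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
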