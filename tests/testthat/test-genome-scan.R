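# plant one single-exon domain CDS in a random contig and return the truth
plant_one <- function(len = 100000L, strand = "-", seed = 5L) {
  hmm <- study_hmm()
  withr::with_seed(seed, {
    bgseq <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
    domain <- profile_consensus(hmm)
    protein <- paste0("M", domain)
    codon_table <- split(names(Biostrings::GENETIC_CODE),
                         unname(Biostrings::GENETIC_CODE))
    cds <- paste0(vapply(strsplit(protein, "")[[1]], function(a) {
      if (a == "M") "ATG" else codon_table[[a]][[1]]
    }, character(1)) |> paste(collapse = ""), "TAA")
    at <- 40000L
  })
  insert <- if (strand == "-") reverse_complement(cds) else cds
  contig <- paste0(substr(bgseq, 1, at), insert,
                   substr(bgseq, at + 1, len - nchar(cds)))
  list(assembly = seq_tbl("chr", contig),
       cds_start = at, cds_end = at + nchar(cds), hmm = hmm,
       # the domain box: codons of the domain only (after the ATG)
       box = if (strand == "-") {
         c(at + nchar(cds) - 3L - 3L * nchar(domain),
           at + nchar(cds) - 3L)
       } else {
         c(at + 3L, at + 3L + 3L * nchar(domain))
       })
}

test_that("a planted minus-strand domain is found at its exact codons", {
  px <- plant_one(strand = "-")
  hits <- scan_genome(px$hmm, px$assembly, 20)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "-")
  # allow end-trimming by local alignment but require the core interval
  expect_lte(px$box[[1]], hits$box_start + 6L)
  expect_gte(px$box[[2]], hits$box_end - 6L)
  expect_gte(hits$box_end - hits$box_start, 3L * 50L)
})

test_that("scanning the reverse-complemented assembly mirrors the hits", {
  fx <- small_fixture()
  hmm <- small_hmm()
  asm <- fx$genome$assembly
  h1 <- scan_genome(hmm, asm, 20)
  h2 <- scan_genome(hmm, seq_tbl(asm$id, reverse_complement(asm$seq)), 20)
  expect_gt(nrow(h1), 0)
  L <- setNames(nchar(asm$seq), asm$id)
  mirrored <- tibble::tibble(
    contig_id = h1$contig_id,
    box_start = unname(L[h1$contig_id]) - h1$box_end,
    box_end = unname(L[h1$contig_id]) - h1$box_start,
    strand = ifelse(h1$strand == "+", "-", "+")
  )
  cols <- c("contig_id", "box_start", "box_end", "strand")
  expect_equal(
    dplyr::arrange(mirrored, contig_id, box_start),
    dplyr::arrange(h2[cols], contig_id, box_start),
    ignore_attr = TRUE
  )
})

test_that("every genome hit's substring translates back to the scored span", {
  fx <- small_fixture()
  hmm <- small_hmm()
  asm <- fx$genome$assembly
  hits <- scan_genome(hmm, asm, 20)
  frames <- six_frame_translate(asm)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    sub <- substr(asm$seq[asm$id == h$contig_id], h$box_start + 1L, h$box_end)
    if (h$strand == "-") sub <- reverse_complement(sub)
    fr <- frames[frames$contig_id == h$contig_id & frames$strand == h$strand &
                   frames$frame == h$frame, ]
    span <- substr(fr$peptide, h$segment_peptide_start + h$target_start + 1L,
                   h$segment_peptide_start + h$target_end)
    expect_equal(translate_cds(sub), span)
  }
})

test_that("random contigs yield no hits at the confirmation threshold", {
  hmm <- study_hmm()
  fails <- 0L
  withr::with_seed(31, {
    for (r in 1:20) {
      contig <- seq_tbl("r", paste(sample(c("A", "C", "G", "T"), 100000L,
                                          TRUE), collapse = ""))
      if (nrow(scan_genome(hmm, contig, 20)) > 0) fails <- fails + 1L
    }
  })
  expect_equal(fails, 0L)
})

test_that("min_peptide filters short stop-free segments", {
  segs <- stop_free_segments("AAAA*BB*CCCCCCCC")
  expect_equal(segs$seq, c("AAAA", "BB", "CCCCCCCC"))
  expect_equal(segs$offset, c(0L, 5L, 8L))
})

test_that("unclipped windows have exactly the configured width", {
  asm <- seq_tbl("c", strrep("A", 30000L))
  hit <- tibble::tibble(contig_id = "c", strand = "+", frame = 0L,
                        box_start = 1000L, box_end = 1171L, bit_score = 50)
  r <- extract_region(hit, asm)
  expect_equal(c(r$start, r$end), c(700L, 20700L))
  expect_equal(r$end - r$start, 20000L)  # 300 upstream + 19,700 downstream
  expect_false(r$clipped)

  near <- dplyr::mutate(hit, box_start = 100L, box_end = 271L)
  r2 <- extract_region(near, asm)
  expect_equal(c(r2$start, r2$end), c(0L, 19800L))
  expect_true(r2$clipped)

  minus <- tibble::tibble(contig_id = "c", strand = "-", frame = 0L,
                          box_start = 24829L, box_end = 25000L,
                          bit_score = 50)
  r3 <- extract_region(minus, asm)
  expect_equal(c(r3$start, r3$end), c(5300L, 25300L))
  expect_false(r3$clipped)
})

test_that("custom window sizes drive the region width", {
  asm <- seq_tbl("c", strrep("A", 5000L))
  hit <- tibble::tibble(contig_id = "c", strand = "+", frame = 0L,
                        box_start = 2000L, box_end = 2171L, bit_score = 50)
  r <- extract_region(hit, asm, upstream_bp = 100L, downstream_bp = 400L)
  expect_equal(r$end - r$start, 500L)
  expect_error(extract_region(hit, asm, upstream_bp = -1L))
})
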