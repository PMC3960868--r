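# helper: a region + hit pair around a hand-built contig
region_for <- function(contig, box_start, box_end, strand = "+",
                       start = 0L, end = nchar(contig$seq)) {
  tibble::tibble(contig_id = contig$id, start = as.integer(start),
                 end = as.integer(end), strand = strand, clipped = FALSE,
                 box_start = as.integer(box_start),
                 box_end = as.integer(box_end), bit_score = 50, frame = 0L)
}

test_that("the naive caller recovers a fully contained planted ORF exactly", {
  fx <- small_fixture()
  hmm <- small_hmm()
  asm <- fx$genome$assembly
  hits <- scan_genome(hmm, asm, 20)
  regions <- extract_region(hits, asm)
  man <- fx$genome$manifest
  got <- 0L
  for (i in seq_len(nrow(regions))) {
    model <- call_gene_naive(regions[i, ], asm)
    truth <- man[man$chromosome == regions$contig_id[[i]] &
                   man$start < model$end & man$end > model$start, ]
    if (nrow(truth) == 1L) {
      got <- got + 1L
      expect_equal(model$strand, truth$strand)
      expect_equal(model$end, truth$end)     # 3' stop is exact
      # 5' may extend past the true ATG only through an upstream in-frame ATG
      expect_lte(model$start, truth$start)
      expect_equal((truth$start - model$start) %% 3L, 0)
      expect_equal(model$partial, FALSE)
      # the called protein ends with the true protein's C-terminus
      true_prot <- man$protein[man$gene_id == truth$gene_id]
    }
  }
  expect_equal(got, nrow(man))
})

test_that("a hit near the region edge without a stop yields a partial model", {
  withr::with_seed(40, {
    # ORF runs off the 3' end: ATG + 70 non-stop codons, no terminator
    body <- paste(rep("GCT", 70), collapse = "")
    contig <- seq_tbl("c", paste0(strrep("T", 9), "TAAATG", body))
  })
  reg <- region_for(contig, box_start = 12L, box_end = nchar(contig$seq))
  model <- call_gene_naive(reg, contig)
  expect_equal(nrow(model), 1L)
  expect_true(model$partial)
})

test_that("stops flanking the hit within the minimum ORF give no model", {
  # hit frame interrupted by stops on both sides within 60 codons
  contig <- seq_tbl("c", paste0("TAA", paste(rep("GCT", 20), collapse = ""),
                                "ATG", paste(rep("GCA", 10), collapse = ""),
                                "TGA", strrep("A", 60)))
  reg <- region_for(contig, box_start = 66L, box_end = 96L)
  expect_message(model <- call_gene_naive(reg, contig), "below minimum")
  expect_equal(nrow(model), 0L)
})

test_that("an upstream stop with no start codon yields no model", {
  contig <- seq_tbl("c", paste0("TAA", paste(rep("GCT", 80), collapse = ""),
                                "TGA"))
  reg <- region_for(contig, box_start = 33L, box_end = 63L)
  expect_message(model <- call_gene_naive(reg, contig), "no start codon")
  expect_equal(nrow(model), 0L)
})

test_that("merging keeps CDS-track models and drops redundant genome models", {
  mk <- function(contig, s, e, strand, src) {
    gene_model_row(contig, s, e, strand,
                   tibble::tibble(start = s, end = e), "MKR", src, FALSE)
  }
  a <- mk("c1", 100L, 400L, "+", "cds_track")
  b <- mk("c1", 100L, 400L, "+", "genome_track")     # identical -> dropped
  m1 <- merge_gene_sets(a, b)
  expect_equal(nrow(m1), 1L)
  expect_equal(m1$source, "cds_track")

  d <- mk("c1", 1000L, 1300L, "+", "genome_track")   # disjoint -> kept
  m2 <- merge_gene_sets(a, d)
  expect_equal(nrow(m2), 2L)
  expect_equal(m2$gene_id, c("gene_0001", "gene_0002"))

  # 60% reciprocal overlap at the default 0.5 threshold -> merged away
  e1 <- mk("c1", 0L, 100L, "+", "cds_track")
  e2 <- mk("c1", 40L, 140L, "+", "genome_track")
  expect_equal(pmin(60 / 100, 60 / 100), 0.6)
  m3 <- merge_gene_sets(e1, e2)
  expect_equal(nrow(m3), 1L)

  # same interval on the other strand is a different gene
  f <- mk("c1", 100L, 400L, "-", "genome_track")
  expect_equal(nrow(merge_gene_sets(a, f)), 2L)
})

test_that("merging is idempotent and bounded by the input sizes", {
  fx <- small_fixture()
  hmm <- small_hmm()
  asm <- fx$genome$assembly
  hits <- scan_genome(hmm, asm, 20)
  regions <- extract_region(hits, asm)
  genome_track <- dplyr::bind_rows(lapply(seq_len(nrow(regions)), function(i) {
    call_gene_naive(regions[i, ], asm)
  }))
  ann <- fx$genome$annotation
  fam_ann <- ann[grepl("^focal", ann$gene_id), ]
  cds_track <- dplyr::bind_rows(lapply(seq_len(nrow(fam_ann)), function(i) {
    p <- fam_ann[i, ]
    gene_model_row(p$chromosome, p$start, p$end, p$strand,
                   tibble::tibble(start = p$start, end = p$end),
                   "M", "cds_track", FALSE)
  }))
  merged <- merge_gene_sets(cds_track, genome_track)
  expect_lte(nrow(merged), nrow(cds_track) + nrow(genome_track))
  again <- merge_gene_sets(merged, genome_track)
  expect_equal(nrow(again), nrow(merged))
  expect_equal(again$start, merged$start)
})

test_that("an external predictor's GFF3 is lifted to genomic coordinates", {
  fx <- small_fixture()
  hmm <- small_hmm()
  asm <- fx$genome$assembly
  hits <- scan_genome(hmm, asm, 20)
  regions <- extract_region(hits[1, ], asm)
  # mock predictor: echoes a fixed single-CDS gene covering the real ORF
  model0 <- call_gene_naive(regions[1, ], asm)
  local_start <- model0$start - regions$start[[1]]
  local_end <- model0$end - regions$start[[1]]
  gff <- c("##gff-version 3",
           paste("region", "mock", "gene", local_start + 1, local_end, ".",
                 model0$strand, ".", "ID=g1", sep = "\t"),
           paste("region", "mock", "CDS", local_start + 1, local_end, ".",
                 model0$strand, "0", "ID=c1;Parent=g1", sep = "\t"))
  gff_path <- tempfile(fileext = ".gff3")
  writeLines(gff, gff_path)
  tmpl <- paste("cp", gff_path, "{output}")
  got <- run_external_predictor(regions[1, ], asm, tmpl, hmm)
  expect_equal(nrow(got), 1L)
  expect_equal(got$start, model0$start)
  expect_equal(got$end, model0$end)
  expect_equal(got$source, "external")
  expect_gte(got$confirmation_score, 20)

  # failing predictor: warning, empty result
  expect_warning(bad <- run_external_predictor(regions[1, ], asm, "false",
                                               hmm),
                 "failed")
  expect_equal(nrow(bad), 0L)

  # predictor emitting a domain-free gene: dropped by the confirmation score
  dgff <- c("##gff-version 3",
            paste("region", "mock", "CDS", 1, 90, ".", "+", "0",
                  "ID=c2;Parent=g2", sep = "\t"))
  dpath <- tempfile(fileext = ".gff3")
  writeLines(dgff, dpath)
  got2 <- run_external_predictor(regions[1, ], asm,
                                 paste("cp", dpath, "{output}"), hmm)
  expect_equal(nrow(got2), 0L)
})

test_that("gene models round-trip through GFF3", {
  m <- gene_model_row("c1", 100L, 400L, "-",
                      tibble::tibble(start = 100L, end = 400L),
                      "MKR", "cds_track", FALSE, 33.3, "gene_0001")
  path <- tempfile(fileext = ".gff3")
  write_gene_models_gff3(m, path)
  back <- read_gff3(path)
  expect_equal(back$type, c("gene", "mRNA", "CDS"))
  expect_equal(back$start, rep(100L, 3))   # 1-based closed -> 0-based back
  expect_equal(back$end, rep(400L, 3))
  pos <- read_gene_positions(path)
  expect_equal(pos$gene_id, "gene_0001")
})
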