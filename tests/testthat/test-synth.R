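test_that("seed alignments are reproducible and divergence-controlled", {
  a <- sample_seed_alignment(seed = 5)
  b <- sample_seed_alignment(seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$seq, sample_seed_alignment(seed = 6)$seq))

  flat <- sample_seed_alignment(divergence = 0, n_insert_columns = 0,
                                seed = 5)
  expect_equal(length(unique(flat$seq)), 1L)
  expect_error(sample_seed_alignment(length = 0), "out of range")
  expect_error(sample_seed_alignment(n_rows = 1), "two seed rows")
})

test_that("profile size tracks the requested seed-domain length", {
  for (sd in 1:4) {
    aln <- sample_seed_alignment(length = 57, divergence = 0.2, seed = sd)
    hmm <- build_profile(aln)
    expect_gte(hmm$K, 55L)
    expect_lte(hmm$K, 59L)
  }
})

test_that("zero-mutation families are identical within a lineage", {
  fam <- simulate_family("MKRGAWQDLLKKAYELSVLCDAEVALIIFS",
                         genes_per_species = list(s1 = c(Malpha = 3L)),
                         mutation_rate = 0, seed = 3)
  expect_equal(nrow(fam$genes), 3L)
  expect_equal(length(unique(fam$genes$domain)), 1L)
  expect_equal(sort(fam$tree$tip.label), sort(fam$genes$gene_id))
  # the genealogy is the recorded parent forest
  expect_equal(sum(is.na(fam$genes$parent)), 1L)
  expect_equal(nrow(fam$events), 2L)
})

test_that("per-group gene counts are honored exactly", {
  fam <- simulate_family("MKRGAWQDLLKKAYELSVLCDAEVALIIFS",
                         genes_per_species = list(
                           s1 = c(Malpha = 4L, MIKCc = 2L),
                           s2 = c(Malpha = 1L)),
                         seed = 9)
  counts <- table(fam$genes$species, fam$genes$group)
  expect_equal(unname(counts["s1", "Malpha"]), 4L)
  expect_equal(unname(counts["s1", "MIKCc"]), 2L)
  expect_equal(unname(counts["s2", "Malpha"]), 1L)
  expect_equal(unique(fam$genes$type[fam$genes$group == "MIKCc"]), "TypeII")
})

test_that("tandem-only duplication makes every cherry rank-adjacent", {
  fam <- simulate_family("MKRGAWQDLLKKAYELSVLCDAEVALIIFS",
                         genes_per_species = list(s1 = c(Malpha = 6L)),
                         duplication_model = c(tandem = 1, proximal = 0,
                                               distal = 0),
                         seed = 12)
  gen <- plant_genome(fam, n_contigs = 2L, contig_length = 60000L,
                      decoy_gene_count = 10L, seed = 13)
  ch <- gen$cherries
  rnk <- setNames(gen$truth_positions$rank, gen$truth_positions$gene_id)
  chrom <- setNames(gen$truth_positions$chromosome,
                    gen$truth_positions$gene_id)
  for (i in seq_len(nrow(ch))) {
    expect_equal(chrom[[ch$gene1[[i]]]], chrom[[ch$gene2[[i]]]])
    expect_equal(abs(rnk[[ch$gene1[[i]]]] - rnk[[ch$gene2[[i]]]]), 1L)
  }
})

test_that("planted genomes are byte-reproducible under a fixed seed", {
  fam <- simulate_family("MKRGAWQDLLKKAYELSVLCDAEVALIIFS",
                         genes_per_species = list(s1 = c(Malpha = 3L)),
                         seed = 3)
  g1 <- plant_genome(fam, n_contigs = 1L, contig_length = 40000L,
                     decoy_gene_count = 5L, seed = 8)
  g2 <- plant_genome(fam, n_contigs = 1L, contig_length = 40000L,
                     decoy_gene_count = 5L, seed = 8)
  expect_identical(g1$assembly, g2$assembly)
  expect_identical(g1$manifest, g2$manifest)
})

test_that("manifest coordinates are consistent with the emitted assembly", {
  fx <- small_fixture()
  asm <- fx$genome$assembly
  man <- fx$genome$manifest
  for (i in seq_len(nrow(man))) {
    m <- man[i, ]
    cds <- substr(asm$seq[asm$id == m$chromosome], m$start + 1L, m$end)
    if (m$strand == "-") cds <- reverse_complement(cds)
    expect_equal(sub("\\*$", "", translate_cds(cds)), m$protein)
  }
})

test_that("infeasible packing is reported with the required length", {
  fam <- simulate_family("MKRGAWQDLLKKAYELSVLCDAEVALIIFS",
                         genes_per_species = list(s1 = c(Malpha = 8L)),
                         seed = 3)
  expect_error(plant_genome(fam, n_contigs = 1L, contig_length = 2000L,
                            decoy_gene_count = 5L, seed = 8),
               "infeasible packing")
})

test_that("the dupstats closed loop reproduces the manifest classes", {
  fx <- study_fixture()
  genes <- fx$family$genes
  focal_ids <- genes$gene_id[genes$species == "focal"]
  tree <- ape::multi2di(ape::keep.tip(fx$family$tree, focal_ids),
                        random = FALSE)
  sm <- tibble::tibble(gene_id = genes$gene_id, species = genes$species)
  rep <- duplication_report(tree, sm[sm$species == "focal", ],
                            fx$genome$truth_positions)
  truth <- fx$genome$cherries
  truth <- truth[!is.na(truth$class), ]
  got <- dplyr::inner_join(rep$pairs, truth, by = c("gene1", "gene2"),
                           suffix = c("_got", "_true"))
  expect_equal(nrow(got), nrow(truth))
  expect_equal(got$class_got, got$class_true)
})
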