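sp_map <- function(ids, species) tibble::tibble(gene_id = ids,
                                                species = species)

test_that("maximal monospecific clades match hand-built examples", {
  tree <- ape::read.tree(text = "((a1:1,a2:1):1,b1:1);")
  cl <- species_specific_clades(tree, sp_map(c("a1", "a2", "b1"),
                                             c("A", "A", "B")))
  expect_equal(cl$species, c("A", "B"))
  expect_equal(cl$size, c(2L, 1L))
  expect_equal(cl$genes[[1]], c("a1", "a2"))

  cat5 <- ape::read.tree(text = "((((a1:1,a2:1):1,a3:1):1,a4:1):1,a5:1);")
  cl5 <- species_specific_clades(cat5, sp_map(paste0("a", 1:5), rep("A", 5)))
  expect_equal(cl5$size, 5L)

  alt <- species_specific_clades(cat5, sp_map(paste0("a", 1:5),
                                              c("A", "B", "A", "B", "A")))
  expect_equal(alt$size, rep(1L, 5))
  expect_error(species_specific_clades(cat5, sp_map(paste0("a", 1:4),
                                                    rep("A", 4))),
               "leaf without species")
})

test_that("clades of one species partition that species' leaves", {
  withr::with_seed(23, {
    for (r in 1:20) {
      n <- sample(5:40, 1)
      tr <- ape::rtree(n)
      sm <- sp_map(tr$tip.label, sample(c("A", "B", "C"), n, TRUE))
      cl <- species_specific_clades(tr, sm)
      for (s in unique(sm$species)) {
        got <- sort(unlist(cl$genes[cl$species == s]))
        expect_equal(got, sort(sm$gene_id[sm$species == s]))
      }
      expect_equal(anyDuplicated(unlist(cl$genes)), 0L)
    }
  })
})

test_that("the size histogram bins, conserves and reports the full table", {
  clades <- tibble::tibble(species = "A", size = c(12L, 5L, 5L, 2L),
                           genes = list("x"), clade_id = "c")
  h <- clade_size_histogram(clades)
  expect_equal(h$count[h$bin == ">=10"], 1L)
  expect_equal(h$count[h$bin == "5"], 2L)
  expect_equal(h$count[h$bin == "other"], 1L)
  expect_equal(sum(h$count), nrow(clades))
  full <- attr(h, "full")
  expect_equal(full$count[full$size == 5], 2L)

  empty <- clade_size_histogram(clades[0, ])
  expect_true(all(empty$count == 0L))
})

test_that("duplication counts match the clade-size identity and the oracle", {
  tree <- ape::read.tree(text = "(((a1:1,a2:1):1,a3:1):1,b1:1);")
  sm <- sp_map(c("a1", "a2", "a3", "b1"), c("A", "A", "A", "B"))
  expect_equal(lineage_specific_duplications(tree, sm, "A"), 2L)
  expect_equal(lineage_specific_duplications(tree, sm, "B"), 0L)
  expect_error(lineage_specific_duplications(tree, sm, "Z"),
               "unknown species")

  withr::with_seed(24, {
    for (r in 1:40) {
      n <- sample(4:50, 1)
      tr <- ape::rtree(n)
      sm <- sp_map(tr$tip.label, sample(c("A", "B"), n, TRUE))
      sp <- setNames(sm$species, sm$gene_id)
      cl <- species_specific_clades(tr, sm)
      for (s in c("A", "B")) {
        if (!s %in% sm$species) next
        mine <- lineage_specific_duplications(tr, sm, s)
        # independent oracle: brute-force scan over every internal node
        oracle <- sum(vapply((n + 1):(n + tr$Nnode), function(v) {
          leaves <- ape::extract.clade(tr, v)$tip.label
          all(sp[leaves] == s)
        }, logical(1)))
        expect_equal(mine, oracle)
        expect_equal(mine, sum(cl$size[cl$species == s] - 1L))
      }
    }
  })
})

test_that("duplicate pairs classify by chromosome and rank gap", {
  tree <- ape::read.tree(
    text = "(((g1:1,g2:1):1,(g3:1,g4:1):1):1,(g5:1,g6:1):1);")
  sm <- sp_map(paste0("g", 1:6), rep("A", 6))
  clades <- species_specific_clades(tree, sm)
  pos <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    chromosome = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    rank = c(7L, 8L, 2L, 12L, 20L, 1L),
    start = c(700L, 800L, 200L, 1200L, 2000L, 100L),
    end = c(750L, 850L, 250L, 1250L, 2050L, 150L)
  )
  got <- classify_duplicate_pairs(tree, clades, pos)
  cls <- setNames(got$class, paste(got$gene1, got$gene2))
  expect_equal(cls[["g1 g2"]], "tandem")       # ranks 7,8
  expect_equal(cls[["g3 g4"]], "proximal")     # ranks 2,12 with gap 10
  expect_equal(cls[["g5 g6"]], "distal")       # different chromosomes
  tighter <- classify_duplicate_pairs(tree, clades, pos,
                                      proximal_max_gap = 5L)
  expect_equal(setNames(tighter$class, paste(tighter$gene1, tighter$gene2))[["g3 g4"]],
               "distal")
  expect_error(classify_duplicate_pairs(tree, clades, pos[-1, ]),
               "missing from positions")
})

test_that("ranks derive from start order within each chromosome", {
  pos <- tibble::tibble(gene_id = c("x", "y", "z"),
                        chromosome = c("c1", "c1", "c2"),
                        start = c(500L, 100L, 50L),
                        end = c(600L, 200L, 90L))
  got <- add_gene_ranks(pos)
  expect_equal(got$rank[got$gene_id == "y"], 1L)
  expect_equal(got$rank[got$gene_id == "x"], 2L)
  expect_equal(got$rank[got$gene_id == "z"], 1L)
})

test_that("the full report mirrors its parts and prints", {
  fx <- small_fixture()
  genes <- fx$family$genes
  focal_ids <- genes$gene_id[genes$species == "focal"]
  tree <- ape::multi2di(ape::keep.tip(fx$family$tree, focal_ids),
                        random = FALSE)
  sm <- sp_map(genes$gene_id, genes$species)
  rep <- duplication_report(tree, sm[sm$species == "focal", ],
                            fx$genome$truth_positions)
  expect_equal(sum(rep$histogram$count), nrow(rep$clades))
  expect_equal(rep$duplications$duplications,
               sum(rep$clades$size - 1L))
  out <- capture.output(print(rep))
  expect_true(any(grepl("histogram", out)))
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
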