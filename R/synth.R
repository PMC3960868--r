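# Seeded synthetic-data generator: seed alignments, simulated gene families
# with recorded duplication histories, and planted genome assemblies with
# truth manifests. The generator exercises pipeline mechanics (detection,
# coordinate math, merging, classification, duplication statistics); it uses
# a uniform amino-acid replacement model and single-exon genes, so it does
# not emulate intron structure, codon usage or realistic substitution
# processes.

# amino-acid background used for random proteins (approximate database
# frequencies; exact values are not critical for pipeline mechanics)
BG_FREQ <- c(
  A = 0.078, C = 0.019, D = 0.053, E = 0.063, F = 0.039, G = 0.072,
  H = 0.023, I = 0.053, K = 0.059, L = 0.091, M = 0.022, N = 0.043,
  P = 0.052, Q = 0.042, R = 0.051, S = 0.068, T = 0.059, V = 0.066,
  W = 0.014, Y = 0.032
)

GROUP_TYPES <- c(Malpha = "TypeI", Mbeta = "TypeI", Mgamma = "TypeI",
                 MIKCc = "TypeII", MIKCstar = "TypeII")

random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE, prob = BG_FREQ), collapse = "")
}

# uniform replacement model: each position mutates with probability `rate`
# to one of the 19 other residues
mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[[i]] <- sample(setdiff(AA20, chars[[i]]), 1)
  }
  paste(chars, collapse = "")
}

#' Sample a synthetic seed alignment of domain exemplars
#'
#' A random ancestral domain is mutated independently per row; a few
#' low-occupancy columns (below the 0.5 match threshold) are inserted so
#' profile construction exercises the insert-column rule. The ancestral
#' domain is attached as attribute `"ancestral"`.
#'
#' @param n_rows Number of exemplar rows (>= 2).
#' @param length Domain length in residues (56–60 for a MADS domain).
#' @param divergence Per-residue substitution probability per row.
#' @param n_insert_columns Number of low-occupancy (insert) columns added.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return Aligned sequence tibble.
#' @export
sample_seed_alignment <- function(n_rows = 12L, length = 57L,
                                  divergence = 0.15, n_insert_columns = 2L,
                                  seed = 1L) {
  if (n_rows < 2L) stop("need at least two seed rows")
  if (length < 1L || length > 1000L) stop("length out of range [1, 1000]")
  withr::with_seed(seed, {
    anc <- random_protein(length)
    rows <- vapply(seq_len(n_rows), function(i) mutate_protein(anc, divergence),
                   character(1))
    mat <- do.call(rbind, strsplit(rows, ""))
    if (n_insert_columns > 0L) {
      at <- sort(sample(length + 1L, n_insert_columns, replace = TRUE))
      occupied <- max(1L, floor(0.3 * n_rows))   # < 50% => insert column
      for (col_pos in rev(at)) {
        col <- rep("-", n_rows)
        who <- sample(n_rows, occupied)
        col[who] <- sample(AA20, occupied, replace = TRUE, prob = BG_FREQ)
        left <- seq_len(col_pos - 1L)
        mat <- cbind(mat[, left, drop = FALSE], col,
                     mat[, setdiff(seq_len(ncol(mat)), left), drop = FALSE])
      }
    }
    out <- seq_tbl(sprintf("seed%02d", seq_len(n_rows)),
                   apply(mat, 1, paste, collapse = ""), alphabet = "protein")
    attr(out, "ancestral") <- anc
    out
  })
}

#' Simulate a gene family with a recorded duplication history
#'
#' Group ancestors diverge from type ancestors, which diverge from the root
#' domain. Within each species and group, genes arise by successive
#' duplication of a random existing gene (a birth process); every
#' duplication event is recorded with a positional class drawn from
#' `duplication_model`, which later drives the planted gene ranks. Each
#' gene's domain is an independent draw at `mutation_rate` around its
#' lineage founder's domain — emulating purifying selection on a highly
#' conserved domain, whose divergence stays bounded rather than
#' accumulating along the genealogy; flanks are free random sequence.
#'
#' @param seed_domain Root domain protein string (e.g. the `"ancestral"`
#'   attribute of [sample_seed_alignment()]).
#' @param genes_per_species Named list: species id -> named integer vector
#'   of gene counts per group.
#' @param duplication_model Named probabilities for `tandem`, `proximal`,
#'   `distal`; must sum to 1.
#' @param mutation_rate Per-residue substitution probability per
#'   duplication/speciation event.
#' @param type_divergence,group_divergence Divergence of type/group
#'   ancestors from their parent sequence.
#' @param group_types Named map group -> type label; defaults to the
#'   MADS-box vocabulary (M-alpha/beta/gamma = Type I, MIKC^C/MIKC* =
#'   Type II).
#' @param seed Integer seed.
#' @return A list: `genes` (manifest tibble with `gene_id`, `species`,
#'   `type`, `group`, `parent`, `dup_class`, `domain`, `protein`), `tree`
#'   (the true genealogy as a `phylo`), `events` (duplication events).
#' @export
simulate_family <- function(seed_domain,
                            genes_per_species = list(
                              focal = c(Malpha = 8L, Mbeta = 5L, Mgamma = 7L,
                                        MIKCc = 7L, MIKCstar = 3L)
                            ),
                            duplication_model = c(tandem = 0.2,
                                                  proximal = 0.2,
                                                  distal = 0.6),
                            mutation_rate = 0.05,
                            type_divergence = 0.2,
                            group_divergence = 0.1,
                            group_types = GROUP_TYPES,
                            seed = 1L) {
  stopifnot(abs(sum(duplication_model) - 1) < 1e-9)
  groups <- unique(unlist(lapply(genes_per_species, names)))
  if (!all(groups %in% names(group_types))) {
    stop("unknown group in genes_per_species")
  }
  if (sum(unlist(genes_per_species)) == 0L) {
    return(list(genes = tibble(), tree = NULL, events = tibble()))
  }
  withr::with_seed(seed, {
    types <- unique(unname(group_types[groups]))
    type_anc <- setNames(
      lapply(types, function(t) mutate_protein(seed_domain, type_divergence)),
      types)
    group_anc <- setNames(
      lapply(groups, function(g) {
        mutate_protein(type_anc[[group_types[[g]]]], group_divergence)
      }), groups)

    genes <- list(); events <- list()
    subtree <- list()   # newick fragment per (group, species)
    for (g in groups) {
      for (sp in names(genes_per_species)) {
        target <- genes_per_species[[sp]][g]
        if (is.na(target) || target == 0L) next
        make_id <- function(i) sprintf("%s_%s_g%03d", sp, g, i)
        founder <- make_id(1L)
        founder_domain <- mutate_protein(group_anc[[g]], mutation_rate)
        domains <- setNames(list(founder_domain), founder)
        nwk <- founder
        ids <- founder
        parents <- setNames(NA_character_, founder)
        classes <- setNames(NA_character_, founder)
        i <- 1L
        while (length(ids) < target) {
          parent <- sample(ids, 1L)
          i <- i + 1L
          child <- make_id(i)
          cls <- sample(names(duplication_model), 1L,
                        prob = duplication_model)
          # purifying selection: the domain stays near the lineage founder's
          # sequence instead of accumulating substitutions without bound
          domains[[child]] <- mutate_protein(founder_domain, mutation_rate)
          nwk <- sub(paste0("(?<![A-Za-z0-9_])", parent, "(?![A-Za-z0-9_])"),
                     paste0("(", parent, ",", child, ")"), nwk, perl = TRUE)
          ids <- c(ids, child)
          parents[[child]] <- parent
          classes[[child]] <- cls
          events[[length(events) + 1L]] <- tibble(
            parent = parent, child = child, class = cls,
            species = sp, group = g)
        }
        subtree[[paste(g, sp, sep = ".")]] <- nwk
        genes[[paste(g, sp, sep = ".")]] <- tibble(
          gene_id = ids, species = sp, type = unname(group_types[[g]]),
          group = g, parent = unname(parents[ids]),
          dup_class = unname(classes[ids]),
          domain = unname(unlist(domains[ids]))
        )
      }
    }
    genes <- dplyr::bind_rows(genes)
    # random flanks: proteins start with M, total length >= 60 residues
    genes$protein <- vapply(genes$domain, function(d) {
      paste0("M", random_protein(sample(5:15, 1L)), d,
             random_protein(sample(30:80, 1L)))
    }, character(1), USE.NAMES = FALSE)

    # assemble the true genealogy: genes within (group, species) are the
    # recorded birth trees; species subtrees join under their group, groups
    # under their type, types at the root
    join <- function(parts) {
      if (length(parts) == 1L) parts[[1]]
      else paste0("(", paste(parts, collapse = ","), ")")
    }
    type_parts <- vapply(types, function(t) {
      gparts <- vapply(groups[group_types[groups] == t], function(g) {
        keys <- grep(paste0("^", g, "\\."), names(subtree), value = TRUE)
        join(unlist(subtree[keys]))
      }, character(1))
      join(gparts[nzchar(gparts)])
    }, character(1))
    tree <- ape::read.tree(text = paste0(join(type_parts), ";"))
    tree$edge.length <- rep(1, nrow(tree$edge))

    list(genes = genes, tree = tree,
         events = dplyr::bind_rows(events))
  })
}

# cherry pairs of the family tree restricted to one species, with the
# positional class of the duplication event that formed each cherry
family_cherries <- function(family, species) {
  tree <- family$tree
  genes <- family$genes
  keep <- genes$gene_id[genes$species == species]
  if (is.null(tree) || length(keep) < 2L) return(NULL)
  ch <- cherries_in(tree, keep)
  if (is.null(ch)) return(NULL)
  parent_of <- setNames(genes$parent, genes$gene_id)
  class_of <- setNames(genes$dup_class, genes$gene_id)
  cls <- vapply(seq_len(nrow(ch)), function(i) {
    a <- ch[i, 1]; b <- ch[i, 2]
    if (!is.na(parent_of[[b]]) && parent_of[[b]] == a) class_of[[b]]
    else if (!is.na(parent_of[[a]]) && parent_of[[a]] == b) class_of[[a]]
    else NA_character_
  }, character(1))
  tibble(gene1 = ch[, 1], gene2 = ch[, 2], class = cls)
}

#' Plant a simulated family into a synthetic genome assembly
#'
#' Generates random background contigs at the requested GC content, lays
#' the focal species' genes out so that each duplicate cherry realises its
#' recorded positional class (tandem pairs adjacent in gene rank, proximal
#' pairs at rank gap 3 with decoy genes between, distal pairs on different
#' contigs), adds length-matched decoy ORFs, and emits the assembly, the
#' CDS track, gene positions and a truth manifest. A configurable fraction
#' of planted family genes is withheld from the CDS track and annotation to
#' exercise the genome-track rescue path.
#'
#' @param family Output of [simulate_family()].
#' @param species Which species of the family to plant (default: first).
#' @param n_contigs,contig_length Assembly shape (bp per contig).
#' @param gc_content Background GC fraction.
#' @param decoy_gene_count Number of non-family decoy genes (must cover the
#'   proximal-gap spacers).
#' @param withhold_frac Fraction of family genes withheld from the CDS
#'   track/annotation.
#' @param intergenic Min/max background bp between consecutive genes.
#' @param seed Integer seed.
#' @return A list: `assembly`, `cds` (CDS-track DNA), `cds_proteins`,
#'   `annotation` (positions of annotated genes), `truth_positions` (all
#'   genes), `manifest` (family genes with coordinates, ranks, labels,
#'   `withheld` flag), `cherries` (realised pair classes).
#' @export
plant_genome <- function(family, species = NULL, n_contigs = 5L,
                         contig_length = 400000L, gc_content = 0.36,
                         decoy_gene_count = 60L, withhold_frac = 0,
                         intergenic = c(500L, 3000L), seed = 1L) {
  genes <- family$genes
  if (is.null(species)) species <- genes$species[[1]]
  fam <- genes[genes$species == species, , drop = FALSE]
  if (nrow(fam) == 0L) stop("no genes for species ", species)
  withr::with_seed(seed, {
    # reverse-translate proteins into CDS (random synonymous codons + stop)
    codon_table <- split(names(Biostrings::GENETIC_CODE),
                         unname(Biostrings::GENETIC_CODE))
    rev_translate <- function(protein) {
      aa <- strsplit(protein, "")[[1]]
      codons <- vapply(aa, function(a) {
        opts <- codon_table[[a]]
        if (a == "M") "ATG" else opts[sample.int(length(opts), 1L)]
      }, character(1), USE.NAMES = FALSE)
      paste0(paste(codons, collapse = ""),
             sample(c("TAA", "TAG", "TGA"), 1L))
    }
    fam_cds <- setNames(vapply(fam$protein, rev_translate, character(1),
                               USE.NAMES = FALSE), fam$gene_id)

    decoy_ids <- sprintf("decoy_%03d", seq_len(decoy_gene_count))
    decoy_prot <- setNames(vapply(decoy_ids, function(i) {
      n <- nchar(sample(fam$protein, 1L))   # length-matched to the family
      paste0("M", random_protein(n - 1L))
    }, character(1), USE.NAMES = FALSE), decoy_ids)
    decoy_cds <- setNames(vapply(decoy_prot, rev_translate, character(1),
                                 USE.NAMES = FALSE), decoy_ids)

    # layout units: tandem cherry -> [a, b]; proximal -> [a, d, d, b];
    # distal -> members forced onto different contigs
    cherries <- family_cherries(family, species)
    unit_of <- list(); in_unit <- character(0)
    distal_pairs <- list()
    decoy_pool <- decoy_ids
    if (!is.null(cherries)) {
      for (r in seq_len(nrow(cherries))) {
        a <- cherries$gene1[[r]]; b <- cherries$gene2[[r]]
        cls <- cherries$class[[r]]
        if (is.na(cls) || a %in% in_unit || b %in% in_unit) next
        if (cls == "tandem") {
          unit_of[[length(unit_of) + 1L]] <- c(a, b)
          in_unit <- c(in_unit, a, b)
        } else if (cls == "proximal") {
          if (length(decoy_pool) < 2L) {
            stop("decoy_gene_count too small for proximal spacers")
          }
          spacer <- decoy_pool[1:2]; decoy_pool <- decoy_pool[-(1:2)]
          unit_of[[length(unit_of) + 1L]] <- c(a, spacer, b)
          in_unit <- c(in_unit, a, b)
        } else {
          distal_pairs[[length(distal_pairs) + 1L]] <- c(a, b)
          in_unit <- c(in_unit, a, b)
        }
      }
    }
    singles <- setdiff(fam$gene_id, in_unit)
    for (s in singles) unit_of[[length(unit_of) + 1L]] <- s

    # distribute units over contigs; distal pair members must differ
    contigs <- paste0("contig", seq_len(n_contigs))
    layout <- setNames(vector("list", n_contigs), contigs)
    for (u in unit_of) {
      ci <- sample.int(n_contigs, 1L)
      layout[[ci]] <- append(layout[[ci]], list(u),
                             after = sample(0:length(layout[[ci]]), 1L))
    }
    for (p in distal_pairs) {
      # distal pairs land on different contigs when the assembly has more
      # than one; on a single contig the members are placed independently
      cs <- if (n_contigs >= 2L) sample.int(n_contigs, 2L) else c(1L, 1L)
      for (k in 1:2) {
        layout[[cs[[k]]]] <- append(layout[[cs[[k]]]], list(p[[k]]),
                                    after = sample(0:length(layout[[cs[[k]]]]),
                                                   1L))
      }
    }
    # remaining decoys go between units, never inside one
    for (d in decoy_pool) {
      ci <- sample.int(n_contigs, 1L)
      layout[[ci]] <- append(layout[[ci]], list(d),
                             after = sample(0:length(layout[[ci]]), 1L))
    }

    all_cds <- c(fam_cds, decoy_cds)
    bg <- function(n) {
      paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                   prob = c(gc_content / 2, gc_content / 2,
                            (1 - gc_content) / 2, (1 - gc_content) / 2)),
            collapse = "")
    }
    rows <- list(); contig_seq <- character(n_contigs)
    for (ci in seq_len(n_contigs)) {
      order_ids <- unlist(layout[[ci]])
      lens <- nchar(all_cds[order_ids])
      min_needed <- sum(lens) + (length(order_ids) + 1L) * intergenic[[1]]
      if (min_needed > contig_length) {
        stop("infeasible packing: contig needs at least ", min_needed, " bp")
      }
      gaps <- if (length(order_ids)) {
        sample(seq(intergenic[[1]], intergenic[[2]]), length(order_ids),
               replace = TRUE)
      } else integer(0)
      # trim gaps if they would overflow, keeping the minimum spacing
      while (sum(lens) + sum(gaps) > contig_length - intergenic[[1]]) {
        gaps <- pmax(intergenic[[1]], gaps - intergenic[[1]])
      }
      pieces <- character(0); pos <- 0L; rank <- 0L
      for (gi in seq_along(order_ids)) {
        gid <- order_ids[[gi]]
        pieces <- c(pieces, bg(gaps[[gi]]))
        pos <- pos + gaps[[gi]]
        strand <- sample(c("+", "-"), 1L)
        cds <- all_cds[[gid]]
        insert <- if (strand == "-") reverse_complement(cds) else cds
        pieces <- c(pieces, insert)
        rank <- rank + 1L
        rows[[length(rows) + 1L]] <- tibble(
          gene_id = gid, chromosome = contigs[[ci]],
          start = pos, end = pos + nchar(cds), strand = strand,
          rank = rank, is_family = gid %in% fam$gene_id)
        pos <- pos + nchar(cds)
      }
      tail_len <- contig_length - pos
      contig_seq[[ci]] <- paste0(paste(pieces, collapse = ""), bg(tail_len))
    }
    positions <- dplyr::bind_rows(rows)

    n_withheld <- floor(withhold_frac * nrow(fam))
    withheld <- sort(sample(fam$gene_id, n_withheld), method = "radix")

    manifest <- dplyr::left_join(fam, positions, by = "gene_id")
    manifest$withheld <- manifest$gene_id %in% withheld

    annotated <- positions[!positions$gene_id %in% withheld, , drop = FALSE]
    cds_ids <- annotated$gene_id
    list(
      assembly = seq_tbl(contigs, contig_seq, alphabet = "dna"),
      cds = seq_tbl(cds_ids, unname(all_cds[cds_ids]), alphabet = "dna"),
      cds_proteins = seq_tbl(
        cds_ids,
        sub("\\*$", "", translate_cds(unname(all_cds[cds_ids]))),
        alphabet = "protein"),
      annotation = dplyr::select(annotated, -"is_family"),
      truth_positions = dplyr::select(positions, -"is_family"),
      manifest = manifest,
      cherries = cherries
    )
  })
}

#' Generate a complete synthetic study fixture
#'
#' One call produces everything the pipeline consumes: a seed alignment, a
#' two-species simulated family (a focal species whose genome is planted
#' and a reference species providing labeled reference proteins), the
#' planted assembly with truth manifest, and the reference label table.
#'
#' @param seed Integer master seed (all derived seeds are offsets of it).
#' @param genes_per_group Focal-species gene counts per group (default 30
#'   genes: 8/5/7 in M-alpha/M-beta/M-gamma, 7/3 in MIKC^C/MIKC*).
#' @param ref_genes_per_group Reference-species gene counts per group.
#' @param mutation_rate Per-event substitution rate of the family
#'   simulation.
#' @param withhold_frac Fraction of planted genes withheld from the CDS
#'   track.
#' @param n_contigs,contig_length Assembly shape.
#' @param decoy_gene_count Decoy ORFs added to the genome and CDS track.
#' @return A list: `seed_alignment`, `family`, `genome` (see
#'   [plant_genome()]), `refs` (label table), `ref_proteins`.
#' @export
simulate_study <- function(seed = 1L,
                           genes_per_group = c(Malpha = 8L, Mbeta = 5L,
                                               Mgamma = 7L, MIKCc = 7L,
                                               MIKCstar = 3L),
                           ref_genes_per_group = c(Malpha = 3L, Mbeta = 3L,
                                                   Mgamma = 3L, MIKCc = 3L,
                                                   MIKCstar = 3L),
                           mutation_rate = 0.05,
                           withhold_frac = 0.3,
                           n_contigs = 5L, contig_length = 400000L,
                           decoy_gene_count = 60L) {
  seed_alignment <- sample_seed_alignment(seed = seed)
  family <- simulate_family(
    attr(seed_alignment, "ancestral"),
    genes_per_species = list(focal = genes_per_group,
                             refsp = ref_genes_per_group),
    mutation_rate = mutation_rate,
    seed = seed + 1L
  )
  genome <- plant_genome(family, species = "focal", n_contigs = n_contigs,
                         contig_length = contig_length,
                         decoy_gene_count = decoy_gene_count,
                         withhold_frac = withhold_frac, seed = seed + 2L)
  ref_genes <- family$genes[family$genes$species == "refsp", , drop = FALSE]
  list(
    seed_alignment = seed_alignment,
    family = family,
    genome = genome,
    refs = tibble(gene_id = ref_genes$gene_id, species = ref_genes$species,
                  type = ref_genes$type, group = ref_genes$group),
    ref_proteins = seq_tbl(ref_genes$gene_id, ref_genes$protein,
                           alphabet = "protein")
  )
}
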