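# Duplication-pattern statistics on a labeled gene tree plus gene
# coordinates: maximal species-specific clades and their size histogram,
# lineage-specific duplication counts, and tandem/proximal/distal
# classification of duplicate (cherry) pairs.

#' Maximal species-specific clades
#'
#' Enumerates all maximal clades whose leaves belong to a single species
#' (maximal: the parent clade is not monospecific). Singletons are
#' included, so each species' clades partition that species' leaves.
#'
#' @param tree A rooted `phylo`.
#' @param species_map Tibble `gene_id` -> `species`, total over the leaves.
#' @return A tibble ordered by species then smallest leaf label:
#'   `clade_id`, `species`, `size`, `genes` (list-column), `node`.
#' @export
species_specific_clades <- function(tree, species_map) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  sp <- setNames(species_map$species, species_map$gene_id)
  tips <- tree$tip.label
  missing <- setdiff(tips, names(sp))
  if (length(missing)) stop("leaf without species: ", missing[[1]])

  n <- length(tips)
  n_nodes <- n + tree$Nnode
  parent <- rep(NA_integer_, n_nodes)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # per node: the single species of its leaves, or NA when mixed
  node_sp <- c(unname(sp[tips]), rep(NA_character_, tree$Nnode))
  seen <- c(rep(TRUE, n), rep(FALSE, tree$Nnode))
  for (e in rev(seq_len(nrow(tree$edge)))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    if (!seen[a]) { node_sp[a] <- node_sp[b]; seen[a] <- TRUE }
    else if (is.na(node_sp[a]) || is.na(node_sp[b]) ||
             node_sp[a] != node_sp[b]) node_sp[a] <- NA_character_
  }
  leaves_below <- leaves_per_node(tree)
  maximal <- which(!is.na(node_sp) &
                     (is.na(parent) | is.na(node_sp[parent])))
  out <- tibble(
    species = node_sp[maximal],
    node = maximal,
    genes = lapply(maximal, function(v) sort(tips[leaves_below[[v]]],
                                             method = "radix")),
    size = vapply(maximal, function(v) length(leaves_below[[v]]), integer(1))
  )
  first <- vapply(out$genes, `[[`, character(1), 1)
  out <- out[order(out$species, first, method = "radix"), , drop = FALSE]
  out$clade_id <- sprintf("%s_clade_%02d", out$species,
                          as.integer(stats::ave(seq_len(nrow(out)),
                                                out$species,
                                                FUN = seq_along)))
  dplyr::select(out, "clade_id", "species", "size", "genes", "node")
}

# list of descendant leaf indices per node
leaves_per_node <- function(tree) {
  n <- length(tree$tip.label)
  below <- c(as.list(seq_len(n)), vector("list", tree$Nnode))
  tree <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    below[[a]] <- c(below[[a]], below[[b]])
  }
  below
}

#' Histogram of species-specific clade sizes
#'
#' Bins clade sizes the way family-expansion tables are usually presented:
#' a top bin for sizes at or above the largest cut, one bin per listed
#' size, and an `"other"` bucket for everything smaller. The full unbinned
#' histogram is attached as attribute `"full"`.
#'
#' @param clades Clade tibble from [species_specific_clades()].
#' @param bins Decreasing integer sizes; the first is the `>=` cut.
#' @return A tibble `bin`, `count`, with attribute `"full"`.
#' @export
clade_size_histogram <- function(clades, bins = c(10L, 9L, 8L, 7L, 6L, 5L)) {
  bins <- sort(unique(as.integer(bins)), decreasing = TRUE)
  sizes <- clades$size
  counts <- c(
    sum(sizes >= bins[[1]]),
    vapply(bins[-1], function(b) sum(sizes == b), integer(1)),
    sum(sizes < bins[[length(bins)]])
  )
  out <- tibble(
    bin = c(paste0(">=", bins[[1]]), as.character(bins[-1]), "other"),
    count = as.integer(counts)
  )
  full <- if (length(sizes)) {
    tab <- table(sizes)
    tibble(size = as.integer(names(tab)), count = as.integer(tab))
  } else {
    tibble(size = integer(), count = integer())
  }
  attr(out, "full") <- full
  out
}

#' Count lineage-specific duplications
#'
#' The number of internal nodes whose descendant leaves all belong to the
#' focal species — duplications not shared with any other sampled species.
#' For binary trees this equals the sum of (size - 1) over the focal
#' species' maximal monospecific clades. Non-binary nodes are resolved
#' deterministically before counting (in input order, with a message).
#'
#' @param tree A rooted `phylo`.
#' @param species_map Tibble `gene_id` -> `species`.
#' @param focal_species Species whose duplications are counted.
#' @return Integer count.
#' @export
lineage_specific_duplications <- function(tree, species_map, focal_species) {
  if (!focal_species %in% species_map$species) {
    stop("unknown species id: ", focal_species)
  }
  if (!ape::is.binary.phylo(tree)) {
    message("resolving multifurcations deterministically before counting")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  sp <- setNames(species_map$species, species_map$gene_id)
  below <- leaves_per_node(tree)
  n <- length(tree$tip.label)
  internal <- seq(n + 1L, n + tree$Nnode)
  sum(vapply(internal, function(v) {
    all(sp[tree$tip.label[below[[v]]]] == focal_species)
  }, logical(1)))
}

#' Classify duplicate pairs as tandem, proximal or distal
#'
#' Within each maximal monospecific clade, every cherry (a pair of sibling
#' leaves) is taken as one duplication event and classified from the two
#' genes' chromosomal positions: same chromosome and adjacent gene ranks
#' (|rank difference| = 1) is tandem; same chromosome within
#' `proximal_max_gap` ranks is proximal; anything else — including
#' different chromosomes — is distal. With `all_pairs = TRUE` every
#' within-clade leaf pair is classified instead (exploratory mode).
#'
#' @param tree The rooted tree the clades were derived from.
#' @param clades Clade tibble from [species_specific_clades()].
#' @param positions Position tibble with `gene_id`, `chromosome` and
#'   either `rank` or `start` (ranks computed via [add_gene_ranks()]).
#' @param proximal_max_gap Largest rank difference still called proximal.
#' @param all_pairs Classify all within-clade pairs instead of cherries.
#' @return A tibble: `gene1`, `gene2`, `species`, `clade_id`, `class`.
#' @export
classify_duplicate_pairs <- function(tree, clades, positions,
                                     proximal_max_gap = 10L,
                                     all_pairs = FALSE) {
  if (!"rank" %in% names(positions)) positions <- add_gene_ranks(positions)
  needed <- unique(unlist(clades$genes))
  missing <- setdiff(needed, positions$gene_id)
  if (length(missing)) stop("gene missing from positions: ", missing[[1]])
  chrom <- setNames(positions$chromosome, positions$gene_id)
  rnk <- setNames(positions$rank, positions$gene_id)

  tree <- ape::reorder.phylo(tree, "cladewise")
  tips <- tree$tip.label
  pairs <- purrr::map(seq_len(nrow(clades)), function(ci) {
    genes <- clades$genes[[ci]]
    if (length(genes) < 2L) return(NULL)
    if (all_pairs) {
      idx <- utils::combn(sort(genes, method = "radix"), 2)
      g1 <- idx[1, ]; g2 <- idx[2, ]
    } else {
      ch <- cherries_in(tree, genes)
      if (is.null(ch)) return(NULL)
      g1 <- ch[, 1]; g2 <- ch[, 2]
    }
    tibble(gene1 = g1, gene2 = g2, species = clades$species[[ci]],
           clade_id = clades$clade_id[[ci]])
  })
  out <- dplyr::bind_rows(pairs)
  if (nrow(out) == 0L) {
    return(tibble(gene1 = character(), gene2 = character(),
                  species = character(), clade_id = character(),
                  class = character()))
  }
  same_chr <- chrom[out$gene1] == chrom[out$gene2]
  gap <- abs(rnk[out$gene1] - rnk[out$gene2])
  out$class <- dplyr::case_when(
    same_chr & gap == 1 ~ "tandem",
    same_chr & gap >= 2 & gap <= proximal_max_gap ~ "proximal",
    .default = "distal"
  )
  out
}

# sibling leaf pairs (cherries) among the given genes
cherries_in <- function(tree, genes) {
  tips <- tree$tip.label
  idx <- match(genes, tips)
  parent <- tree$edge[match(idx, tree$edge[, 2]), 1]
  ch <- split(genes, parent)
  ch <- ch[lengths(ch) == 2L]
  if (length(ch) == 0L) return(NULL)
  m <- do.call(rbind, lapply(ch, function(g) sort(g, method = "radix")))
  m[order(m[, 1], method = "radix"), , drop = FALSE]
}

#' Full duplication report
#'
#' Combines [species_specific_clades()], [clade_size_histogram()],
#' per-species duplication counts and [classify_duplicate_pairs()] into one
#' object with a printed summary mirroring the usual expansion tables.
#'
#' @param tree A rooted `phylo`.
#' @param species_map Tibble `gene_id` -> `species`.
#' @param positions Optional position tibble; pair classes are skipped when
#'   absent.
#' @param proximal_max_gap Passed to [classify_duplicate_pairs()].
#' @param bins Passed to [clade_size_histogram()].
#' @return A `duplication_report`: list with `clades`, `histogram`,
#'   `duplications` (per species), `pairs`.
#' @export
duplication_report <- function(tree, species_map, positions = NULL,
                               proximal_max_gap = 10L,
                               bins = c(10L, 9L, 8L, 7L, 6L, 5L)) {
  clades <- species_specific_clades(tree, species_map)
  hist <- clade_size_histogram(clades, bins = bins)
  species <- sort(unique(species_map$species), method = "radix")
  dups <- tibble(
    species = species,
    duplications = vapply(species, function(s) {
      as.integer(lineage_specific_duplications(tree, species_map, s))
    }, integer(1), USE.NAMES = FALSE)
  )
  pairs <- if (!is.null(positions)) {
    classify_duplicate_pairs(tree, clades, positions,
                             proximal_max_gap = proximal_max_gap)
  } else NULL
  structure(list(clades = clades, histogram = hist, duplications = dups,
                 pairs = pairs),
            class = "duplication_report")
}

#' @export
print.duplication_report <- function(x, ...) {
  cat("Species-specific clades:", nrow(x$clades), "\n")
  cat("\nClade-size histogram:\n")
  print(as.data.frame(x$histogram), row.names = FALSE)
  cat("\nLineage-specific duplications:\n")
  print(as.data.frame(x$duplications), row.names = FALSE)
  if (!is.null(x$pairs) && nrow(x$pairs)) {
    cat("\nDuplicate-pair classes:\n")
    print(table(x$pairs$class))
  }
  invisible(x)
}

#' Plot the species-specific clade-size histogram
#'
#' @param object A `duplication_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.duplication_report <- function(object, ...) {
  h <- object$histogram
  h$bin <- factor(h$bin, levels = h$bin)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "clade size", y = "number of species-specific clades")
}
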