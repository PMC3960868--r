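# Reference-anchored classification: each unlabeled gene takes the label of
# the first ancestor clade containing reference genes, provided those
# references agree; otherwise it is reported as unclassified, mirroring the
# "could not be assigned unambiguously" category of reference-guided
# phylogenetic annotation.

#' Read a reference label table
#'
#' TSV with columns `gene_id`, `species`, `type` and optionally `group`
#' (empty/NA when a reference is informative only at type level).
#'
#' @param path Path to the TSV.
#' @return A tibble with those columns.
#' @export
read_reference_labels <- function(path) {
  refs <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  stopifnot(all(c("gene_id", "species", "type") %in% names(refs)))
  if (!"group" %in% names(refs)) refs$group <- NA_character_
  refs
}

#' Assign labels to tree leaves from reference positions
#'
#' For each unlabeled leaf, ascend from the leaf toward the root; at the
#' first proper ancestor clade that contains at least one reference leaf,
#' assign that clade's reference label if all references in it agree,
#' otherwise `"unclassified"`. The root clade is not accepted as support:
#' it contains every leaf and is therefore uninformative about placement —
#' a query whose first reference-containing ancestor is the root (e.g.
#' when no reference of its true label is present at all) stays
#' `"unclassified"` rather than taking the label of references it never
#' clusters with. Reference leaves keep their own labels. The supporting
#' clade size and reference count are recorded.
#'
#' @param tree A rooted `phylo`.
#' @param refs Reference tibble (`gene_id`, `species`, `type`, `group`).
#' @param level `"type"` or `"group"`: which reference column to use.
#' @return A tibble: `gene_id`, `label`, `clade_size`, `n_refs`,
#'   `is_reference`.
#' @export
assign_labels <- function(tree, refs, level = c("type", "group")) {
  level <- match.arg(level)
  labels <- setNames(refs[[level]], refs$gene_id)
  labels <- labels[!is.na(labels) & nzchar(labels)]
  tree <- ape::reorder.phylo(tree, "cladewise")
  tips <- tree$tip.label
  if (!any(tips %in% names(labels))) stop("no reference leaves in tree")

  n <- length(tips)
  parent <- rep(NA_integer_, n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  # reference labels contained in each node's clade, by postorder sweep
  ref_at <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) {
    if (tips[[i]] %in% names(labels)) ref_at[[i]] <- labels[[tips[[i]]]]
  }
  for (e in rev(seq_len(nrow(tree$edge)))) {   # cladewise edges reversed
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]
    ref_at[a] <- list(c(ref_at[[a]], ref_at[[b]]))
  }
  clade_sizes <- clade_size_per_node(tree)

  rows <- purrr::map(seq_len(n), function(i) {
    gid <- tips[[i]]
    if (gid %in% names(labels)) {
      return(tibble(gene_id = gid, label = labels[[gid]],
                    clade_size = 1L, n_refs = 1L, is_reference = TRUE))
    }
    node <- i
    repeat {
      node <- parent[[node]]
      if (is.na(node) || is.na(parent[[node]])) {
        # reached the root without informative support below it
        return(tibble(gene_id = gid, label = "unclassified",
                      clade_size = NA_integer_, n_refs = 0L,
                      is_reference = FALSE))
      }
      found <- ref_at[[node]]
      if (length(found)) {
        lab <- if (length(unique(found)) == 1L) found[[1]] else "unclassified"
        return(tibble(gene_id = gid, label = lab,
                      clade_size = clade_sizes[[node]],
                      n_refs = length(found), is_reference = FALSE))
      }
    }
  })
  dplyr::bind_rows(rows)
}

# number of descendant leaves per node (tips count as 1)
clade_size_per_node <- function(tree) {
  n <- length(tree$tip.label)
  size <- c(rep(1L, n), rep(0L, tree$Nnode))
  tree <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tree$edge))) {
    size[tree$edge[e, 1]] <- size[tree$edge[e, 1]] + size[tree$edge[e, 2]]
  }
  size
}

#' Two-stage type/group classification
#'
#' Stage 1 builds a joint tree of all genes plus references and assigns the
#' type label (Type I vs Type II in the MADS-box setting). Stage 2 rebuilds
#' a separate tree per assigned type, restricted to that type's genes and
#' group-labeled references, and assigns group labels (M-alpha/M-beta/
#' M-gamma within Type I; MIKC^C/MIKC* within Type II, or any user label
#' vocabulary). Genes unclassified at stage 1 are excluded from stage 2 and
#' reported as unclassified at both levels.
#'
#' Trees are built with [implicit_msa()] + [p_distance_matrix()] +
#' [nj_tree()] + [midpoint_root()]. A stage with fewer than three leaves
#' falls back to direct label transfer when its references agree.
#'
#' @param hits Hit tibble covering query and reference genes (paths kept).
#' @param proteins Sequence tibble for all hit genes.
#' @param hmm The profile the hits were scored with.
#' @param refs Reference tibble (`gene_id`, `species`, `type`, `group`).
#' @return A tibble: `gene_id`, `type`, `group`, clade support columns, and
#'   `is_reference`; plus the stage trees in attribute `"trees"`.
#' @export
two_stage_classify <- function(hits, proteins, hmm, refs) {
  msa <- implicit_msa(hmm, hits, proteins)
  if (nrow(msa) < 3L) stop("need at least three genes to build a tree")
  tree1 <- midpoint_root(nj_tree(p_distance_matrix(msa)))
  stage1 <- assign_labels(tree1, refs, level = "type")

  types <- sort(unique(refs$type), method = "radix")
  trees <- list(joint = tree1)
  stage2 <- purrr::map(types, function(ty) {
    members <- stage1$gene_id[stage1$label == ty]
    grefs <- refs[refs$type == ty & !is.na(refs$group) & nzchar(refs$group), ,
                  drop = FALSE]
    sub <- msa[msa$id %in% members, , drop = FALSE]
    queries <- setdiff(members, refs$gene_id)
    if (length(queries) == 0L) return(NULL)
    if (nrow(sub) < 3L || nrow(grefs) == 0L) {
      lab <- if (length(unique(grefs$group)) == 1L) grefs$group[[1]]
             else "unclassified"
      return(tibble(gene_id = queries, group = lab,
                    group_clade_size = NA_integer_,
                    group_n_refs = nrow(grefs)))
    }
    ty_tree <- midpoint_root(nj_tree(p_distance_matrix(sub)))
    trees[[ty]] <<- ty_tree
    got <- assign_labels(ty_tree, grefs, level = "group")
    tibble(gene_id = got$gene_id, group = got$label,
           group_clade_size = got$clade_size, group_n_refs = got$n_refs)
  })
  stage2 <- dplyr::bind_rows(stage2)

  out <- tibble(
    gene_id = stage1$gene_id,
    type = stage1$label,
    type_clade_size = stage1$clade_size,
    type_n_refs = stage1$n_refs,
    is_reference = stage1$is_reference
  )
  out <- dplyr::left_join(out, stage2, by = "gene_id")
  # references keep their own group labels; unclassified genes stay so
  ref_group <- setNames(refs$group, refs$gene_id)
  is_ref <- out$gene_id %in% refs$gene_id
  out$group[is_ref] <- unname(ref_group[out$gene_id[is_ref]])
  out$group[is.na(out$group)] <- "unclassified"
  attr(out, "trees") <- trees
  class(out) <- c("famscan_classification", class(out))
  out
}

#' @export
glance.famscan_classification <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_unclassified_type = sum(x$type == "unclassified"),
    n_unclassified_group = sum(x$group == "unclassified")
  )
}
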