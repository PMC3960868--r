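# Domain alignment and tree building: implicit MSA from HMM match states,
# p-distances, Saitou-Nei neighbor joining, midpoint rooting and Newick I/O.
# Trees are ape "phylo" objects throughout.

#' Implicit multiple alignment from HMM alignment paths
#'
#' Every hit scored against the same profile carries a state path; placing
#' each match-emitted residue in its match state's column yields a
#' fixed-width alignment of exactly K columns without running an external
#' aligner. Delete states become `"-"`; insert-state residues are dropped.
#'
#' @param hmm The `profile_hmm` the hits were scored against.
#' @param hits Hit tibble with retained `path` column (from
#'   [scan_proteins()]), plus `target_start` and `state_first`.
#' @param proteins Sequence tibble the hits refer to.
#' @return Aligned sequence tibble (`id`, `seq`), all rows of length K.
#' @export
implicit_msa <- function(hmm, hits, proteins) {
  if (any(is.na(hits$path))) stop("hit without an alignment path")
  seqs <- setNames(proteins$seq, proteins$id)
  rows <- vapply(seq_len(nrow(hits)), function(r) {
    h <- hits[r, ]
    chars <- strsplit(seqs[[h$target_id]], "")[[1]]
    ops <- strsplit(h$path, "")[[1]]
    col <- rep("-", hmm$K)
    k <- h$state_first
    i <- h$target_start + 1L
    for (op in ops) {
      if (op == "M") { col[[k]] <- chars[[i]]; i <- i + 1L; k <- k + 1L }
      else if (op == "D") { k <- k + 1L }
      else { i <- i + 1L }          # insert residues are dropped
    }
    paste(col, collapse = "")
  }, character(1))
  tibble(id = hits$target_id, seq = rows, description = "")
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` is the mismatch fraction over columns where neither row has a
#' gap. A pair with no comparable columns is an error.
#'
#' @param msa Aligned sequence tibble (>= 2 rows, equal lengths).
#' @return A symmetric matrix with zero diagonal, dimnames = ids.
#' @export
p_distance_matrix <- function(msa) {
  n <- nrow(msa)
  if (n < 2L) stop("need at least two aligned sequences")
  mat <- do.call(rbind, strsplit(msa$seq, ""))
  d <- matrix(0, n, n, dimnames = list(msa$id, msa$id))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1L, n)) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between ", msa$id[[i]], " and ",
             msa$id[[j]])
      }
      d[i, j] <- d[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    }
  }
  d
}

#' Write a distance matrix to TSV
#'
#' Labels in the first column, one column per taxon.
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  out <- as_tibble(as.data.frame(d), rownames = "id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimising
#' `Q(i, j) = (N - 2) d(i, j) - r_i - r_j`, with branch lengths from the
#' standard closed form; ties are broken by the lexicographically smallest
#' label pair (each cluster is represented by its smallest leaf label).
#' Negative branch-length estimates are clamped to zero with the deficit
#' moved to the sibling branch, preserving the pair's summed length.
#'
#' @param distances Symmetric matrix with zero diagonal, n >= 3.
#' @param labels Leaf labels; defaults to the matrix dimnames.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(distances, labels = rownames(distances)) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (is.null(labels)) stop("labels required")
  if (n < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
      any(abs(diag(d)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  # locale-independent label ranks for deterministic tie-breaking
  lab_rank <- match(labels, labels[order(labels, method = "radix")])

  n_nodes <- 2L * n - 2L                 # leaves + internal (unrooted binary)
  edge <- matrix(0L, 0, 2); elen <- numeric(0)
  active <- seq_len(n)                   # node ids of active clusters
  rep_rank <- lab_rank                   # smallest-label rank per cluster
  next_node <- n + 1L
  rownames(d) <- colnames(d) <- NULL

  while (length(active) > 3L) {
    N <- length(active)
    r <- rowSums(d)
    q <- (N - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- NULL
    for (i in seq_len(N - 1)) for (j in seq(i + 1L, N)) {
      key <- sort(c(rep_rank[[i]], rep_rank[[j]]))
      if (is.null(best) || q[i, j] < best$q - 1e-12 ||
          (abs(q[i, j] - best$q) <= 1e-12 &&
           (key[[1]] < best$key[[1]] ||
            (key[[1]] == best$key[[1]] && key[[2]] < best$key[[2]])))) {
        best <- list(q = q[i, j], i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    li <- d[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (N - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    node <- next_node; next_node <- next_node + 1L
    edge <- rbind(edge, c(node, active[[i]]), c(node, active[[j]]))
    elen <- c(elen, li, lj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    active <- c(active[keep], node)
    rep_rank <- c(rep_rank[keep], min(best$key))
  }

  # final three clusters join at the central (root) node
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  node <- next_node
  edge <- rbind(edge, c(node, active[[1]]), c(node, active[[2]]),
                c(node, active[[3]]))
  elen <- c(elen, pmax(c(la, lb, lc), 0))

  # ape convention: root must be node n + 1; swap numbering accordingly
  swap <- function(x, a, b) { x[x == a] <- 0L; x[x == b] <- a; x[x == 0L] <- b; x }
  if (node != n + 1L) edge <- swap(edge, n + 1L, node)
  tree <- structure(
    list(edge = edge, edge.length = elen, tip.label = labels,
         Nnode = n - 2L),
    class = "phylo", order = NULL
  )
  ape::reorder.phylo(tree, "cladewise")
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path. With
#' every branch length zero the tree has no midpoint; the root is then
#' placed deterministically at the first tip in label order, with a
#' warning.
#'
#' @param tree An unrooted `phylo` with >= 2 leaves.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) == 2L) {
    total <- sum(tree$edge.length)
    tree$edge.length <- rep(total / 2, length(tree$edge.length))
    return(tree)
  }
  if (all(tree$edge.length <= 0)) {
    warning("all branch lengths zero; rooting at the first tip in label order",
            call. = FALSE)
    tip <- tree$tip.label[order(tree$tip.label, method = "radix")][[1]]
    return(ape::root(tree, outgroup = tip, resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Read a Newick tree
#'
#' Standard Newick with branch lengths and quoted labels. Unbalanced
#' parentheses are reported with their position.
#'
#' @param path Path to a Newick file.
#' @return A `phylo`.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  in_quote <- FALSE
  for (pos in seq_along(chars)) {
    ch <- chars[[pos]]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced parenthesis at position ", pos)
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " unclosed")
  tree <- tryCatch(ape::read.tree(text = txt), error = function(e) NULL,
                   warning = function(w) NULL)
  if (is.null(tree)) stop("failed to parse Newick in ", path)
  tree
}

#' Write a Newick tree
#'
#' @param tree A `phylo`.
#' @param path Output path.
#' @param digits Branch-length precision.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, digits = 10L) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}
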