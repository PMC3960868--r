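# Profile HMM built from a seed alignment of domain exemplars. Match/insert
# column assignment follows the classical gap-fraction rule; emissions and
# transitions are estimated with background-weighted Laplace pseudocounts.

#' Build a profile HMM from a seed alignment
#'
#' Alignment columns whose gap fraction is below `gap_threshold` become match
#' states; the remaining columns are treated as insert columns. Match
#' emissions for residue `a` in a column with `n_a` observations out of
#' `n` residues are `(n_a + w * q_a) / (n + w)` where `q_a` is the
#' background frequency (the seed's overall residue frequencies, smoothed
#' with a uniform pseudocount) and `w = pseudocount_weight`. Transition
#' probabilities are estimated from the observed match/insert/delete paths
#' of the seed rows with the analogous pseudocount rule (uniform prior over
#' the outgoing options of each state). Insert states emit at background.
#'
#' @param seed_msa Aligned protein records: a tibble with columns `id`,
#'   `seq`, all rows the same length, gap character `"-"`.
#' @param gap_threshold Columns with gap fraction strictly below this become
#'   match states.
#' @param pseudocount_weight Total pseudocount mass added per
#'   emission/transition distribution. Must be positive.
#' @return An object of class `profile_hmm` with elements `K`,
#'   `match_emissions` (K x 20), `insert_emissions`, `background`,
#'   `trans` (per-position M/I/D transition probabilities), and the
#'   construction parameters.
#' @export
build_profile <- function(seed_msa, gap_threshold = 0.5,
                          pseudocount_weight = 1.0) {
  stopifnot(all(c("id", "seq") %in% names(seed_msa)))
  if (nrow(seed_msa) < 1L) stop("empty seed alignment")
  if (pseudocount_weight <= 0) stop("pseudocount_weight must be positive")
  wdt <- unique(nchar(seed_msa$seq))
  if (length(wdt) != 1L) stop("seed alignment rows have unequal lengths")
  mat <- do.call(rbind, strsplit(toupper(seed_msa$seq), ""))
  bad <- setdiff(unique(as.vector(mat)), c(AA20, "-", "X"))
  if (length(bad)) stop("invalid residue in seed alignment: ", bad[[1]])

  gap_frac <- colMeans(mat == "-")
  is_match <- gap_frac < gap_threshold
  K <- sum(is_match)
  if (K == 0L) stop("no match states: every column exceeds the gap threshold")

  # background: overall seed residue frequencies with a uniform pseudocount
  res <- as.vector(mat)
  res <- res[res %in% AA20]
  counts <- table(factor(res, levels = AA20))
  background <- (as.numeric(counts) + 1) / (length(res) + 20)
  names(background) <- AA20

  w <- pseudocount_weight
  match_cols <- which(is_match)
  match_emissions <- t(vapply(match_cols, function(j) {
    col <- mat[, j]
    col <- col[col %in% AA20]
    cnt <- as.numeric(table(factor(col, levels = AA20)))
    (cnt + w * background) / (length(col) + w)
  }, numeric(20)))
  dimnames(match_emissions) <- list(paste0("M", seq_len(K)), AA20)

  trans <- estimate_transitions(mat, is_match, K, w)

  structure(
    list(K = K, alphabet = AA20, match_emissions = match_emissions,
         insert_emissions = background, background = background,
         trans = trans, match_columns = match_cols,
         gap_threshold = gap_threshold, pseudocount_weight = w,
         n_seq = nrow(seed_msa)),
    class = "profile_hmm"
  )
}

# Count M/I/D transitions between consecutive match positions from each seed
# row's implied state path; pseudocount with a uniform prior over each
# state's outgoing options. Insert residues before the first and after the
# last match position are outside the local model and ignored.
estimate_transitions <- function(mat, is_match, K, w) {
  if (K == 1L) {
    z <- numeric(0)
    return(list(MM = z, MI = z, MD = z, IM = z, II = z, DM = z, DD = z))
  }
  cnt <- matrix(0, nrow = K - 1, ncol = 7,
                dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  match_cols <- which(is_match)
  for (r in seq_len(nrow(mat))) {
    row <- mat[r, ]
    for (k in seq_len(K - 1)) {
      j0 <- match_cols[[k]]; j1 <- match_cols[[k + 1]]
      src <- if (row[[j0]] == "-") "D" else "M"
      dst <- if (row[[j1]] == "-") "D" else "M"
      between <- row[seq(j0 + 1L, length.out = j1 - j0 - 1L)]
      n_ins <- sum(between != "-")
      if (n_ins == 0L) {
        cnt[k, paste0(src, dst)] <- cnt[k, paste0(src, dst)] + 1
      } else {
        # src -> I, (n_ins - 1) x I -> I, I -> dst; inserts after a deleted
        # match position are attributed to the same insert state
        # the model has no D->I edge; an insert run opened after a deletion
        # contributes only its I->I / I->M events
        if (src == "M") cnt[k, "MI"] <- cnt[k, "MI"] + 1
        else cnt[k, "DM"] <- cnt[k, "DM"] + 1
        cnt[k, "II"] <- cnt[k, "II"] + (n_ins - 1)
        # the model has no I->D edge; an insert run is always closed by I->M
        cnt[k, "IM"] <- cnt[k, "IM"] + 1
      }
    }
  }
  norm <- function(block, prior) {
    tot <- rowSums(block) + w
    sweep(block + w * matrix(prior, nrow(block), length(prior), byrow = TRUE),
          1, tot, "/")
  }
  m <- norm(cnt[, c("MM", "MI", "MD"), drop = FALSE], rep(1 / 3, 3))
  i <- norm(cnt[, c("IM", "II"), drop = FALSE], rep(1 / 2, 2))
  d <- norm(cnt[, c("DM", "DD"), drop = FALSE], rep(1 / 2, 2))
  list(MM = m[, 1], MI = m[, 2], MD = m[, 3],
       IM = i[, 1], II = i[, 2], DM = d[, 1], DD = d[, 2])
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("Profile HMM:", x$K, "match states, built from", x$n_seq,
      "seed sequences\n")
  cat("  gap threshold", x$gap_threshold, "| pseudocount weight",
      x$pseudocount_weight, "\n")
  invisible(x)
}

#' @export
glance.profile_hmm <- function(x, ...) {
  tibble(n_states = x$K, n_seed = x$n_seq,
         gap_threshold = x$gap_threshold,
         pseudocount_weight = x$pseudocount_weight,
         consensus = profile_consensus(x))
}

#' @export
tidy.profile_hmm <- function(x, ...) {
  em <- as_tibble(x$match_emissions)
  em$state <- seq_len(x$K)
  tidyr::pivot_longer(em, -"state", names_to = "residue",
                      values_to = "probability")
}

#' Consensus sequence of a profile
#'
#' The most probable residue of each match state (ties broken by alphabet
#' order).
#'
#' @param hmm A `profile_hmm`.
#' @return A protein string of length `K`.
#' @export
profile_consensus <- function(hmm) {
  paste(AA20[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

# internal sanity check used by tests and on deserialisation
validate_profile <- function(hmm, tol = 1e-9) {
  stopifnot(inherits(hmm, "profile_hmm"), hmm$K >= 1)
  if (any(abs(rowSums(hmm$match_emissions) - 1) > tol))
    stop("match emission rows do not sum to 1")
  if (abs(sum(hmm$background) - 1) > tol) stop("background does not sum to 1")
  if (any(hmm$match_emissions <= 0)) stop("zero emission probability")
  if (hmm$K > 1) {
    tr <- hmm$trans
    if (any(abs(tr$MM + tr$MI + tr$MD - 1) > tol) ||
        any(abs(tr$IM + tr$II - 1) > tol) ||
        any(abs(tr$DM + tr$DD - 1) > tol))
      stop("transition distributions do not sum to 1")
  }
  invisible(hmm)
}

#' Serialise a profile HMM to a plain-text table
#'
#' A versioned fixed-point text format: header, background, one match
#' emission row per state, and one transition row per state boundary, all at
#' six decimals. [read_profile()] renormalises on load so the stored
#' rounding does not violate probability invariants.
#'
#' @param hmm A `profile_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(hmm, path) {
  validate_profile(hmm)
  fmt <- function(x) paste(sprintf("%.6f", x), collapse = "\t")
  lines <- c(
    "#famscan-profile\t1",
    paste0("K\t", hmm$K),
    paste0("alphabet\t", paste(hmm$alphabet, collapse = "")),
    paste0("background\t", fmt(hmm$background)),
    vapply(seq_len(hmm$K), function(k) {
      paste0("match\t", k, "\t", fmt(hmm$match_emissions[k, ]))
    }, character(1)),
    if (hmm$K > 1) vapply(seq_len(hmm$K - 1), function(k) {
      tr <- hmm$trans
      paste0("trans\t", k, "\t",
             fmt(c(tr$MM[k], tr$MI[k], tr$MD[k], tr$IM[k], tr$II[k],
                   tr$DM[k], tr$DD[k])))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a serialised profile HMM
#'
#' @param path Path written by [write_profile()].
#' @return A `profile_hmm`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[[1]], "#famscan-profile")) {
    stop("not a famscan profile file: ", path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(fields, `[[`, character(1), 1)
  K <- as.integer(fields[[which(tag == "K")]][[2]])
  nums <- function(x, from) as.numeric(x[seq(from, length(x))])
  background <- nums(fields[[which(tag == "background")]], 2)
  background <- background / sum(background)
  names(background) <- AA20
  em <- do.call(rbind, lapply(fields[tag == "match"], nums, from = 3))
  em <- sweep(em, 1, rowSums(em), "/")
  dimnames(em) <- list(paste0("M", seq_len(K)), AA20)
  if (K > 1) {
    tr <- do.call(rbind, lapply(fields[tag == "trans"], nums, from = 3))
    m <- sweep(tr[, 1:3, drop = FALSE], 1, rowSums(tr[, 1:3, drop = FALSE]), "/")
    i <- sweep(tr[, 4:5, drop = FALSE], 1, rowSums(tr[, 4:5, drop = FALSE]), "/")
    d <- sweep(tr[, 6:7, drop = FALSE], 1, rowSums(tr[, 6:7, drop = FALSE]), "/")
    trans <- list(MM = m[, 1], MI = m[, 2], MD = m[, 3],
                  IM = i[, 1], II = i[, 2], DM = d[, 1], DD = d[, 2])
  } else {
    z <- numeric(0)
    trans <- list(MM = z, MI = z, MD = z, IM = z, II = z, DM = z, DD = z)
  }
  hmm <- structure(
    list(K = K, alphabet = AA20, match_emissions = em,
         insert_emissions = background, background = background,
         trans = trans, match_columns = NA_integer_,
         gap_threshold = NA_real_, pseudocount_weight = NA_real_,
         n_seq = NA_integer_),
    class = "profile_hmm"
  )
  validate_profile(hmm)
}
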