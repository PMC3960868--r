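# Independent brute-force oracle for the profile-HMM dynamic programming:
# explicit enumeration of every legal single-domain local alignment path.
# Shares no code with the DP kernels — transitions and emissions are walked
# recursively and each complete path's score is accumulated.

# Returns list(viterbi = max path score, forward = log2 sum of path odds).
oracle_scores <- function(hmm, protein) {
  obs <- strsplit(protein, "")[[1]]
  L <- length(obs)
  K <- hmm$K
  em <- function(k, i) {
    a <- obs[[i]]
    if (a == "X") 0 else log2(hmm$match_emissions[k, a] / hmm$background[[a]])
  }
  tr <- lapply(hmm$trans, log2)
  entry <- -log2(K)
  best <- -Inf
  total_odds <- 0
  # state: "M"/"I"/"D"; k = profile position; i = last consumed residue
  rec <- function(state, k, i, score) {
    if (state == "M") {
      # exit is free after any match state: record the completed path
      if (score > best) best <<- score
      total_odds <<- total_odds + 2^score
      if (k < K) {
        if (i < L) rec("M", k + 1L, i + 1L,
                       score + tr$MM[[k]] + em(k + 1L, i + 1L))
        rec("D", k + 1L, i, score + tr$MD[[k]])
        if (i < L) rec("I", k, i + 1L, score + tr$MI[[k]])
      }
    } else if (state == "I") {
      if (i < L) {
        rec("M", k + 1L, i + 1L, score + tr$IM[[k]] + em(k + 1L, i + 1L))
        rec("I", k, i + 1L, score + tr$II[[k]])
      }
    } else {                                  # D
      if (k < K) {
        if (i < L) rec("M", k + 1L, i + 1L,
                       score + tr$DM[[k]] + em(k + 1L, i + 1L))
        rec("D", k + 1L, i, score + tr$DD[[k]])
      }
    }
  }
  for (i0 in seq_len(L)) {
    for (k0 in seq_len(K)) {
      rec("M", k0, i0, entry + em(k0, i0))
    }
  }
  list(viterbi = best, forward = log2(total_odds))
}

# small profiles over a reduced alphabet for oracle comparisons
reduced_profile <- function(K, seed = 1L) {
  alpha <- c("A", "C", "D")
  withr::with_seed(seed, {
    rows <- replicate(4, paste(sample(alpha, K, replace = TRUE),
                               collapse = ""))
  })
  build_profile(seq_tbl(paste0("s", 1:4), rows, alphabet = "protein"))
}

all_reduced_proteins <- function(max_len, alpha = c("A", "C", "D")) {
  unlist(lapply(seq_len(max_len), function(l) {
    do.call(paste0, expand.grid(rep(list(alpha), l)))
  }))
}
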