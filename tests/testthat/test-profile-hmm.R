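test_that("match emissions follow the pseudocount formula on identical seeds", {
  msa <- seq_tbl(c("a", "b", "c"), rep("MKRGA", 3), alphabet = "protein")
  hmm <- build_profile(msa, pseudocount_weight = 1)
  expect_equal(hmm$K, 5L)
  # (observed + w * q_a) / (depth + w), observed = 3, depth = 3, w = 1
  cols <- strsplit("MKRGA", "")[[1]]
  for (k in 1:5) {
    q <- hmm$background[[cols[[k]]]]
    expect_equal(hmm$match_emissions[k, cols[[k]]], (3 + q) / 4)
  }
})

test_that("the gap-fraction threshold decides match vs insert columns", {
  # column 3 has 60% gaps at threshold 0.5 -> insert column, K = 4
  rows <- c("MK-GA", "MK-GA", "MKRGA", "MK-GA", "MKRGA")
  hmm <- build_profile(seq_tbl(paste0("s", 1:5), rows, alphabet = "protein"))
  expect_equal(hmm$K, 4L)
  expect_equal(hmm$match_columns, c(1L, 2L, 4L, 5L))

  single <- build_profile(seq_tbl("only", "MKR-A", alphabet = "protein"))
  expect_equal(single$K, 4L)  # ungapped length of a single-sequence seed

  expect_error(build_profile(seq_tbl("a", "ACD", alphabet = "protein")[0, ]),
               "empty")
  allgap <- seq_tbl(c("a", "b"), c("A-", "-C"), alphabet = "protein")
  expect_error(build_profile(allgap, gap_threshold = 0.4), "no match states")
})

test_that("profiles are properly normalised and strictly positive", {
  withr::with_seed(3, {
    for (i in 1:5) {
      rows <- replicate(6, paste(sample(AA20, 12, TRUE), collapse = ""))
      rows[2] <- sub("^..", "--", rows[2])
      hmm <- build_profile(seq_tbl(paste0("s", 1:6), rows,
                                   alphabet = "protein"))
      expect_equal(unname(rowSums(hmm$match_emissions)), rep(1, hmm$K),
                   tolerance = 1e-9)
      expect_equal(sum(hmm$background), 1, tolerance = 1e-9)
      expect_true(all(hmm$match_emissions > 0))
      tr <- hmm$trans
      expect_equal(unname(tr$MM + tr$MI + tr$MD), rep(1, hmm$K - 1),
                   tolerance = 1e-9)
      expect_equal(unname(tr$IM + tr$II), rep(1, hmm$K - 1), tolerance = 1e-9)
      expect_equal(unname(tr$DM + tr$DD), rep(1, hmm$K - 1), tolerance = 1e-9)
    }
  })
})

test_that("consensus scoring uses all match states with a positive score", {
  msa <- seq_tbl(paste0("s", 1:4), rep("MKRGAWQD", 4), alphabet = "protein")
  hmm <- build_profile(msa)
  v <- viterbi_score(hmm, "MKRGAWQD")
  expect_gt(v$bit_score, 0)
  expect_equal(v$path, paste(rep("M", 8), collapse = ""))
  expect_equal(v$state_first, 1L)
  expect_equal(v$state_last, 8L)
  # flanking residues are free: same score inside a longer sequence
  v2 <- viterbi_score(hmm, "CCMKRGAWQDCC")
  expect_equal(v2$bit_score, v$bit_score)
  expect_equal(v2$target_start, 2L)
  expect_equal(v2$target_end, 10L)
})

test_that("scores of unrelated sequences can be negative but never empty-span", {
  msa <- seq_tbl(paste0("s", 1:4), rep("WWWWWWWW", 4), alphabet = "protein")
  hmm <- build_profile(msa)
  withr::with_seed(9, {
    for (i in 1:10) {
      p <- paste(sample(setdiff(AA20, "W"), 12, TRUE), collapse = "")
      v <- viterbi_score(hmm, p)
      expect_true(is.finite(v$bit_score))
      expect_gte(v$target_end - v$target_start, 1L)  # at least one residue
    }
  })
  expect_error(viterbi_score(hmm, ""), "non-empty")
  expect_error(viterbi_score(hmm, "MKB"), "outside alphabet")
})

test_that("X residues are emitted at background (zero bits)", {
  msa <- seq_tbl(paste0("s", 1:4), rep("MKRGA", 4), alphabet = "protein")
  hmm <- build_profile(msa)
  full <- viterbi_score(hmm, "MKRGA")$bit_score
  withx <- viterbi_score(hmm, "MKXGA")$bit_score
  m <- log2(hmm$match_emissions[3, "R"] / hmm$background[["R"]])
  expect_equal(withx, full - m, tolerance = 1e-9)
})

test_that("log-odds scores are invariant to a consistent background rescale", {
  hmm <- reduced_profile(4, seed = 2)
  scale <- c(2, rep(1, 19))            # rescale residue A consistently
  hmm2 <- hmm
  hmm2$match_emissions <- sweep(hmm$match_emissions, 2, scale, "*")
  hmm2$background <- hmm$background * scale
  for (p in c("AACD", "CDAC", "DDDD")) {
    expect_equal(viterbi_score(hmm2, p)$bit_score,
                 viterbi_score(hmm, p)$bit_score, tolerance = 1e-9)
    expect_equal(forward_score(hmm2, p), forward_score(hmm, p),
                 tolerance = 1e-9)
  }
})

test_that("profile serialisation round-trips within format precision", {
  hmm <- study_hmm()
  path <- withr::local_tempfile(fileext = ".txt")
  write_profile(hmm, path)
  got <- read_profile(path)
  expect_equal(got$K, hmm$K)
  expect_equal(got$match_emissions, hmm$match_emissions, tolerance = 1e-4)
  expect_equal(got$trans$MM, hmm$trans$MM, tolerance = 1e-4,
               ignore_attr = TRUE)
  validate_profile(got)  # renormalised on read
  expect_error(read_profile(withr::local_tempfile(lines = "garbage")),
               "not a famscan profile")
})

test_that("scan threshold semantics: disabled, selective and saturated", {
  withr::with_seed(21, {
    decoys <- vapply(1:10, function(i) {
      paste(sample(AA20, 80, TRUE), collapse = "")
    }, character(1))
  })
  hmm <- study_hmm()
  planted <- profile_consensus(hmm)
  proteome <- seq_tbl(c(paste0("r", 1:10), "planted"), c(decoys, planted),
                      alphabet = "protein")
  strict <- scan_proteins(hmm, proteome, 20)
  expect_equal(strict$target_id, "planted")
  all_hits <- scan_proteins(hmm, proteome, -Inf)
  expect_equal(sort(all_hits$target_id), sort(proteome$id))
  expect_equal(all_hits$bit_score, sort(all_hits$bit_score, decreasing = TRUE))
  none <- scan_proteins(hmm, proteome, max(all_hits$bit_score) + 1)
  expect_equal(nrow(none), 0L)
  expect_equal(nrow(scan_proteins(hmm, proteome[0, ], 0)), 0L)
})
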