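test_that("pairwise identity ignores shared gaps and counts one-sided gaps as mismatch", {
  expect_equal(pairwise_identity("ARNDK", "ARNDK"), 1)
  expect_equal(pairwise_identity("AR-K", "AK-K"), 2 / 3)
  expect_equal(pairwise_identity("A-RK", "AARK"), 3 / 4)
  expect_error(pairwise_identity("AR", "ARK"), "equal length")
  expect_error(pairwise_identity("--", "--"), "comparable")
})

test_that("pairwise identity equals a naive column scan on random pairs", {
  set.seed(51)
  alphabet <- c("A", "R", "N", "D", "K", "-")
  for (i in 1:25) {
    a <- paste(sample(alphabet, 30, replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, 30, replace = TRUE), collapse = "")
    if (all(strsplit(a, "")[[1]] == "-" & strsplit(b, "")[[1]] == "-")) next
    expect_equal(pairwise_identity(a, b), scan_identity(a, b))
  }
})

test_that("dereplication keeps one of an identical pair and leaves diverse sets alone", {
  msa <- make_msa("ARNDK", "ARNDK")
  expect_equal(nrow(dereplicate(msa)), 1L)
  diverse <- make_msa("ARNDK", "GHILM", "PQSTV")
  expect_equal(dereplicate(diverse), diverse)
  expect_error(dereplicate(diverse, threshold = 0), "\\(0, 1\\]")
  expect_error(dereplicate(diverse, threshold = 1.2), "\\(0, 1\\]")
})

test_that("dereplication matches the quadratic greedy oracle and is idempotent", {
  # crafted set: one duplicate cluster (rows 1, 3, 5) plus two diverse rows
  seqs <- c("ARNDKARNDK", "GHILMGHILM", "ARNDKARNDK", "PQSTVPQSTV", "ARNDKARNDT")
  msa <- make_msa(seqs)
  d <- dereplicate(msa, threshold = 0.9)
  expect_equal(d$seq_id, msa$seq_id[greedy_derep_oracle(seqs, 0.9)])
  expect_equal(dereplicate(d, threshold = 0.9), d)
  # protected reference scanned first survives even if a duplicate precedes it
  d_ref <- dereplicate(msa, threshold = 0.9, ref_id = "s3")
  expect_true("s3" %in% d_ref$seq_id)
  expect_false("s1" %in% d_ref$seq_id)
})

test_that("consensus profile reproduces single sequences and hand-counted columns", {
  one <- tibble::tibble(seq_id = "only", aligned_seq = "ARND")
  prof <- consensus_profile(one)
  expect_equal(prof$consensus, c("A", "R", "N", "D"))
  expect_equal(prof$conservation, rep(1, 4))

  col <- make_msa("R", "R", "R", "K")
  prof2 <- consensus_profile(col)
  expect_equal(prof2$consensus, "R")
  expect_equal(prof2$conservation, 0.75)

  # gap-majority column emits a gap; a half-gapped column does not
  gappy <- make_msa("A-", "--", "-K", "-A")
  prof3 <- consensus_profile(gappy)
  expect_equal(prof3$consensus[1], "-")    # 3/4 gapped
  expect_equal(prof3$conservation[1], 0.25)  # top residue A counted over all rows
  expect_equal(prof3$consensus[2], "A")    # 2/4 gapped, A/K tie -> lexicographic
  expect_equal(prof3$conservation[2], 0.25)
  tie <- make_msa("K", "R")
  expect_equal(consensus_profile(tie)$consensus, "K")
})

test_that("consensus conservation equals a brute-force column tally on a synthetic MSA", {
  msa <- generate_msa(n_sequences = 50, length = 40,
                      planted = tibble::tibble(column = c(5, 20),
                                               residue = c("R", "W"),
                                               conservation = c(0.9, 0.4)),
                      seed = 8)
  prof <- consensus_profile(msa)
  m <- do.call(rbind, strsplit(msa$aligned_seq, ""))
  for (j in seq_len(ncol(m))) {
    counts <- table(m[, j][m[, j] != "-"])
    expect_equal(prof$conservation[j], max(counts) / nrow(m))
    expect_lte(prof$conservation[j], 1 - prof$gap_fraction[j] + 1e-12)
    expect_gte(prof$conservation[j], 1 / nrow(m))
  }
})

test_that("reference positions map through gaps to alignment columns", {
  msa <- tibble::tibble(seq_id = c("ref", "h1"), aligned_seq = c("A-RG", "AKRG"))
  expect_equal(map_position(msa, "ref", 1), 1L)
  expect_equal(map_position(msa, "ref", 2), 3L)
  expect_equal(map_position(msa, "ref", 3), 4L)
  expect_error(map_position(msa, "ref", 4), "outside")
  expect_error(map_position(msa, "nope", 1), "not found")
  # ungapped reference: column equals position; random gapped vs linear scan
  set.seed(9)
  for (i in 1:10) {
    chars <- sample(c("A", "R", "K", "-"), 20, replace = TRUE)
    if (!any(chars != "-")) chars[1] <- "A"
    msa2 <- tibble::tibble(seq_id = "ref",
                           aligned_seq = paste(chars, collapse = ""))
    non_gap <- which(chars != "-")
    pos <- sample(seq_along(non_gap), 1)
    expect_equal(map_position(msa2, "ref", pos), non_gap[pos])
  }
})

test_that("residue conservation excludes the reference and treats gaps as mismatch", {
  msa <- make_msa("R", "R", "R")
  names(msa)[1] <- "seq_id"
  expect_equal(residue_conservation(msa, "s1", 1), 1)
  msa2 <- make_msa("R", "K", "-")
  expect_equal(residue_conservation(msa2, "s1", 1), 0)
})

test_that("residue conservation is invariant to entry order and all-gap columns", {
  msa <- generate_msa(n_sequences = 40, length = 30,
                      planted = tibble::tibble(column = 10, residue = "R",
                                               conservation = 0.6),
                      seed = 21)
  base <- residue_conservation(msa, "ref", 10)
  set.seed(22)
  shuffled <- msa[c(1, sample(2:nrow(msa))), ]
  expect_equal(residue_conservation(shuffled, "ref", 10), base)
  # inserting an all-gap column in every entry changes nothing
  padded <- msa
  padded$aligned_seq <- paste0(substr(msa$aligned_seq, 1, 5), "-",
                               substr(msa$aligned_seq, 6, 30))
  expect_equal(residue_conservation(padded, "ref", 10), base)
  expect_equal(pairwise_identity(padded$aligned_seq[1], padded$aligned_seq[2]),
               pairwise_identity(msa$aligned_seq[1], msa$aligned_seq[2]))
})
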