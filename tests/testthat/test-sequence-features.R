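test_that("AT fraction handles plain, ambiguous and degenerate sequences", {
  expect_equal(at_fraction(c("ATAT", "GCGC", "ATGC")), c(1, 0, 0.5))
  # N excluded from numerator and denominator
  expect_equal(at_fraction("ATNN"), 1)
  expect_equal(at_fraction("ANGC"), 1 / 3)
  expect_error(at_fraction(""), "non-empty")
  expect_error(at_fraction("NNN"), "undefined")
})

test_that("longest AT run counts contiguous A/T only, broken by N", {
  expect_equal(longest_at_run(c("GCATATGC", "CCCC", "ATTTA")), c(4L, 0L, 5L))
  expect_equal(longest_at_run("AANTTT"), 3L)
  expect_error(longest_at_run(""), "non-empty")
})

test_that("both statistics are case-insensitive and reverse-complement invariant", {
  set.seed(41)
  seqs <- random_dna(50, 60, alphabet = c("A", "C", "G", "T", "N"))
  expect_equal(at_fraction(tolower(seqs)), at_fraction(seqs))
  expect_equal(longest_at_run(tolower(seqs)), longest_at_run(seqs))
  revcomp <- chartr("ACGT", "TGCA", sapply(lapply(strsplit(seqs, ""), rev),
                                           paste, collapse = ""))
  expect_equal(at_fraction(revcomp), at_fraction(seqs))
  expect_equal(longest_at_run(revcomp), longest_at_run(seqs))
})

test_that("features match an independent per-character scan on random probes", {
  set.seed(42)
  seqs <- random_dna(100, 60, alphabet = c("A", "C", "G", "T", "N"))
  expect_equal(at_fraction(seqs), vapply(seqs, scan_at_fraction, 0, USE.NAMES = FALSE))
  expect_equal(longest_at_run(seqs),
               vapply(seqs, scan_longest_at_run, 0L, USE.NAMES = FALSE))
})

test_that("probe_features preserves order, handles empty sets, rejects duplicates", {
  probes <- tibble::tibble(probe_id = "p1", sequence = "ATGC", signal = 1)
  row <- probe_features(probes)
  expect_equal(row$at_fraction, 0.5)
  expect_equal(row$longest_at_run, 2L)

  empty <- probe_features(tibble::tibble(probe_id = character(),
                                         sequence = character(),
                                         signal = numeric()))
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("at_fraction", "longest_at_run") %in% names(empty)))

  dup <- tibble::tibble(probe_id = c("p1", "p1"), sequence = c("AT", "GC"),
                        signal = c(1, 2))
  expect_error(probe_features(dup), "unique")
  expect_error(probe_features(tibble::tibble(probe_id = "p", sequence = "AT",
                                             signal = Inf)), "finite")
})

test_that("binning splits signals as hand-checked arithmetic", {
  feats <- tibble::tibble(longest_at_run = c(2L, 2L, 5L, 5L),
                          signal = c(1, 3, 5, 7))
  b <- bin_signal(feats, max_run = 8)
  expect_equal(b$mean_signal[b$bin == "2"], 2)
  expect_equal(b$mean_signal[b$bin == "5"], 6)
  expect_equal(sum(b$n_probes), 4L)
  # singleton bin: mean equals the probe's signal, sd undefined
  single <- bin_signal(tibble::tibble(at_fraction = 0.42, signal = 3.5),
                       feature = "at_fraction")
  expect_equal(single$mean_signal[single$n_probes == 1L], 3.5)
  expect_true(is.na(single$sd_signal[single$n_probes == 1L]))
})

test_that("bin means match a brute-force group-by oracle and conserve the grand mean", {
  probes <- generate_probe_set(n_probes = 2000, seed = 13)
  feats <- probe_features(probes)
  for (feature in c("longest_at_run", "at_fraction")) {
    b <- bin_signal(feats, feature = feature)
    # oracle: naive split + mean using the same assignment rule
    key <- as.character(
      if (feature == "longest_at_run") {
        ifelse(feats$longest_at_run >= 12, ">=12", feats$longest_at_run)
      } else {
        as.character(cut(feats$at_fraction, seq(0, 1, 0.05), right = FALSE,
                         include.lowest = TRUE))
      }
    )
    oracle <- vapply(split(feats$signal, key), mean, 0)
    got <- setNames(b$mean_signal, as.character(b$bin))[names(oracle)]
    expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
    # grand mean conservation over bins
    expect_equal(sum(b$n_probes * b$mean_signal, na.rm = TRUE) / sum(b$n_probes),
                 mean(feats$signal), tolerance = 1e-12)
  }
})

test_that("out-of-range feature values are collected, not dropped", {
  feats <- tibble::tibble(at_fraction = c(0.1, 0.9), signal = c(1, 2))
  b <- bin_signal(feats, feature = "at_fraction", edges = c(0, 0.2, 0.4))
  expect_equal(b$n_probes[b$bin == "out of range"], 1L)
  expect_equal(sum(b$n_probes), 2L)
  expect_error(bin_signal(feats, feature = "at_fraction", edges = c(0.4, 0.2)),
               "increasing")
})

test_that("optimum_bin is a deterministic argmax with lower-label tie-break", {
  s <- tibble::tibble(bin = factor(c("2", "5"), ordered = TRUE),
                      n_probes = c(2L, 2L), mean_signal = c(2, 6))
  expect_equal(optimum_bin(s), "5")
  tie <- tibble::tibble(bin = factor(c("3", "4"), ordered = TRUE),
                        n_probes = c(1L, 1L), mean_signal = c(6, 6))
  expect_equal(optimum_bin(tie), "3")
  one <- tibble::tibble(bin = "7", n_probes = 5L, mean_signal = 1.2)
  expect_equal(optimum_bin(one), "7")
  # empty bins are ignored; all-empty errors
  s$n_probes <- c(0L, 2L)
  expect_equal(optimum_bin(s), "5")
  s$n_probes <- c(0L, 0L)
  expect_error(optimum_bin(s), "empty")
})

test_that("planted optimal tract length is recovered across replicates", {
  hits <- vapply(1:20, function(rep) {
    probes <- generate_probe_set(n_probes = 2000, optimal_tract = 6,
                                 effect_size = 2, noise_sd = 0.5,
                                 seed = 100 + rep)
    optimum_bin(bin_signal(probe_features(probes))) == "6"
  }, logical(1))
  expect_gte(sum(hits), 19L)
})
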