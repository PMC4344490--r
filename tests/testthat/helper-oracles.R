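# Independent brute-force oracles, deliberately naive.

# per-character scan for AT statistics
scan_at_fraction <- function(seq) {
  chars <- toupper(strsplit(seq, "", fixed = TRUE)[[1]])
  at <- 0L; acgt <- 0L
  for (ch in chars) {
    if (ch %in% c("A", "T")) at <- at + 1L
    if (ch %in% c("A", "C", "G", "T")) acgt <- acgt + 1L
  }
  at / acgt
}

scan_longest_at_run <- function(seq) {
  chars <- toupper(strsplit(seq, "", fixed = TRUE)[[1]])
  best <- 0L; cur <- 0L
  for (ch in chars) {
    if (ch %in% c("A", "T")) {
      cur <- cur + 1L
      if (cur > best) best <- cur
    } else cur <- 0L
  }
  best
}

# column scan for pairwise identity
scan_identity <- function(a, b) {
  ca <- toupper(strsplit(a, "", fixed = TRUE)[[1]])
  cb <- toupper(strsplit(b, "", fixed = TRUE)[[1]])
  comp <- 0L; match <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] == "-" && cb[i] == "-") next
    comp <- comp + 1L
    if (ca[i] == cb[i]) match <- match + 1L
  }
  match / comp
}

# all-pairs greedy dereplication applying the same rule naively
greedy_derep_oracle <- function(seqs, threshold) {
  kept <- integer(0)
  for (i in seq_along(seqs)) {
    drop <- FALSE
    for (j in kept) {
      if (scan_identity(seqs[i], seqs[j]) >= threshold) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, i)
  }
  kept
}

# exhaustive two-class partition minimising within-class sum of squares
all_partitions_wss <- function(x) {
  n <- length(x)
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    ss <- sum((x[grp] - mean(x[grp]))^2) + sum((x[!grp] - mean(x[!grp]))^2)
    if (ss < best) best <- ss
  }
  best
}

random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n),
         function(i) paste(sample(alphabet, len, replace = TRUE), collapse = ""),
         character(1))
}

make_msa <- function(...) {
  seqs <- c(...)
  tibble::tibble(seq_id = paste0("s", seq_along(seqs)), aligned_seq = seqs)
}
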