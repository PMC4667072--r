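# Independent oracles and shared fixtures for the suite.

# Minimal semi-global (infix) Levenshtein distance of `guide` against any
# substring of `insert`, by enumeration of substrings + utils::adist.
# A substring of length L is at distance >= |L - m| from an m-mer, so
# restricting to |L - m| <= B is exact whenever the restricted minimum is
# <= B; B grows until that holds. Independent of the package's DP.
oracle_min_dist <- function(insert, guide) {
  n <- nchar(insert)
  m <- nchar(guide)
  B <- 8L
  repeat {
    lo <- max(0, m - B)
    hi <- min(n, m + B)
    lens <- if (lo > hi) 0L else lo:hi
    subs <- unlist(lapply(lens, function(L) {
      if (L == 0) return("")
      starts <- seq_len(n - L + 1)
      substring(insert, starts, starts + L - 1)
    }))
    d <- min(utils::adist(unique(subs), guide))
    if (d <= B || (m - B <= 0 && m + B >= n)) return(d)
    B <- B * 2L
  }
}

# random DNA string
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# all single-deletion variants of a sequence (unique strings)
single_deletions <- function(seq) {
  L <- nchar(seq)
  unique(vapply(seq_len(L), function(p) {
    paste0(substr(seq, 1, p - 1), substr(seq, p + 1, L))
  }, character(1)))
}

# leftmost-equivalent position of deleting position p from seq
oracle_leftmost_pos <- function(seq, p) {
  ch <- substr(seq, p, p)
  while (p > 1 && substr(seq, p - 1, p - 1) == ch) p <- p - 1
  p
}

guides6 <- mimicqc::mir17_92_guides()
endo6 <- mimicqc::example_endogenous()

# small deterministic simulation config for reuse
quick_sim <- function(n = 2000, seed = 11, mix = default_class_mix(),
                      error = 0, ...) {
  sim_config(n_reads = n, class_mix = mix, per_base_error = error,
             rng_seed = seed, ...)
}

# read-level truth-vs-classifier agreement on a simulated library;
# returns a list with raw and ambiguity-aware agreement fractions
sim_agreement <- function(sim, min_frac = NULL) {
  tab <- preprocess_fastq(sim, min_frac = min_frac)
  cls <- classify_inserts(tab, sim$config$guides, sim$config$endogenous)
  tr <- trim_adapter(sim$reads)
  m <- match(tr$insert, cls$insert)
  got <- cls$class[m]
  truth <- sim$truth
  raw <- !is.na(got) & got == truth$class
  ok_alt <- raw | (truth$ambiguous & !is.na(got) &
                     got == truth$alt_class)
  list(raw = mean(raw), aware = mean(ok_alt),
       truth = truth, got = got, classified = cls)
}
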