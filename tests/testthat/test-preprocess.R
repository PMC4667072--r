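adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("trim_adapter removes exact, partial, and absent adapters correctly", {
  # exact full adapter
  r1 <- paste0(strrep("G", 22), adapter)
  out1 <- trim_adapter(r1, adapter)
  expect_equal(out1$insert, strrep("G", 22))
  expect_true(out1$trimmed)
  # 5-nt adapter prefix at the read end
  r2 <- paste0(strrep("G", 70), "TGGAA")
  out2 <- trim_adapter(r2, adapter, min_overlap = 3)
  expect_equal(out2$insert, strrep("G", 70))
  expect_true(out2$trimmed)
  # no adapter-like suffix: untrimmed, flagged
  r3 <- strrep("C", 40)
  out3 <- trim_adapter(r3, adapter)
  expect_equal(out3$insert, r3)
  expect_false(out3$trimmed)
  expect_equal(out3$reason, "no adapter match")
  # empty read rejected with a reason
  out4 <- trim_adapter("", adapter)
  expect_true(out4$rejected)
  expect_equal(out4$reason, "empty read")
})

test_that("trim_adapter matches a brute-force suffix/prefix overlap scan", {
  set.seed(7)
  brute <- function(read, min_overlap, max_err) {
    L <- nchar(read)
    for (o in seq(min(L, nchar(adapter)), min_overlap)) {
      suf <- strsplit(substr(read, L - o + 1, L), "")[[1]]
      pre <- strsplit(substr(adapter, 1, o), "")[[1]]
      if (sum(suf != pre) <= floor(max_err * o + 1e-9)) return(L - o)
    }
    L
  }
  reads <- c(
    replicate(40, paste0(rand_dna(sample(15:60, 1)),
                         substr(adapter, 1, sample(3:21, 1)))),
    replicate(40, rand_dna(sample(15:75, 1))))
  # sprinkle mismatches into some adapters
  got <- trim_adapter(reads, adapter, min_overlap = 3, max_error_rate = 0.1)
  want <- vapply(reads, brute, numeric(1), min_overlap = 3, max_err = 0.1)
  expect_equal(nchar(got$insert), unname(want))
})

test_that("length filter is inclusive at 15 and 80 and reports discards", {
  inserts <- vapply(c(14, 15, 80, 81), rand_dna, character(1))
  kept <- length_filter(inserts)
  expect_equal(nchar(kept), c(15, 80))
  expect_equal(attr(kept, "discards")[["short"]], 1)
  expect_equal(attr(kept, "discards")[["long"]], 1)
  # empty input
  empty <- length_filter(character(0))
  expect_length(empty, 0)
  expect_equal(sum(attr(empty, "discards")), 0)
})

test_that("length filter equals an independent recount on random lengths", {
  set.seed(15)
  lens <- sample(10:85, 1000, replace = TRUE)
  inserts <- vapply(lens, rand_dna, character(1))
  kept <- length_filter(inserts)
  expect_equal(length(kept), sum(lens >= 15 & lens <= 80))
  # idempotence
  again <- length_filter(kept)
  expect_equal(as.character(again), as.character(kept))
  expect_equal(sum(attr(again, "discards")), 0)
})

test_that("contaminant filter removes exact substrings of contaminants or their RC", {
  set.seed(31)
  contaminant <- rand_dna(2000)
  window <- substr(contaminant, 101, 122)
  rc_window <- reverse_complement(substr(contaminant, 500, 530))
  keepme <- rand_dna(22)
  out <- contaminant_filter(c(window, rc_window, keepme),
                            tibble::tibble(name = "rRNA", seq = contaminant))
  expect_equal(as.character(out), keepme)
  expect_equal(attr(out, "removed"), 2L)
})

test_that("contaminant filter agrees with a naive substring scan on random inserts", {
  set.seed(32)
  contaminant <- rand_dna(2000)
  # half random, half planted windows
  planted <- vapply(1:250, function(i) {
    s <- sample(1:(2000 - 25), 1)
    substr(contaminant, s, s + sample(15:25, 1))
  }, character(1))
  inserts <- sample(c(planted, replicate(250, rand_dna(22))))
  naive_hit <- vapply(inserts, function(x) {
    grepl(x, contaminant, fixed = TRUE) ||
      grepl(x, reverse_complement(contaminant), fixed = TRUE)
  }, logical(1))
  out <- contaminant_filter(inserts, contaminant)
  expect_equal(sort(as.character(out)), sort(inserts[!naive_hit]))
})

test_that("abundance filter applies a strict >0.1% rule per unique insert", {
  set.seed(44)
  # 10,000 reads: one species at exactly 0.1% (removed), one at 0.11% (kept)
  filler <- rep(vapply(1:20, function(i) rand_dna(30), character(1)),
                length.out = 10000 - 21)
  at_cut <- rep(rand_dna(25), 10)     # 10/10000 = 0.1% exactly
  above <- rep(rand_dna(26), 11)      # 11/10000 = 0.11%
  tab <- collapse_inserts(c(filler, at_cut, above))
  kept <- abundance_filter(tab, threshold = 0.001)
  expect_true(above[1] %in% kept$insert)
  expect_false(at_cut[1] %in% kept$insert)
  # enumeration oracle
  expect_setequal(kept$insert, tab$insert[tab$count / sum(tab$count) > 0.001])
  # idempotence on the retained rows' fractions
  again <- abundance_filter(kept, threshold = 0.001)
  expect_equal(again$insert, kept$insert)
})

test_that("insert fractions account for all retained reads", {
  sim <- simulate_library(quick_sim(n = 3000, seed = 8))
  tab <- preprocess_fastq(sim, min_frac = NULL)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
  enr <- preprocess_fastq(sim, min_frac = 0.001)
  expect_equal(sum(enr$fraction) + attr(enr, "removed_mass"), 1,
               tolerance = 1e-9)
  expect_true(all(nchar(enr$insert) >= 15 & nchar(enr$insert) <= 80))
})

test_that("read counts are conserved across preprocessing stages", {
  mix <- c(MATURE = 0.5, ENDOGENOUS = 0.2, CONTAMINANT = 0.2,
           HMW_CONCATEMER = 0.1)
  sim <- simulate_library(quick_sim(n = 4000, seed = 23, mix = mix))
  tab <- preprocess_fastq(sim, contaminants = sim$config$contaminants,
                          min_frac = NULL)
  st <- preprocess_stats(tab)
  expect_equal(st$reads_in,
               st$retained + st$discarded_short + st$discarded_long +
                 st$contaminant + st$rejected_empty)
  # contaminant reads were simulated and all removed
  expect_equal(st$contaminant, sum(sim$truth$class == "CONTAMINANT"))
  expect_equal(sum(tab$count), st$retained)
})

test_that("zero-error libraries with full adapters round-trip every insert", {
  sim <- simulate_library(quick_sim(n = 2000, seed = 55))
  tr <- trim_adapter(sim$reads)
  # every simulated insert is recovered exactly
  expect_equal(tr$insert, sim$truth$insert)
  expect_true(all(tr$trimmed | nchar(sim$truth$insert) +
                    nchar(sim$config$adapter3) > 75))
})
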