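mir17 <- guides6$guide[guides6$name == "miR-17"]

test_that("edit_match finds identity and single-deletion placements", {
  h <- edit_match(mir17, c("miR-17" = mir17))
  expect_equal(nrow(h), 1)
  expect_equal(h$dist, 0L)
  expect_equal(c(h$start, h$end), c(1L, nchar(mir17)))
  expect_equal(h$strand, "sense")

  # guide with position-10 base removed: one deletion, position recoverable
  del10 <- paste0(substr(mir17, 1, 9), substr(mir17, 11, nchar(mir17)))
  h2 <- edit_match(del10, c("miR-17" = mir17))
  expect_equal(h2$dist[1], 1L)
  expect_equal(h2$ndel[1], 1L)
  expect_match(h2$ops[1], "^D(9|10):")  # leftmost within the TT homopolymer

  # antisense orientation is recorded
  h3 <- edit_match(reverse_complement(mir17), c("miR-17" = mir17))
  expect_equal(h3$strand[1], "antisense")
  expect_equal(h3$dist[1], 0L)
})

test_that("edit_match minimal distances agree with the substring DP oracle", {
  set.seed(202)
  n_pairs <- 250
  for (i in seq_len(n_pairs)) {
    insert <- rand_dna(sample(15:74, 1))
    guide <- if (i %% 3 == 0) {
      # mutated copies of a real guide embedded or free-floating
      g <- sample(guides6$guide, 1)
      substr(g, 1, min(nchar(g), sample(18:24, 1)))
    } else rand_dna(sample(18:26, 1))
    want <- oracle_min_dist(insert, guide)
    hits <- edit_match(insert, guide, max_edits = 8, both_strands = FALSE)
    if (want > 8) {
      expect_equal(nrow(hits), 0)
    } else {
      expect_equal(min(hits$dist), want,
                   label = sprintf("pair %d (insert %s guide %s)", i,
                                   insert, guide))
    }
  }
})

test_that("edit_match is symmetric under reverse complement", {
  set.seed(203)
  for (i in 1:20) {
    insert <- paste0(rand_dna(10), reverse_complement(mir17), rand_dna(8))
    anti <- edit_match(insert, c(g = mir17))
    anti <- anti[anti$strand == "antisense", ]
    sense_on_rc <- edit_match(reverse_complement(insert), c(g = mir17))
    sense_on_rc <- sense_on_rc[sense_on_rc$strand == "sense", ]
    expect_equal(min(anti$dist), min(sense_on_rc$dist))
    # intervals mirror: start' = n - end + 1
    n <- nchar(insert)
    expect_setequal(n - anti$end + 1, sense_on_rc$start)
  }
})

test_that("all-N inserts yield no hits; N mismatches everything", {
  expect_equal(nrow(edit_match(strrep("N", 30), c(g = mir17))), 0)
  one_n <- paste0(substr(mir17, 1, 11), "N", substr(mir17, 13, nchar(mir17)))
  h <- edit_match(one_n, c(g = mir17))
  expect_equal(min(h$dist), 1L)
})

test_that("classification precedence: exact, antisense, endogenous, trimmed", {
  refs <- guides6
  expect_equal(classify_species(mir17, refs, endo6)$class, "MATURE")
  expect_equal(classify_species(reverse_complement(mir17), refs, endo6)$class,
               "ANTISENSE")
  expect_equal(classify_species(endo6$seq[1], refs, endo6)$class, "ENDOGENOUS")
  # guide minus its two 3'-terminal bases is TRIMMED, not MUTANT_DELETION
  t2 <- classify_species(substr(mir17, 1, nchar(mir17) - 2), refs, endo6)
  expect_equal(t2$class, "TRIMMED")
  expect_match(t2$detail, "trim_3p:2")
  t5 <- classify_species(substr(mir17, 3, nchar(mir17)), refs, endo6)
  expect_equal(t5$class, "TRIMMED")
  expect_match(t5$detail, "trim_5p:2")
})

test_that("every single-deletion variant of every guide is a reconstructable mutant", {
  # note: one variant of miR-19b is string-identical to a variant of miR-19a
  # (deleting C11 vs T11 give the same 22-mer), so reconstruction is checked
  # against the guide the classifier assigned, not the generating one
  for (gi in seq_len(nrow(guides6))) {
    g <- guides6$guide[gi]
    L <- nchar(g)
    for (p in seq_len(L)) {
      variant <- paste0(substr(g, 1, p - 1), substr(g, p + 1, L))
      cls <- classify_species(variant, guides6, endo6)
      expect_equal(cls$class, "MUTANT_DELETION",
                   label = paste(guides6$name[gi], "del", p))
      assigned <- guides6$guide[guides6$name == cls$guide]
      # leftmost convention: the smallest position in the assigned guide
      # whose deletion yields this variant
      valid <- vapply(seq_len(nchar(assigned)), function(q) {
        paste0(substr(assigned, 1, q - 1),
               substr(assigned, q + 1, nchar(assigned))) == variant
      }, logical(1))
      expect_equal(cls$del_pos, min(which(valid)))
      # re-inserting the deleted base at the recorded position reconstructs
      rebuilt <- paste0(substr(variant, 1, cls$del_pos - 1), cls$del_base,
                        substr(variant, cls$del_pos, L - 1))
      expect_equal(rebuilt, assigned)
    }
  }
})

test_that("HMW decomposition calls dimers, tails, poly(A) and hybrids", {
  refs <- guides6
  p <- classify_params()
  # perfect dimer
  dimer <- strrep(mir17, 2)
  d <- decompose_hmw(dimer, refs, endo6, p)
  expect_equal(d$subclass, "HMW_CONCATEMER")
  expect_equal(d$units, 2L)
  expect_equal(nchar(d$tail5), 0)
  expect_equal(nchar(d$tail3), 0)
  # mixed-guide dimer
  mixed <- paste0(mir17, guides6$guide[guides6$name == "miR-92"])
  expect_equal(decompose_hmw(mixed, refs, endo6, p)$subclass,
               "HMW_CONCATEMER")
  # constructed 5' tail
  t5 <- decompose_hmw(paste0("ACGT", mir17), refs, endo6, p)
  expect_equal(t5$subclass, "HMW_5TAIL")
  expect_equal(t5$tail5, "ACGT")
  # poly(A) takes precedence over generic 3' tailing
  pa <- decompose_hmw(paste0(mir17, "AAAAAA"), refs, endo6, p)
  expect_equal(pa$subclass, "HMW_POLYA")
  # non-homogeneous 3' tail stays 3TAIL
  t3 <- decompose_hmw(paste0(mir17, "GAAAA"), refs, endo6, p)
  expect_equal(t3$subclass, "HMW_3TAIL")
  expect_equal(t3$tail3, "GAAAA")
  # hybrid with an exact endogenous unit
  hy <- decompose_hmw(paste0(mir17, endo6$seq[1]), refs, endo6, p)
  expect_equal(hy$subclass, "HMW_HYBRID")
  # out-of-window precondition
  expect_error(decompose_hmw(rand_dna(80), refs, endo6, p), "outside")
})

test_that("classify_species routes HMW inserts through decomposition", {
  cls <- classify_species(strrep(mir17, 2), guides6, endo6)
  expect_equal(cls$class, "HMW_CONCATEMER")
  expect_equal(cls$units, 2L)
  cls2 <- classify_species(paste0("ACGTT", mir17), guides6, endo6)
  expect_equal(cls2$class, "HMW_5TAIL")
  expect_equal(cls2$tail5, "ACGTT")
  # random sequence in the window is UNASSIGNED
  set.seed(9)
  expect_equal(classify_species(rand_dna(40), guides6, endo6)$class,
               "UNASSIGNED")
})

test_that("simulated HMW species recover their truth subclass at zero error", {
  mix <- c(HMW_CONCATEMER = 0.3, HMW_5TAIL = 0.2, HMW_3TAIL = 0.2,
           HMW_POLYA = 0.15, HMW_HYBRID = 0.15)
  sim <- simulate_library(quick_sim(n = 2000, seed = 61, mix = mix))
  res <- sim_agreement(sim)
  expect_gte(res$aware, 0.95)
  # every raw disagreement is a flagged ambiguous construction
  dis <- which(!(res$got == res$truth$class))
  expect_true(all(res$truth$ambiguous[dis]))
})

test_that("length histogram equals a brute-force recount", {
  sim <- simulate_library(quick_sim(n = 3000, seed = 37))
  tab <- preprocess_fastq(sim, min_frac = NULL)
  cls <- classify_inserts(tab, guides6, endo6)
  hist <- length_histogram(cls, lo = 25, hi = 74)
  # single species check
  one <- tibble::tibble(insert = strrep(mir17, 2), count = 7,
                        class = "HMW_CONCATEMER", guide = "miR-17")
  h1 <- length_histogram(one)
  expect_equal(h1$reads[h1$length == 48], 7)
  expect_equal(sum(h1$reads), 7)
  # recount oracle over the classified table
  recount <- cls |>
    dplyr::mutate(len = nchar(insert)) |>
    dplyr::filter(len >= 25, len <= 74)
  expect_equal(sum(hist$reads), sum(recount$count))
  for (L in unique(recount$len)) {
    expect_equal(sum(hist$reads[hist$length == L]),
                 sum(recount$count[recount$len == L]))
  }
  # empty input: all-zero histogram over the window
  h0 <- length_histogram(cls[0, ])
  expect_true(all(h0$reads == 0))
  expect_equal(sort(unique(h0$length)), 25:74)
})

test_that("windowed HMW fold change is a ratio of library-normalized rates", {
  mk <- function(insert, count, class, guide) {
    tibble::tibble(insert = insert, count = count, class = class,
                   guide = guide)
  }
  sample_tbl <- mk(paste0(mir17, strrep("G", 10)), 100, "HMW_3TAIL", "miR-17")
  control_tbl <- mk(paste0(mir17, strrep("G", 10)), 10, "HMW_3TAIL", "miR-17")
  fc <- hmw_fold_change(sample_tbl, control_tbl,
                        sample_total = 1e5, control_total = 1e5)
  expect_equal(fc$fold_change$fold_change[fc$fold_change$guide == "miR-17"],
               10)
  # 61-nt species fall outside the 30-60 window
  sample_out <- mk(paste0(mir17, strrep("G", 37)), 100, "HMW_3TAIL", "miR-17")
  fc2 <- hmw_fold_change(sample_out, control_tbl,
                         sample_total = 1e5, control_total = 1e5)
  row <- fc2$fold_change[fc2$fold_change$guide == "miR-17", ]
  expect_equal(row$sample_reads, 0)
  # zero control count: Inf sentinel, no pseudo-count
  fc3 <- hmw_fold_change(sample_tbl, control_tbl[0, ],
                         sample_total = 1e5, control_total = 1e5)
  expect_equal(fc3$fold_change$fold_change[1], Inf)
  # composition triple normalizes to 1
  comp_tbl <- dplyr::bind_rows(
    mk(strrep(mir17, 2), 30, "HMW_CONCATEMER", "miR-17"),
    mk(paste0(strrep("C", 8), mir17), 30, "HMW_5TAIL", "miR-17"),
    mk(paste0(mir17, strrep("G", 8)), 40, "HMW_3TAIL", "miR-17"))
  fc4 <- hmw_fold_change(comp_tbl, comp_tbl,
                         sample_total = 1000, control_total = 1000)
  comp <- fc4$composition[fc4$composition$library == "sample", ]
  expect_equal(comp$proportion[comp$class == "HMW_CONCATEMER"], 0.30)
  expect_equal(comp$proportion[comp$class == "HMW_5TAIL"], 0.30)
  expect_equal(comp$proportion[comp$class == "HMW_3TAIL"], 0.40)
  expect_equal(sum(comp$proportion), 1)
})

test_that("a non-transfected library has no mimic artifacts above threshold", {
  mix <- c(ENDOGENOUS = 0.97, CONTAMINANT = 0.03)
  sim <- simulate_library(quick_sim(n = 5000, seed = 71, mix = mix))
  tab <- preprocess_fastq(sim, contaminants = sim$config$contaminants,
                          min_frac = 0.001)
  cls <- classify_inserts(tab, guides6, endo6)
  mimic_classes <- c("MATURE", "ANTISENSE", "MUTANT_DELETION", "TRIMMED",
                     grep("^HMW_", species_classes(), value = TRUE))
  expect_false(any(cls$class %in% mimic_classes))
  expect_true(all(cls$class == "ENDOGENOUS"))
})
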