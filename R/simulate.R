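#' Default class mixture for simulated mimic-transfected libraries
#'
#' Proportions emulate a mimic-transfected small-RNA library: the exact guide
#' dominates, the unnatural antisense passenger is prominent, mutant /
#' trimmed forms and the high molecular weight (HMW) artifact subclasses are
#' minor but well represented, on top of an endogenous miRNA background.
#'
#' @return Named numeric vector over the truth label set, summing to 1.
#' @export
default_class_mix <- function() {
  c(MATURE = 0.40, TRIMMED = 0.03, MUTANT_DELETION = 0.05, ANTISENSE = 0.12,
    HMW_CONCATEMER = 0.08, HMW_5TAIL = 0.06, HMW_3TAIL = 0.08,
    HMW_POLYA = 0.04, HMW_HYBRID = 0.04, ENDOGENOUS = 0.10)
}

#' Simulation configuration
#'
#' Bundles everything the library simulator needs: the class mixture, the
#' mimic guide set, endogenous and contaminant backgrounds, the 3' adapter,
#' read geometry, the per-base substitution error rate, and the tail-length
#' law for 5'/3' tailing.
#'
#' @param n_reads Number of reads to emit.
#' @param class_mix Named proportions over truth labels (must sum to 1).
#' @param guides Mimic reference tibble (see [mimic_reference_set()]).
#' @param endogenous Tibble `name`,`seq` of endogenous miRNAs.
#' @param contaminants Tibble `name`,`seq` of contaminant sequences (emitted
#'   verbatim when `CONTAMINANT` is in the mixture).
#' @param adapter3 3' adapter, DNA space. The default is the small-RNA
#'   3' adapter left after removing the App/ddC chemistry decorations.
#' @param read_length Fixed sequencer read length (nt).
#' @param per_base_error Per-base substitution error probability, in `[0, 1)`.
#' @param tail_lengths Integer support of the non-templated tail-length law
#'   (sampled uniformly). Default 3..25 keeps tailed species inside the
#'   25--74 nt HMW window for ~22 nt guides.
#' @param polya_min Minimum poly(A) run for `HMW_POLYA` (nt).
#' @param deletion_positions `"uniform"` (internal positions 2..L-1) or an
#'   integer vector of allowed 1-based guide positions.
#' @param concatemer_units Integer vector of unit counts to sample for
#'   concatemers.
#' @param rng_seed Integer seed; identical configs give byte-identical output.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_reads = 10000,
                       class_mix = default_class_mix(),
                       guides = mir17_92_guides(),
                       endogenous = example_endogenous(),
                       contaminants = NULL,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       read_length = 75,
                       per_base_error = 0,
                       tail_lengths = 3:25,
                       polya_min = 5,
                       deletion_positions = "uniform",
                       concatemer_units = 2:3,
                       rng_seed = 1L) {
  if (is.null(contaminants)) {
    path <- system.file("extdata", "contaminants_synthetic.fasta",
                        package = "mimicqc")
    contaminants <- if (nzchar(path)) read_fasta_tbl(path) else
      tibble::tibble(name = character(), seq = character())
  }
  cfg <- list(n_reads = as.integer(n_reads), class_mix = class_mix,
              guides = guides, endogenous = endogenous,
              contaminants = contaminants, adapter3 = dna_space(adapter3),
              read_length = as.integer(read_length),
              per_base_error = per_base_error,
              tail_lengths = as.integer(tail_lengths),
              polya_min = as.integer(polya_min),
              deletion_positions = deletion_positions,
              concatemer_units = as.integer(concatemer_units),
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  mix <- cfg$class_mix
  if (is.null(names(mix)) || any(!nzchar(names(mix))))
    stop("class_mix must be a named vector")
  unknown <- setdiff(names(mix), species_classes(truth = TRUE))
  if (length(unknown) > 0)
    stop("unknown class label(s) in class_mix: ", paste(unknown, collapse = ", "))
  if (any(mix < 0)) stop("class_mix proportions must be non-negative")
  if (abs(sum(mix) - 1) > 1e-9) stop("class_mix must sum to 1 (got ", sum(mix), ")")
  if (cfg$per_base_error < 0 || cfg$per_base_error >= 1)
    stop("per_base_error must be in [0, 1)")
  if (cfg$read_length < 15) stop("read_length must be >= 15")
  if (!nzchar(cfg$adapter3)) stop("adapter3 must be non-empty")
  mimic_classes <- c("MATURE", "TRIMMED", "MUTANT_DELETION", "ANTISENSE",
                     "HMW_CONCATEMER", "HMW_5TAIL", "HMW_3TAIL", "HMW_POLYA",
                     "HMW_HYBRID")
  if (any(mix[intersect(names(mix), mimic_classes)] > 0) &&
      (is.null(cfg$guides) || nrow(cfg$guides) == 0))
    stop("mimic-derived classes requested but guide list is empty")
  if (isTRUE(mix["HMW_HYBRID"] > 0) && nrow(cfg$endogenous) == 0)
    stop("HMW_HYBRID requested but endogenous list is empty")
  if (isTRUE(mix["ENDOGENOUS"] > 0) && nrow(cfg$endogenous) == 0)
    stop("ENDOGENOUS requested but endogenous list is empty")
  if (isTRUE(mix["CONTAMINANT"] > 0) && nrow(cfg$contaminants) == 0)
    stop("CONTAMINANT requested but contaminant list is empty")
  if (any(grepl("[^ACGT]", cfg$guides$guide)))
    stop("guide sequences must be over {A,C,G,T}")
  invisible(cfg)
}

# leftmost-equivalent deletion position: start of the homopolymer run
# containing position p of `seq`
leftmost_del_pos <- function(seq, p) {
  ch <- substr(seq, p, p)
  while (p > 1 && substr(seq, p - 1, p - 1) == ch) p <- p - 1
  p
}

random_tail <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# A non-templated tail must not itself contain a guide unit within the
# classifier's edit radius, or the construction would genuinely be a
# concatemer and the truth label would be wrong. Tails shorter than the
# shortest guide minus the radius cannot host a unit and are always clean.
tail_has_guide_unit <- function(tail, guides, max_edits = 5) {
  if (nchar(tail) < min(nchar(guides$guide)) - max_edits) return(FALSE)
  for (g in guides$guide) {
    if (cpp_semiglobal_min(tail, g) <= max_edits) return(TRUE)
  }
  FALSE
}

sample_clean_tail <- function(len, guides, polya_min = NULL) {
  repeat {
    tail <- random_tail(len)
    if (!is.null(polya_min) && len >= polya_min && grepl("^A+$", tail)) next
    if (!tail_has_guide_unit(tail, guides)) return(tail)
  }
}

#' Draw insert species with truth labels
#'
#' Realizes the artifact taxonomy generatively: class counts are drawn
#' multinomially from `class_mix` (classes in sorted-name order -- the seed
#' policy tests rely on), then each class is constructed from the guide /
#' endogenous / contaminant sets. Truth rows flag deliberately ambiguous
#' constructions (1-base end-trims, which are string-identical to terminal
#' single deletions; tailed species falling outside the 25--74 nt HMW window)
#' together with the alternative label the classifier may legitimately assign.
#'
#' Uses the current RNG state; [simulate_library()] seeds it from the config.
#'
#' @param config A [sim_config()].
#' @return Tibble with columns `insert`, `class`, `source`, `tail5`, `tail3`,
#'   `del_pos`, `del_base`, `units`, `ambiguous`, `alt_class`.
#' @export
simulate_species <- function(config) {
  validate_sim_config(config)
  mix <- config$class_mix[order(names(config$class_mix))]
  counts <- stats::rmultinom(1, config$n_reads, mix)[, 1]
  guides <- config$guides
  rows <- vector("list", sum(counts))
  k <- 0L
  emit <- function(insert, class, source, tail5 = "", tail3 = "",
                   del_pos = NA_integer_, del_base = NA_character_,
                   units = NA_integer_, ambiguous = FALSE,
                   alt_class = NA_character_) {
    k <<- k + 1L
    rows[[k]] <<- tibble::tibble(
      insert = insert, class = class, source = source, tail5 = tail5,
      tail3 = tail3, del_pos = del_pos, del_base = del_base, units = units,
      ambiguous = ambiguous, alt_class = alt_class)
  }
  for (cls in names(mix)) {
    n <- counts[[cls]]
    if (n == 0) next
    for (i in seq_len(n)) {
      switch(cls,
        MATURE = {
          g <- guides[sample.int(nrow(guides), 1), ]
          emit(g$guide, cls, g$name)
        },
        TRIMMED = {
          g <- guides[sample.int(nrow(guides), 1), ]
          ktrim <- sample(1:3, 1)
          end5 <- sample(c(TRUE, FALSE), 1)
          L <- nchar(g$guide)
          ins <- if (end5) substr(g$guide, ktrim + 1, L) else
            substr(g$guide, 1, L - ktrim)
          emit(ins, cls, g$name, ambiguous = ktrim == 1,
               alt_class = if (ktrim == 1) "MUTANT_DELETION" else NA_character_)
        },
        MUTANT_DELETION = {
          g <- guides[sample.int(nrow(guides), 1), ]
          L <- nchar(g$guide)
          pos_pool <- if (identical(config$deletion_positions, "uniform"))
            2:(L - 1) else config$deletion_positions
          p <- if (length(pos_pool) == 1) pos_pool else sample(pos_pool, 1)
          ins <- paste0(substr(g$guide, 1, p - 1), substr(g$guide, p + 1, L))
          canon <- leftmost_del_pos(g$guide, p)
          emit(ins, cls, g$name, del_pos = canon,
               del_base = substr(g$guide, p, p))
        },
        ANTISENSE = {
          g <- guides[sample.int(nrow(guides), 1), ]
          emit(rc(g$guide), cls, g$name)
        },
        HMW_CONCATEMER = {
          u <- if (length(config$concatemer_units) == 1)
            config$concatemer_units else sample(config$concatemer_units, 1)
          gi <- sample.int(nrow(guides), u, replace = TRUE)
          emit(paste(guides$guide[gi], collapse = ""), cls,
               paste(guides$name[gi], collapse = "+"), units = u)
        },
        HMW_5TAIL = {
          g <- guides[sample.int(nrow(guides), 1), ]
          tl <- if (length(config$tail_lengths) == 1) config$tail_lengths else
            sample(config$tail_lengths, 1)
          tail <- sample_clean_tail(tl, guides)
          ins <- paste0(tail, g$guide)
          out <- nchar(ins) < 25 || nchar(ins) > 74
          emit(ins, cls, g$name, tail5 = tail, units = 1L,
               ambiguous = out,
               alt_class = if (out) "UNASSIGNED" else NA_character_)
        },
        HMW_3TAIL = {
          g <- guides[sample.int(nrow(guides), 1), ]
          tl <- if (length(config$tail_lengths) == 1) config$tail_lengths else
            sample(config$tail_lengths, 1)
          # reject all-A tails >= polya_min (those ARE poly(A) by definition)
          # and tails containing a guide unit (those would be concatemers)
          tail <- sample_clean_tail(tl, guides, polya_min = config$polya_min)
          ins <- paste0(g$guide, tail)
          out <- nchar(ins) < 25 || nchar(ins) > 74
          emit(ins, cls, g$name, tail3 = tail, units = 1L,
               ambiguous = out,
               alt_class = if (out) "UNASSIGNED" else NA_character_)
        },
        HMW_POLYA = {
          g <- guides[sample.int(nrow(guides), 1), ]
          tl <- sample(config$polya_min:max(config$tail_lengths,
                                            config$polya_min), 1)
          tail <- strrep("A", tl)
          emit(paste0(g$guide, tail), cls, g$name, tail3 = tail, units = 1L)
        },
        HMW_HYBRID = {
          g <- guides[sample.int(nrow(guides), 1), ]
          e <- config$endogenous[sample.int(nrow(config$endogenous), 1), ]
          mimic_first <- sample(c(TRUE, FALSE), 1)
          ins <- if (mimic_first) paste0(g$guide, e$seq) else
            paste0(e$seq, g$guide)
          emit(ins, cls, paste(g$name, e$name, sep = "+"), units = 2L)
        },
        ENDOGENOUS = {
          e <- config$endogenous[sample.int(nrow(config$endogenous), 1), ]
          emit(e$seq, cls, e$name)
        },
        CONTAMINANT = {
          ct <- config$contaminants[sample.int(nrow(config$contaminants), 1), ]
          emit(ct$seq, cls, ct$name)
        },
        UNASSIGNED = {
          emit(random_tail(sample(20:40, 1)), cls, "random")
        })
    }
  }
  out <- dplyr::bind_rows(rows[seq_len(k)])
  # shuffle so file order is not class-blocked
  out[sample.int(nrow(out)), ]
}

#' Ligate the 3' adapter and sequence
#'
#' Each read is the insert followed by the 3' adapter, truncated to
#' `read_length`; inserts at or beyond the read length yield an insert-prefix
#' read with no adapter. Reads shorter than `read_length` are not padded, so
#' adapter trimming is exercised on both full and partial adapters. Per-base
#' substitution errors are applied at `per_base_error`; qualities are constant
#' Phred 30.
#'
#' @param species Tibble from [simulate_species()] (columns `insert`, truth).
#' @param config A [sim_config()].
#' @return List with `reads` (tibble `read_id`, `seq`, `qual`) and `truth`
#'   (the species tibble keyed by `read_id`).
#' @export
ligate_and_sequence <- function(species, config) {
  if (!nzchar(config$adapter3)) stop("adapter3 must be non-empty")
  n <- nrow(species)
  ids <- sprintf("read_%06d", seq_len(n))
  reads <- substr(paste0(species$insert, config$adapter3), 1,
                  config$read_length)
  if (config$per_base_error > 0) {
    alphabet <- c("A", "C", "G", "T")
    reads <- vapply(reads, function(r) {
      ch <- strsplit(r, "", fixed = TRUE)[[1]]
      hit <- stats::runif(length(ch)) < config$per_base_error
      if (any(hit)) {
        ch[hit] <- vapply(ch[hit],
                          function(b) sample(setdiff(alphabet, b), 1),
                          character(1))
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  truth <- dplyr::bind_cols(tibble::tibble(read_id = ids), species)
  list(reads = tibble::tibble(read_id = ids, seq = reads,
                              qual = strrep("?", nchar(reads))),
       truth = truth)
}

#' Simulate a complete small-RNA library
#'
#' Seeds the RNG from `config$rng_seed`, draws species, ligates and sequences.
#' Identical configs (including seed) give byte-identical FASTQ and truth
#' tables.
#'
#' @param config A [sim_config()].
#' @return A `mimic_sim` list: `reads`, `truth`, `config`.
#' @export
simulate_library <- function(config) {
  out <- withr::with_seed(config$rng_seed, {
    species <- simulate_species(config)
    ligate_and_sequence(species, config)
  })
  structure(c(out, list(config = config)), class = "mimic_sim")
}

#' @export
print.mimic_sim <- function(x, ...) {
  cat("<mimic_sim> ", nrow(x$reads), " reads, ",
      length(unique(x$truth$class)), " truth classes, seed ",
      x$config$rng_seed, "\n", sep = "")
  print(dplyr::count(x$truth, .data$class, sort = TRUE), ...)
  invisible(x)
}

#' Write simulated reads as FASTQ (+ truth TSV)
#'
#' @param sim A `mimic_sim` from [simulate_library()].
#' @param fastq_path Output FASTQ path.
#' @param truth_path Optional truth TSV path.
#' @return `fastq_path`, invisibly.
#' @export
write_simulated_library <- function(sim, fastq_path, truth_path = NULL) {
  dna <- Biostrings::DNAStringSet(sim$reads$seq)
  names(dna) <- sim$reads$read_id
  Biostrings::writeXStringSet(dna, fastq_path, format = "fastq",
                              qualities = Biostrings::BStringSet(sim$reads$qual))
  if (!is.null(truth_path)) {
    write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fastq_path)
}

#' Read a FASTQ file into a reads tibble
#'
#' @param path FASTQ (Phred+33) file.
#' @return Tibble with columns `read_id`, `seq`, `qual`.
#' @export
read_fastq_tbl <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  tryCatch({
    ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
    tibble::tibble(
      read_id = sub("\\s.*$", "", names(ss)),
      seq = unname(as.character(ss)),
      qual = unname(as.character(S4Vectors::mcols(ss)$qualities))
    )
  }, error = function(e) {
    stop("malformed FASTQ '", path, "': ", conditionMessage(e))
  })
}
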