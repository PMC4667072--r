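#' Classifier parameters
#'
#' @param max_edits Maximum unit-cost Levenshtein distance for a guide
#'   placement (substitutions + insertions + deletions).
#' @param min_tail Minimum unmatched flank length (nt) to call a 5'/3' tail.
#' @param polya_min Minimum all-A 3' flank (nt) to call polyadenylation.
#' @param hmw_window Inclusive length window (nt) in which high molecular
#'   weight decomposition applies.
#' @return A named list of parameters.
#' @export
classify_params <- function(max_edits = 5, min_tail = 3, polya_min = 5,
                            hmw_window = c(25, 74)) {
  stopifnot(max_edits >= 0, min_tail >= 1, polya_min >= 1,
            length(hmw_window) == 2, hmw_window[1] <= hmw_window[2])
  list(max_edits = as.integer(max_edits), min_tail = as.integer(min_tail),
       polya_min = as.integer(polya_min),
       hmw_window = as.integer(hmw_window))
}

# greedy reduction of overlapping placements to locally optimal hits:
# lowest distance, then leftmost start, then longest span
reduce_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits <- hits[order(hits$dist, hits$start, -(hits$end - hits$start)), ]
  sel <- logical(nrow(hits))
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- hits$end[i]
    if (nrow(occupied) == 0 ||
        all(e < occupied[, 1] | s > occupied[, 2])) {
      sel[i] <- TRUE
      occupied <- rbind(occupied, c(s, e))
    }
  }
  out <- hits[sel, ]
  out[order(out$start), ]
}

#' Approximate placements of a guide within an insert
#'
#' Finds every placement of the guide (and, if `both_strands`, its reverse
#' complement) inside the insert with unit-cost Levenshtein distance at most
#' `max_edits`, then reduces overlapping placements to locally optimal,
#' non-overlapping hits (lowest distance, then leftmost, then longest).
#' With `allow_indels = FALSE` the search degenerates to a Hamming scan.
#' `N` bases mismatch everything.
#'
#' @param insert Insert sequence (DNA space).
#' @param guide Guide sequence; a named character scalar names the hits.
#' @param max_edits Maximum edit distance (default 5).
#' @param allow_indels Permit insertions/deletions (default `TRUE`).
#' @param both_strands Also search the reverse complement (default `TRUE`).
#' @return Tibble of hits: `guide`, `strand` (`"sense"`/`"antisense"`),
#'   `start`, `end` (1-based inclusive insert coordinates), `dist`, `nsub`,
#'   `ndel`, `nins`, `ops` (edit operations in guide coordinates).
#' @examples
#' g <- "CAAAGTGCTTACAGTGCAGGTAGT"
#' edit_match(g, c("miR-17" = g))
#' @export
edit_match <- function(insert, guide, max_edits = 5, allow_indels = TRUE,
                       both_strands = TRUE) {
  stopifnot(length(insert) == 1, length(guide) == 1, max_edits >= 0)
  gname <- if (!is.null(names(guide))) names(guide) else "guide"
  guide <- dna_space(unname(guide))
  insert <- dna_space(insert)
  if (!nzchar(guide)) stop("guide must be non-empty")
  one_strand <- function(g, strand) {
    raw <- if (allow_indels) {
      cpp_semiglobal_hits(insert, g, as.integer(max_edits))
    } else {
      hamming_scan(insert, g, max_edits)
    }
    if (nrow(raw) == 0) return(NULL)
    tibble::tibble(guide = gname, strand = strand,
                   start = raw$start, end = raw$end, dist = raw$dist,
                   nsub = raw$nsub, ndel = raw$ndel, nins = raw$nins,
                   ops = raw$ops)
  }
  hits <- dplyr::bind_rows(
    one_strand(guide, "sense"),
    if (both_strands) one_strand(rc(guide), "antisense"))
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble::tibble(guide = character(), strand = character(),
                          start = integer(), end = integer(),
                          dist = integer(), nsub = integer(),
                          ndel = integer(), nins = integer(),
                          ops = character()))
  }
  reduce_hits(hits)
}

# fixed-length sliding-window mismatch scan (no indels)
hamming_scan <- function(insert, guide, max_edits) {
  n <- nchar(insert); m <- nchar(guide)
  if (n < m) {
    return(data.frame(start = integer(), end = integer(), dist = integer(),
                      nsub = integer(), ndel = integer(), nins = integer(),
                      ops = character()))
  }
  ic <- strsplit(insert, "", fixed = TRUE)[[1]]
  gc <- strsplit(guide, "", fixed = TRUE)[[1]]
  res <- lapply(seq_len(n - m + 1), function(s) {
    win <- ic[s:(s + m - 1)]
    mm <- which(win != gc | win == "N" | gc == "N")
    if (length(mm) > max_edits) return(NULL)
    data.frame(start = s, end = s + m - 1, dist = length(mm),
               nsub = length(mm), ndel = 0L, nins = 0L,
               ops = paste(sprintf("S%d:%s", mm, win[mm]), collapse = ";"))
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(), dist = integer(),
                      nsub = integer(), ndel = integer(), nins = integer(),
                      ops = character()))
  }
  out
}

# If `insert` can be obtained from `guide` by deletions only, return the
# leftmost-equivalent deleted guide positions (rightmost subsequence
# embedding yields leftmost deletions); otherwise NULL.
deletion_positions <- function(insert, guide) {
  n <- nchar(insert); L <- nchar(guide)
  if (n >= L) return(NULL)
  ic <- strsplit(insert, "", fixed = TRUE)[[1]]
  gc <- strsplit(guide, "", fixed = TRUE)[[1]]
  keep <- integer(n)
  j <- L
  for (i in rev(seq_len(n))) {
    while (j >= 1 && gc[j] != ic[i]) j <- j - 1
    if (j < 1) return(NULL)
    keep[i] <- j
    j <- j - 1
  }
  setdiff(seq_len(L), keep)
}

#' Classify one insert against the artifact taxonomy
#'
#' Precedence (exact classes before approximate, single-unit before
#' multi-unit): exact guide -> `MATURE`; exact reverse complement ->
#' `ANTISENSE`; exact endogenous -> `ENDOGENOUS`; deletion-only variant of a
#' guide -> `MUTANT_DELETION` (one or more internal/terminal deletions;
#' exactly one base removed is always a mutant) or `TRIMMED` (2--3 bases off
#' the ends); length within the HMW window and containing guide units ->
#' high molecular weight subclass via [decompose_hmw()]; otherwise
#' `UNASSIGNED`. Deletion positions are reported leftmost within homopolymer
#' runs; the recorded deleted bases reconstruct the guide.
#'
#' @param insert Insert sequence (DNA space).
#' @param refset Mimic reference tibble ([mimic_reference_set()]).
#' @param endogenous Tibble `name`,`seq` of endogenous miRNAs.
#' @param params [classify_params()].
#' @return One-row tibble: `insert`, `class`, `guide` (primary source),
#'   `source`, `dist`, `del_pos`, `del_base`, `tail5`, `tail3`, `units`,
#'   `detail`.
#' @export
classify_species <- function(insert, refset, endogenous = NULL,
                             params = classify_params()) {
  insert <- dna_space(insert)
  row <- function(class, guide = NA_character_, source = guide, dist = 0L,
                  del_pos = NA_integer_, del_base = NA_character_,
                  tail5 = "", tail3 = "", units = NA_integer_,
                  detail = NA_character_) {
    tibble::tibble(insert = insert, class = class, guide = guide,
                   source = source, dist = as.integer(dist),
                   del_pos = del_pos, del_base = del_base,
                   tail5 = tail5, tail3 = tail3,
                   units = as.integer(units), detail = detail)
  }
  i <- match(insert, refset$guide)
  if (!is.na(i)) return(row("MATURE", refset$name[i], units = 1L))
  i <- match(insert, rc(refset$guide))
  if (!is.na(i)) return(row("ANTISENSE", refset$name[i], units = 1L))
  if (!is.null(endogenous) && nrow(endogenous) > 0) {
    i <- match(insert, endogenous$seq)
    if (!is.na(i)) {
      return(row("ENDOGENOUS", guide = NA_character_,
                 source = endogenous$name[i]))
    }
  }
  # deletion-only variants of a guide (insert strictly shorter)
  best <- NULL
  for (i in seq_len(nrow(refset))) {
    g <- refset$guide[i]
    d <- nchar(g) - nchar(insert)
    if (d < 1 || d > params$max_edits) next
    dels <- deletion_positions(insert, g)
    if (is.null(dels)) next
    if (is.null(best) || d < best$d) best <- list(i = i, d = d, dels = dels)
  }
  if (!is.null(best)) {
    g <- refset$guide[best$i]
    gname <- refset$name[best$i]
    L <- nchar(g)
    d <- best$d
    if (d >= 2 && d <= 3) {
      for (a in 0:d) {
        b <- d - a
        if (insert == substr(g, a + 1, L - b)) {
          side <- if (a > 0 && b > 0) "both" else if (a > 0) "5p" else "3p"
          return(row("TRIMMED", gname, dist = d,
                     detail = sprintf("trim_%s:%d", side, d)))
        }
      }
    }
    dels <- best$dels
    return(row("MUTANT_DELETION", gname, dist = d,
               del_pos = dels[1],
               del_base = paste(substring(g, dels, dels), collapse = ""),
               detail = paste0("del@", paste(dels, collapse = ","))))
  }
  n <- nchar(insert)
  if (n >= params$hmw_window[1] && n <= params$hmw_window[2]) {
    hm <- decompose_hmw(insert, refset, endogenous, params)
    if (!is.na(hm$subclass)) {
      return(row(hm$subclass, hm$guide, source = hm$source,
                 dist = hm$dist, tail5 = hm$tail5, tail3 = hm$tail3,
                 units = hm$units, detail = hm$detail))
    }
  }
  row("UNASSIGNED", guide = NA_character_, source = NA_character_)
}

#' Decompose a high molecular weight insert
#'
#' Greedily places maximal non-overlapping guide units (via [edit_match()])
#' and exact endogenous-miRNA units, then calls the subclass: two or more
#' mimic units -> `HMW_CONCATEMER`; one mimic unit plus an exact endogenous
#' unit -> `HMW_HYBRID`; one mimic unit with an unmatched flank at least
#' `min_tail` nt -> `HMW_5TAIL` / `HMW_3TAIL`, except that an all-A 3' flank
#' of at least `polya_min` nt is `HMW_POLYA` (polyadenylation takes precedence
#' over generic 3' tailing). Flanks are recorded verbatim.
#'
#' @param insert Insert of length within the HMW window (25--74 nt default).
#' @param refset Mimic reference tibble.
#' @param endogenous Tibble `name`,`seq` (exact matches only; approximate
#'   endogenous units would be indistinguishable from mimic mutants).
#' @param params [classify_params()].
#' @return List: `subclass` (NA when no mimic unit is found), `guide`,
#'   `source`, `units`, `tail5`, `tail3`, `dist`, `detail`, `hits` (tibble of
#'   selected unit placements).
#' @export
decompose_hmw <- function(insert, refset, endogenous = NULL,
                          params = classify_params()) {
  insert <- dna_space(insert)
  n <- nchar(insert)
  if (n < params$hmw_window[1] || n > params$hmw_window[2]) {
    stop("decompose_hmw: insert length ", n, " outside HMW window [",
         params$hmw_window[1], ", ", params$hmw_window[2], "]")
  }
  hits <- purrr::map_dfr(seq_len(nrow(refset)), function(i) {
    h <- edit_match(insert, stats::setNames(refset$guide[i], refset$name[i]),
                    max_edits = params$max_edits)
    if (nrow(h) > 0) h$unit_type <- "mimic"
    h
  })
  if (!is.null(endogenous) && nrow(endogenous) > 0) {
    for (i in seq_len(nrow(endogenous))) {
      at <- gregexpr(endogenous$seq[i], insert, fixed = TRUE)[[1]]
      if (at[1] == -1) next
      hits <- dplyr::bind_rows(hits, tibble::tibble(
        guide = endogenous$name[i], strand = "sense", start = as.integer(at),
        end = as.integer(at) + nchar(endogenous$seq[i]) - 1L,
        dist = 0L, nsub = 0L, ndel = 0L, nins = 0L, ops = "",
        unit_type = "endogenous"))
    }
  }
  none <- list(subclass = NA_character_, guide = NA_character_,
               source = NA_character_, units = NA_integer_, tail5 = "",
               tail3 = "", dist = NA_integer_, detail = NA_character_,
               hits = hits[0, ])
  if (nrow(hits) == 0) return(none)
  units <- reduce_hits(hits)
  mimic <- units[units$unit_type == "mimic", ]
  endo <- units[units$unit_type == "endogenous", ]
  if (nrow(mimic) == 0) return(none)
  tail5 <- substr(insert, 1, min(units$start) - 1)
  tail3 <- substr(insert, max(units$end) + 1, n)
  src <- paste(units$guide, collapse = "+")
  primary <- mimic$guide[1]
  dist <- sum(mimic$dist)
  base <- list(guide = primary, source = src, tail5 = tail5, tail3 = tail3,
               dist = dist, hits = units)
  if (nrow(mimic) >= 2) {
    return(c(list(subclass = "HMW_CONCATEMER", units = nrow(mimic),
                  detail = paste0("units:", nrow(mimic))), base))
  }
  if (nrow(endo) >= 1) {
    return(c(list(subclass = "HMW_HYBRID", units = nrow(units),
                  detail = paste0("endogenous:",
                                  paste(endo$guide, collapse = "+"))), base))
  }
  n5 <- nchar(tail5); n3 <- nchar(tail3)
  if (n3 >= params$polya_min && grepl("^A+$", tail3)) {
    return(c(list(subclass = "HMW_POLYA", units = 1L,
                  detail = paste0("polyA:", n3)), base))
  }
  if (n5 >= params$min_tail || n3 >= params$min_tail) {
    sub <- if (n5 >= params$min_tail && n5 > n3) "HMW_5TAIL" else
      if (n3 >= params$min_tail) "HMW_3TAIL" else "HMW_5TAIL"
    return(c(list(subclass = sub, units = 1L,
                  detail = sprintf("tail5:%d;tail3:%d", n5, n3)), base))
  }
  none
}

#' Classify an insert table
#'
#' Applies [classify_species()] to every row of an insert count table,
#' carrying counts and fractions through.
#'
#' @param table Insert table (from [preprocess_fastq()] or
#'   [collapse_inserts()]), or a character vector of inserts.
#' @param refset Mimic reference tibble.
#' @param endogenous Tibble `name`,`seq`.
#' @param params [classify_params()].
#' @return Tibble: one row per unique insert with `count`, `fraction` (when
#'   present in the input) and the classification columns.
#' @export
classify_inserts <- function(table, refset, endogenous = NULL,
                             params = classify_params()) {
  if (is.character(table)) table <- tibble::tibble(insert = table)
  cls <- purrr::map_dfr(table$insert, classify_species, refset = refset,
                        endogenous = endogenous, params = params)
  extra <- table[setdiff(names(table), "insert")]
  out <- dplyr::bind_cols(cls[, "insert"], extra,
                          cls[, setdiff(names(cls), "insert")])
  stats <- attr(table, "stats")
  if (!is.null(stats)) attr(out, "stats") <- stats
  out
}

#' Read-weighted length histogram
#'
#' Counts reads (not unique inserts) per integer length within `[lo, hi]`,
#' split by primary source guide, zero-filled across the window.
#'
#' @param classified Classified tibble ([classify_inserts()]); a `count`
#'   column weights species by reads (absent -> 1 per insert).
#' @param lo,hi Inclusive length window (nt).
#' @return Tibble `guide`, `length`, `reads`, complete over the window.
#' @export
length_histogram <- function(classified, lo = 25, hi = 74) {
  if (!"count" %in% names(classified)) classified$count <- 1L
  df <- classified |>
    dplyr::mutate(length = nchar(.data$insert),
                  guide = dplyr::coalesce(.data$guide, "(none)")) |>
    dplyr::filter(.data$length >= lo, .data$length <= hi) |>
    dplyr::group_by(.data$guide, .data$length) |>
    dplyr::summarise(reads = sum(.data$count), .groups = "drop")
  guides <- unique(df$guide)
  if (length(guides) == 0) guides <- "(none)"
  tidyr::complete(df, guide = guides, length = lo:hi,
                  fill = list(reads = 0L)) |>
    dplyr::arrange(.data$guide, .data$length)
}

#' Windowed fold change of high molecular weight species
#'
#' Per guide, the fold change of HMW read abundance between a sample and a
#' control library, restricted to a length window (default 30--60 nt, chosen
#' to exclude a co-migrating endogenous snoRNA): fold = (sample HMW reads in
#' window / sample total) / (control HMW reads in window / control total).
#' The control is 1 by construction. A zero control count yields `Inf` (raw
#' counts are kept; no silent pseudo-count). Also emits the concatemer /
#' 5'-tailing / 3'-tailing composition of each library within the window,
#' normalized to sum to 1 (the pie-chart analogue).
#'
#' @param sample,control Classified tibbles ([classify_inserts()]) built with
#'   identical preprocessing.
#' @param lo,hi Inclusive length window (nt).
#' @param normalized Divide by library totals (default). `FALSE` compares raw
#'   window counts, which is only meaningful for near-identical totals.
#' @param sample_total,control_total Library sizes; default: the retained
#'   read count recorded by preprocessing, else the table's summed counts.
#' @return An object of class `hmw_fc`: list with `fold_change` (tibble
#'   `guide`, `sample_reads`, `control_reads`, `sample_total`,
#'   `control_total`, `fold_change`), `composition` (tibble `library`,
#'   `class`, `reads`, `proportion`), and `window`.
#' @export
hmw_fold_change <- function(sample, control, lo = 30, hi = 60,
                            normalized = TRUE,
                            sample_total = NULL, control_total = NULL) {
  total_of <- function(tbl, given) {
    if (!is.null(given)) return(given)
    st <- attr(tbl, "stats")
    if (!is.null(st)) return(st$retained)
    sum(tbl$count)
  }
  sample_total <- total_of(sample, sample_total)
  control_total <- total_of(control, control_total)
  hmw_in_window <- function(tbl) {
    if (!"count" %in% names(tbl)) tbl$count <- 1L
    tbl |>
      dplyr::mutate(length = nchar(.data$insert)) |>
      dplyr::filter(grepl("^HMW_", .data$class),
                    .data$length >= lo, .data$length <= hi)
  }
  s <- hmw_in_window(sample)
  c0 <- hmw_in_window(control)
  guides <- sort(unique(c(s$guide, c0$guide)))
  guides <- guides[!is.na(guides)]
  per_guide <- function(tbl, g) sum(tbl$count[tbl$guide == g], na.rm = TRUE)
  fc_rows <- purrr::map_dfr(c(guides, "all"), function(g) {
    sr <- if (g == "all") sum(s$count) else per_guide(s, g)
    cr <- if (g == "all") sum(c0$count) else per_guide(c0, g)
    srate <- sr / sample_total
    crate <- cr / control_total
    fc <- if (normalized) {
      if (crate == 0) Inf else srate / crate
    } else {
      if (cr == 0) Inf else sr / cr
    }
    if (sr == 0 && cr == 0) fc <- NA_real_
    tibble::tibble(guide = g, sample_reads = sr, control_reads = cr,
                   sample_total = sample_total,
                   control_total = control_total, fold_change = fc)
  })
  comp_classes <- c("HMW_CONCATEMER", "HMW_5TAIL", "HMW_3TAIL")
  composition <- dplyr::bind_rows(purrr::imap(
    list(sample = s, control = c0), function(tbl, nm) {
      reads <- unname(vapply(comp_classes,
                             function(cl) sum(tbl$count[tbl$class == cl]),
                             numeric(1)))
      tibble::tibble(library = nm, class = comp_classes, reads = reads,
                     proportion = if (sum(reads) > 0) reads / sum(reads)
                                  else rep(NA_real_, length(reads)))
    }))
  structure(list(fold_change = fc_rows, composition = composition,
                 window = c(lo, hi)), class = "hmw_fc")
}

#' @export
print.hmw_fc <- function(x, ...) {
  cat("<hmw_fc> window ", x$window[1], "-", x$window[2], " nt\n", sep = "")
  print(x$fold_change, ...)
  invisible(x)
}

#' Write a classification table as TSV
#'
#' @param x Classified tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
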