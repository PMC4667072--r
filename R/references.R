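#' Convert an antisense Northern probe to the mature miRNA sequence
#'
#' Northern blot probes for miRNAs are DNA oligonucleotides antisense to the
#' mature species, so the mature sequence (in cDNA space) is simply the
#' reverse complement of the probe.
#'
#' @param probe Character vector of probe sequences over `{A,C,G,T}`.
#' @return Character vector of mature sequences (DNA space).
#' @examples
#' probe_to_mature("ACTACCTGCACTGTAAGCACTTTG")  # miR-17-5p
#' @export
probe_to_mature <- function(probe) {
  probe <- toupper(probe)
  bad <- grepl("[^ACGT]", probe)
  if (any(bad)) {
    stop("probe contains non-ACGT characters at position(s): ",
         paste(which(bad), collapse = ", "))
  }
  rc(probe)
}

#' Build a mimic reference set
#'
#' A mimic reference pairs each transfected guide strand with its (optional)
#' passenger strand and family label, and records the seed (guide positions
#' 2--8, 1-based inclusive), the primary determinant of target pairing.
#'
#' @param name Character vector of unique mimic names.
#' @param guide Guide strand sequences (DNA space, 18--30 nt).
#' @param passenger Optional passenger strand sequences (`NA` allowed).
#' @param family Optional family labels.
#' @return A tibble with columns `name`, `guide`, `passenger`, `family`,
#'   `seed`.
#' @export
mimic_reference_set <- function(name, guide, passenger = NA_character_,
                                family = NA_character_) {
  guide <- dna_space(guide)
  if (anyDuplicated(name)) stop("mimic names must be unique")
  if (any(grepl("[^ACGT]", guide))) stop("guide sequences must be over {A,C,G,T}")
  len <- nchar(guide)
  if (any(len < 18 | len > 30)) {
    stop("guide length outside [18, 30] nt: ",
         paste(name[len < 18 | len > 30], collapse = ", "))
  }
  tibble::tibble(
    name = as.character(name),
    guide = guide,
    passenger = dna_space(as.character(passenger)),
    family = as.character(family),
    seed = substr(guide, 2, 8)
  )
}

#' The six transfected miR-17~92 guide strands
#'
#' Guide sequences recovered from the antisense Northern probes for the six
#' mimics of the miR-17~92 cluster (miR-17, miR-18a, miR-19a, miR-20a,
#' miR-19b, miR-92), in DNA space. Passenger strands are set to the exact
#' reverse complement of each guide, matching the "perfectly antisense"
#' passenger species the mimics carry.
#'
#' @return A mimic reference tibble (see [mimic_reference_set()]).
#' @export
mir17_92_guides <- function() {
  probes <- c(
    "miR-17"  = "ACTACCTGCACTGTAAGCACTTTG",
    "miR-18a" = "CTATCTGCACTAGATGCACCTTA",
    "miR-19a" = "TCAGTTTTGCATAGATTTGCACA",
    "miR-20a" = "CTACCTGCACTATAAGCACTTTA",
    "miR-19b" = "TCAGTTTTGCATGGATTTGCACA",
    "miR-92"  = "CAGGCCGGGACAAGTGCAATA"
  )
  family <- c("miR-17", "miR-18", "miR-19", "miR-17", "miR-19", "miR-92")
  guides <- probe_to_mature(unname(probes))
  mimic_reference_set(names(probes), guides,
                      passenger = rc(guides), family = family)
}

#' Endogenous miRNA background set
#'
#' A small set of abundant endogenous HeLa miRNAs (miRBase mature sequences in
#' DNA space), used as the default background for simulation and for hybrid /
#' endogenous classification.
#'
#' @return A tibble with columns `name`, `seq`.
#' @export
example_endogenous <- function() {
  tibble::tibble(
    name = c("miR-16-5p", "miR-21-5p", "let-7a-5p", "miR-26a-5p",
             "miR-221-3p", "miR-24-3p"),
    seq = c("TAGCAGCACGTAAATATTGGCG",
            "TAGCTTATCAGACTGATGTTGA",
            "TGAGGTAGTAGGTTGTATAGTT",
            "TTCAAGTAATCCAGGATAGGCT",
            "AGCTACATTGTCTGCTGGGTTTC",
            "TGGCTCAGTTCAGCAGGAACAG")
  )
}

#' Read a FASTA file into a sequence tibble
#'
#' Sequences are uppercased and mapped to DNA space (U -> T); work downstream
#' is in cDNA coordinates throughout.
#'
#' @param path FASTA file.
#' @return A tibble with columns `name`, `seq`.
#' @export
read_fasta_tbl <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e) {
                   stop("malformed FASTA '", path, "': ", conditionMessage(e))
                 })
  tibble::tibble(
    name = sub("\\s.*$", "", names(ss)),
    seq = dna_space(unname(as.character(ss)))
  )
}

#' Write a sequence tibble to FASTA
#'
#' @param x Tibble with columns `name`, `seq` (a `guide` column is used when
#'   `seq` is absent, so mimic reference tibbles can be written directly).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta_tbl <- function(x, path) {
  seqs <- if ("seq" %in% names(x)) x$seq else x$guide
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- x$name
  Biostrings::writeXStringSet(ss, path, format = "fasta")
  invisible(path)
}

#' Read a guides FASTA into a mimic reference set
#'
#' Entries named `passenger_<name>` are attached as the passenger strand of
#' mimic `<name>` rather than treated as separate mimics.
#'
#' @param path FASTA file of guide strands.
#' @return A mimic reference tibble (see [mimic_reference_set()]).
#' @export
read_guides_fasta <- function(path) {
  tbl <- read_fasta_tbl(path)
  is_pass <- grepl("^passenger_", tbl$name)
  guides <- tbl[!is_pass, ]
  pass <- tbl[is_pass, ]
  pass$name <- sub("^passenger_", "", pass$name)
  passenger <- pass$seq[match(guides$name, pass$name)]
  mimic_reference_set(guides$name, guides$seq, passenger = passenger)
}

#' Validate reference sets
#'
#' Report-only checks on guide and endogenous references: duplicated names,
#' non-ACGTU characters, guides outside 18--30 nt, and sequence collisions
#' between the guide and endogenous sets (a colliding sequence would make the
#' MATURE and ENDOGENOUS labels indistinguishable).
#'
#' @param guides Tibble with `name` and `guide` (or `seq`) columns.
#' @param endogenous Optional tibble with `name`, `seq`.
#' @return A tibble of flags with columns `check`, `name`, `detail`; zero rows
#'   when the references are clean.
#' @export
validate_references <- function(guides, endogenous = NULL) {
  gseq <- if ("guide" %in% names(guides)) guides$guide else guides$seq
  flags <- list()
  flag <- function(check, name, detail) {
    tibble::tibble(check = check, name = name, detail = detail)
  }
  dup <- guides$name[duplicated(guides$name)]
  for (d in unique(dup)) {
    flags <- c(flags, list(flag("duplicate_name", d,
      paste("records", paste(which(guides$name == d), collapse = ",")))))
  }
  bad <- grepl("[^ACGTU]", toupper(gseq))
  if (any(bad)) {
    flags <- c(flags, list(flag("invalid_character", guides$name[bad],
                                gseq[bad])))
  }
  len <- nchar(gseq)
  off <- len < 18 | len > 30
  if (any(off)) {
    flags <- c(flags, list(flag("guide_length", guides$name[off],
                                paste0(len[off], " nt"))))
  }
  if (!is.null(endogenous)) {
    hit <- match(dna_space(gseq), dna_space(endogenous$seq))
    coll <- !is.na(hit)
    if (any(coll)) {
      flags <- c(flags, list(flag("guide_endogenous_collision",
                                  guides$name[coll],
                                  endogenous$name[hit[coll]])))
    }
    edup <- endogenous$name[duplicated(endogenous$name)]
    for (d in unique(edup)) {
      flags <- c(flags, list(flag("duplicate_name", d,
        paste("records", paste(which(endogenous$name == d), collapse = ",")))))
    }
  }
  if (length(flags) == 0) {
    return(tibble::tibble(check = character(), name = character(),
                          detail = character()))
  }
  dplyr::bind_rows(flags)
}
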