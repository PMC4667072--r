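#' Relative expression by the delta-delta-Ct method
#'
#' For each sample and gene, fold change = 2^-ddCt with
#' ddCt = (Ct_gene - Ct_ref)_sample - (Ct_gene - Ct_ref)_control. PCR
#' efficiency is fixed at 2, the classical assumption of the method.
#'
#' @param table Tibble with columns `sample`, `gene`, `ct`.
#' @param reference_gene Reference (housekeeping) gene, present in every
#'   sample.
#' @param control_sample Calibrator sample (fold change 1 by construction).
#' @return Tibble `sample`, `gene`, `delta_ct`, `ddct`, `fold_change` for all
#'   non-reference genes.
#' @examples
#' ct <- tibble::tibble(
#'   sample = rep(c("ctrl", "treated"), each = 2),
#'   gene = rep(c("Actb", "Pten"), 2),
#'   ct = c(15, 24, 15, 23))
#' ddct_fold_change(ct, "Actb", "ctrl")  # Pten fold 2 in treated
#' @export
ddct_fold_change <- function(table, reference_gene, control_sample) {
  stopifnot(all(c("sample", "gene", "ct") %in% names(table)))
  if (!all(is.finite(table$ct)) || any(table$ct <= 0))
    stop("Ct values must be finite and positive")
  if (!control_sample %in% table$sample)
    stop("control sample '", control_sample, "' not in table")
  ref <- table[table$gene == reference_gene, ]
  missing_ref <- setdiff(unique(table$sample), ref$sample)
  if (length(missing_ref) > 0) {
    stop("reference gene '", reference_gene, "' missing in sample(s): ",
         paste(missing_ref, collapse = ", "))
  }
  dct <- table |>
    dplyr::filter(.data$gene != reference_gene) |>
    dplyr::left_join(ref |> dplyr::select("sample", ref_ct = "ct"),
                     by = "sample") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct)
  ctrl <- dct |>
    dplyr::filter(.data$sample == control_sample) |>
    dplyr::select("gene", ctrl_delta_ct = "delta_ct")
  dct |>
    dplyr::left_join(ctrl, by = "gene") |>
    dplyr::mutate(ddct = .data$delta_ct - .data$ctrl_delta_ct,
                  fold_change = 2^(-.data$ddct)) |>
    dplyr::select("sample", "gene", "delta_ct", "ddct", "fold_change")
}

#' Normalize band intensities to an internal control
#'
#' The Northern-blot convention: per lane, target intensity over control
#' (e.g. U6 snRNA) intensity, rescaled so the designated reference lane
#' (e.g. non-transfected cells) is exactly 1.
#'
#' @param table Tibble with columns `lane`, `target`, `control`.
#' @param reference_lane Lane whose ratio defines 1.
#' @return `table` with added `ratio` and `relative` columns.
#' @export
normalize_to_reference <- function(table, reference_lane) {
  stopifnot(all(c("lane", "target", "control") %in% names(table)))
  if (any(table$control <= 0)) stop("control intensity must be > 0 in all lanes")
  i <- match(reference_lane, table$lane)
  if (is.na(i)) stop("reference lane '", reference_lane, "' not in table")
  if (table$target[i] <= 0)
    stop("zero target intensity in reference lane '", reference_lane, "'")
  table |>
    dplyr::mutate(ratio = .data$target / .data$control,
                  relative = .data$ratio / (.data$ratio[i]))
}

#' Copies per cell from a spike-in ladder
#'
#' Calibrates band intensity against graded known amounts of the same
#' synthetic RNA loaded directly on the gel. Interpolation is piecewise
#' linear in log10(copies) vs log10(intensity) -- band intensity is
#' multiplicative -- with clamped extrapolation beyond the ladder ends; the
#' interpolated loaded copies are divided by the number of cells the sample
#' lane represents.
#'
#' @param ladder Tibble with columns `copies` (strictly increasing) and
#'   `intensity` (> 0), at least two rows.
#' @param sample_intensity Measured intensity (vectorized, >= 0; 0 -> 0
#'   copies).
#' @param cells Number of cells represented in the sample lane (> 0).
#' @return Numeric vector of copies per cell.
#' @examples
#' ladder <- tibble::tibble(copies = c(1e5, 1e7), intensity = c(100, 10000))
#' copies_per_cell(ladder, 1000, cells = 10)  # 1e6 copies / 10 cells
#' @export
copies_per_cell <- function(ladder, sample_intensity, cells) {
  stopifnot(all(c("copies", "intensity") %in% names(ladder)))
  if (nrow(ladder) < 2) stop("ladder needs at least 2 points")
  if (any(diff(ladder$copies) <= 0)) stop("ladder copies must be strictly increasing")
  if (any(ladder$intensity <= 0)) stop("ladder intensities must be positive")
  if (any(sample_intensity < 0)) stop("sample intensity must be >= 0")
  if (cells <= 0) stop("cells must be > 0")
  out <- numeric(length(sample_intensity))
  pos <- sample_intensity > 0
  if (any(pos)) {
    fit <- stats::approx(log10(ladder$intensity), log10(ladder$copies),
                         xout = log10(sample_intensity[pos]), rule = 2,
                         ties = "ordered")
    out[pos] <- 10^fit$y / cells
  }
  out
}

#' Division-normalized decay of a transfected RNA
#'
#' Separates true decay from dilution by cell division. The corrected series
#' is `signal(t) * 2^(t / Td)` (Td = doubling time, hours); the observed
#' half-life `t_obs` comes from an ordinary least-squares fit of log2(signal)
#' against time; and the division-corrected decay rate is
#' `k_decay = ln(2) * (1/t_obs - 1/Td)` (per hour). A non-positive `k_decay`
#' means the apparent decline is explained entirely by dilution: no active
#' decay.
#'
#' @param time Time points (hours), strictly increasing, at least 3.
#' @param signal Positive signal values (per-cell abundance, AU).
#' @param doubling_time Cell doubling time Td in hours (default 23, the
#'   HeLa average).
#' @return A `decay_fit` object: list with `series` (tibble `time`, `signal`,
#'   `corrected`), `t_obs`, `k_decay`, `doubling_time`, `no_active_decay`,
#'   `fit` (the `lm`). Methods: [tidy.decay_fit()], [glance.decay_fit()],
#'   [autoplot.decay_fit()].
#' @examples
#' t <- seq(0, 72, by = 12)
#' division_normalized_decay(t, 100 * 2^(-t / 23), doubling_time = 23)
#' @export
division_normalized_decay <- function(time, signal, doubling_time = 23) {
  if (length(time) < 3) stop("need at least 3 time points")
  if (length(signal) != length(time)) stop("time and signal lengths differ")
  if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
  if (doubling_time <= 0) stop("doubling_time must be > 0")
  if (any(signal <= 0)) stop("signals must be positive (log undefined)")
  corrected <- signal * 2^(time / doubling_time)
  fit <- stats::lm(log2(signal) ~ time)
  slope <- unname(stats::coef(fit)[2])
  t_obs <- if (slope < 0) -1 / slope else Inf
  k_decay <- log(2) * (1 / t_obs - 1 / doubling_time)
  structure(list(
    series = tibble::tibble(time = time, signal = signal,
                            corrected = corrected),
    t_obs = t_obs, k_decay = k_decay, doubling_time = doubling_time,
    no_active_decay = k_decay <= 0, fit = fit), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> t_obs = ", signif(x$t_obs, 4), " h, Td = ",
      x$doubling_time, " h, k_decay = ", signif(x$k_decay, 4), " /h",
      if (x$no_active_decay) "  [no active decay]", "\n", sep = "")
  invisible(x)
}

#' Tidy the corrected decay series
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return The `series` tibble (`time`, `signal`, `corrected`).
#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) x$series

#' One-row summary of a decay fit
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return Tibble with `t_obs`, `doubling_time`, `k_decay`,
#'   `no_active_decay`, `r_squared`.
#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  tibble::tibble(t_obs = x$t_obs, doubling_time = x$doubling_time,
                 k_decay = x$k_decay, no_active_decay = x$no_active_decay,
                 r_squared = suppressWarnings(summary(x$fit)$r.squared))
}

#' Genomic interval length
#'
#' @param start,end Coordinates with `end >= start`.
#' @param convention `"1-based inclusive"` (end - start + 1) or
#'   `"0-based half-open"` (end - start).
#' @return Length in bp.
#' @examples
#' interval_length(91350568, 91351574)  # the 1007 bp miR-17~92 insert
#' @export
interval_length <- function(start, end,
                            convention = c("1-based inclusive",
                                           "0-based half-open")) {
  convention <- match.arg(convention)
  if (any(end < start)) stop("end must be >= start")
  if (convention == "1-based inclusive") end - start + 1 else end - start
}
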