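#' Mean of a positional signal in non-overlapping bins
#'
#' Averages track values whose positions fall in each genome bin; bins with
#' no overlapping values are missing (`NA`), never zero.
#'
#' @param track Tibble with `chrom`, `pos` (0-based) and a value column.
#' @param genome Bin table from [make_genome()].
#' @param value Name of the value column (default `"value"`).
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
bin_track_mean <- function(track, genome, value = "value") {
  bin_size <- bin_size_of(genome)
  means <- track |>
    dplyr::group_by(chrom = .data$chrom,
                    start = floor(.data$pos / bin_size) * bin_size) |>
    dplyr::summarise(value = mean(.data[[value]]), .groups = "drop")
  genome |>
    dplyr::select("chrom", "start", "end") |>
    dplyr::left_join(means, by = c("chrom", "start"))
}

#' Per-bin log2 differential between two tracks
#'
#' `log2(ko / wt)` per bin on a shared grid; bins where either value is
#' missing or non-positive are missing.
#'
#' @param data Tibble with `chrom`, `start`, `end` and the two value columns.
#' @param ko,wt Column names of the numerator (e.g. mutant) and denominator
#'   (e.g. wild-type) tracks.
#' @return Tibble `chrom`, `start`, `end`, `log2_ratio`.
#' @export
log2_differential <- function(data, ko = "ko", wt = "wt") {
  k <- data[[ko]]
  w <- data[[wt]]
  ratio <- ifelse(!is.na(k) & !is.na(w) & k > 0 & w > 0, log2(k / w),
                  NA_real_)
  dplyr::mutate(dplyr::select(data, "chrom", "start", "end"),
                log2_ratio = ratio)
}

#' Xi probability of allele-resolved expression
#'
#' `xi / (xi + xa)` per gene: 0 means fully silenced on the inactive X and
#' 0.5 means expression balanced between the two alleles (full reactivation
#' benchmark). Missing when both read counts are zero. Scale-invariant in
#' the read counts.
#'
#' @param xi_reads,xa_reads Allele-resolved read counts (Xi and Xa).
#' @return Numeric vector in \[0, 1\] (or `NA`).
#' @export
xi_probability <- function(xi_reads, xa_reads) {
  if (any(xi_reads < 0 | xa_reads < 0, na.rm = TRUE)) {
    stop("read counts must be >= 0", call. = FALSE)
  }
  total <- xi_reads + xa_reads
  ifelse(is.na(total) | total == 0, NA_real_, xi_reads / total)
}

#' Feature density by RT class
#'
#' Assigns each feature to the class of the bin containing its midpoint and
#' reports per class: feature count, genomic span, density per Mb, density
#' normalized by an optional second feature set (e.g. escapees per Ref-seq
#' gene density), and the fold change versus a reference class (computed on
#' normalized densities when a normalizer is supplied, raw densities
#' otherwise).
#'
#' @param features Tibble with `chrom`, `start`, `end` (features, e.g.
#'   escapees).
#' @param track Class track from [classify_smchd1()] or
#'   [classify_differentiation()].
#' @param normalizer Optional feature tibble for density normalization
#'   (e.g. all genes). Classes with zero normalizer density get a missing
#'   normalized density.
#' @param reference Class label used as the fold-change baseline (default
#'   `"CL"`).
#' @param bin_size Bin width in bp; default inferred from the track.
#' @return Tibble `label`, `bin_count`, `span_mb`, `count`, `density_per_mb`,
#'   `normalized_density`, `fold_vs_reference`.
#' @export
density_by_class <- function(features, track, normalizer = NULL,
                             reference = "CL", bin_size = NULL) {
  bin_size <- bin_size %||% bin_size_of(track)
  spans <- class_spans(track, bin_size)
  count_by_class <- function(feat) {
    feat |>
      dplyr::mutate(mid = (.data$start + .data$end) / 2,
                    bstart = floor(.data$mid / bin_size) * bin_size) |>
      dplyr::inner_join(track, by = c("chrom", "bstart" = "start")) |>
      dplyr::count(.data$label, name = "count")
  }
  out <- spans |>
    dplyr::left_join(count_by_class(features), by = "label") |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::filter(.data$span_mb > 0) |>
    dplyr::mutate(density_per_mb = .data$count / .data$span_mb)
  if (!is.null(normalizer)) {
    norm <- spans |>
      dplyr::left_join(count_by_class(normalizer), by = "label") |>
      dplyr::mutate(norm_density = dplyr::coalesce(.data$count, 0L) /
                      .data$span_mb) |>
      dplyr::select("label", "norm_density")
    out <- out |>
      dplyr::left_join(norm, by = "label") |>
      dplyr::mutate(normalized_density = ifelse(
        .data$norm_density > 0, .data$density_per_mb / .data$norm_density,
        NA_real_
      )) |>
      dplyr::select(-"norm_density")
  } else {
    out$normalized_density <- NA_real_
  }
  basis <- if (is.null(normalizer)) out$density_per_mb else
    out$normalized_density
  ref <- basis[out$label == reference]
  out$fold_vs_reference <- if (length(ref) == 1 && !is.na(ref) && ref > 0) {
    basis / ref
  } else {
    NA_real_
  }
  out
}
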