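#' Count read positions in (sliding) genomic windows
#'
#' Counts reads in windows of `window_bp` placed every `step_bp` along each
#' chromosome (0-based half-open, windows labeled by start, terminal partial
#' windows dropped). With `step_bp == window_bp` this is ordinary
#' non-overlapping binning; with `step_bp < window_bp` each read is counted
#' in every window that contains it, as in sliding-window Repli-seq profiles
#' (e.g. 200-kb windows at 80-kb intervals).
#'
#' @param reads Tibble with columns `chrom` and `pos` (0-based coordinates,
#'   sorted within chromosome).
#' @param genome Chromosome table or bin table carrying chromosome lengths;
#'   either a `make_genome()` result (lengths inferred from the last bin end)
#'   or a tibble `chrom`, `length`.
#' @param window_bp,step_bp Window width and spacing in bp
#'   (`step_bp <= window_bp`).
#' @return Tibble `chrom`, `start`, `end`, `count`.
#' @export
bin_counts <- function(reads, genome, window_bp, step_bp = window_bp) {
  if (step_bp > window_bp) stop("`step_bp` must be <= `window_bp`", call. = FALSE)
  lens <- if ("length" %in% names(genome)) {
    dplyr::distinct(genome, .data$chrom, .data$length)
  } else {
    dplyr::summarise(dplyr::group_by(genome, .data$chrom),
                     length = max(.data$end), .groups = "drop")
  }
  purrr::pmap_dfr(lens, function(chrom, length, ...) {
    starts <- seq(0, length - window_bp, by = step_bp)
    pos <- sort(reads$pos[reads$chrom == chrom])
    if (any(pos < 0 | pos >= length)) {
      stop("read positions outside chromosome bounds", call. = FALSE)
    }
    # reads in [s, s + window): cumulative counts at the two boundaries
    count <- findInterval(starts + window_bp - 0.5, pos) -
      findInterval(starts - 0.5, pos)
    tibble::tibble(chrom = chrom, start = starts, end = starts + window_bp,
                   count = count)
  })
}

#' BrdU-IP replication-timing score from early/late counts
#'
#' Scales each fraction to reads per million, computes the early ratio
#' `r = E / (E + L)` per bin and maps it to an RT score `rt = 2 r - 1`, so
#' scores span \[-1, +1\] with positive = early, negative = late and 0 at
#' equal scaled coverage. Bins whose scaled total `E + L` falls strictly
#' below the `low_count_quantile` quantile of all totals, or is zero, are set
#' to missing (`NA`), never to 0.
#'
#' @param data Tibble with `chrom`, `start`, `end` and the two count columns.
#' @param early,late Names of the early- and late-fraction count columns.
#' @param low_count_quantile Fraction of lowest-total bins to drop
#'   (default 0.05).
#' @return Tibble `chrom`, `start`, `end`, `rt`.
#' @export
rt_score <- function(data, early = "early", late = "late",
                     low_count_quantile = 0.05) {
  e <- data[[early]]
  l <- data[[late]]
  if (any(e < 0, na.rm = TRUE) || any(l < 0, na.rm = TRUE)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  e_rpm <- e / sum(e) * 1e6
  l_rpm <- l / sum(l) * 1e6
  total <- e_rpm + l_rpm
  cutoff <- stats::quantile(total, low_count_quantile, na.rm = TRUE)
  keep <- total > 0 & total >= cutoff  # strictly-below-quantile removed
  rt <- ifelse(keep, 2 * e_rpm / total - 1, NA_real_)
  dplyr::mutate(dplyr::select(data, "chrom", "start", "end"), rt = rt)
}

#' Quantile-normalize RT profiles and average replicates
#'
#' Forces all samples onto a common value distribution -- the mean of the
#' per-sample sorted (non-missing) values -- by rank mapping, with ties
#' sharing the average reference value and missing bins excluded from the
#' mapping and preserved as missing. If `group` is given, profiles are then
#' averaged elementwise within each replicate group (mean over non-missing
#' replicates).
#'
#' @param data Long tibble with columns `chrom`, `start`, `end`, `sample_id`,
#'   `rt` (shared bin grid across samples).
#' @param group Optional named character vector or tibble
#'   (`sample_id`, `group`) assigning samples to replicate groups.
#' @return Long tibble in the same shape; after grouping, `sample_id` holds
#'   the group name.
#' @export
normalize_profiles <- function(data, group = NULL) {
  wide <- tidyr::pivot_wider(data, id_cols = c("chrom", "start", "end"),
                             names_from = "sample_id", values_from = "rt")
  samples <- setdiff(names(wide), c("chrom", "start", "end"))
  vals <- as.matrix(wide[samples])
  n_ok <- colSums(!is.na(vals))
  if (any(n_ok == 0)) stop("profile with all values missing", call. = FALSE)

  # reference distribution: mean of sorted values, interpolated to a common
  # grid when samples differ in their number of non-missing bins
  n_ref <- max(n_ok)
  grid <- seq(0, 1, length.out = n_ref)
  ref <- rowMeans(vapply(samples, function(s) {
    v <- sort(vals[, s])
    if (length(v) == 1) rep(v, n_ref) else
      stats::approx(seq(0, 1, length.out = length(v)), v, xout = grid)$y
  }, numeric(n_ref)))

  norm <- vals
  for (s in samples) {
    ok <- !is.na(vals[, s])
    rk <- rank(vals[ok, s], ties.method = "average")
    p <- if (sum(ok) == 1) 0.5 else (rk - 1) / (sum(ok) - 1)
    norm[ok, s] <- stats::approx(grid, ref, xout = p)$y
  }

  out <- dplyr::mutate(wide[c("chrom", "start", "end")])
  out <- dplyr::bind_cols(out, tibble::as_tibble(norm))
  long <- tidyr::pivot_longer(out, dplyr::all_of(samples),
                              names_to = "sample_id", values_to = "rt")
  if (is.null(group)) {
    return(dplyr::arrange(long,
                          factor(.data$sample_id, levels = samples),
                          factor(.data$chrom, levels = unique(data$chrom)),
                          .data$start))
  }
  if (is.data.frame(group)) {
    map <- stats::setNames(group$group, group$sample_id)
  } else {
    map <- group
  }
  long |>
    dplyr::mutate(sample_id = unname(map[.data$sample_id])) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$sample_id) |>
    dplyr::summarise(
      rt = ifelse(all(is.na(.data$rt)), NA_real_, mean(.data$rt, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$sample_id,
                   factor(.data$chrom, levels = unique(data$chrom)),
                   .data$start)
}
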