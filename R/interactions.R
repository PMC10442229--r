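#' Assign 4C reads to alleles by exact SNP-bearing prefix match
#'
#' Allele demultiplexing of 4C-seq read 2: a read is assigned to an allele
#' only when its prefix matches the expected viewpoint-proximal sequence
#' (carrying the discriminating SNPs) with zero mismatches; anything else is
#' `unassigned`.
#'
#' @param prefixes Character vector of read-2 prefixes.
#' @param snp_table Tibble with columns `allele` and `prefix` (the expected
#'   sequence per allele, e.g. one row for B6 and one for JF1).
#' @return Character vector of allele labels (`unassigned` for no match).
#' @export
assign_allele <- function(prefixes, snp_table) {
  if (anyDuplicated(snp_table$prefix) > 0) {
    stop("ambiguous SNP table: the same prefix is expected for two alleles",
         call. = FALSE)
  }
  idx <- match(prefixes, snp_table$prefix)
  ifelse(is.na(idx), "unassigned", snp_table$allele[idx])
}

#' Running-mean smoothing over restriction fragments
#'
#' Centered running mean over a window of `window` fragments (default 201),
#' truncated at the ends of the fragment series (edge windows average over
#' the available fragments only). Missing values are excluded from each
#' window's mean.
#'
#' @param x Ordered per-fragment signal.
#' @param window Odd window size.
#' @return Smoothed numeric vector, same length as `x`.
#' @export
smooth_fragments <- function(x, window = 201) {
  if (window %% 2 == 0) stop("`window` must be odd", call. = FALSE)
  n <- length(x)
  h <- (window - 1) / 2
  cs <- cumsum(c(0, ifelse(is.na(x), 0, x)))
  ck <- cumsum(c(0, !is.na(x)))
  lo <- pmax(seq_len(n) - h, 1)
  hi <- pmin(seq_len(n) + h, n)
  s <- cs[hi + 1] - cs[lo]
  k <- ck[hi + 1] - ck[lo]
  ifelse(k == 0, NA_real_, s / k)
}

#' Extract a virtual 4C profile from a contact matrix
#'
#' Sums the contact-matrix rows of all bins inside the viewpoint span (for a
#' 400-kb viewpoint at 5-kb resolution, 80 rows) into one genome-wide
#' profile, masks the viewpoint span plus `exclude_flank` bins on each side
#' in cis, and scales the remaining profile to a total of 10,000 (reads per
#' 10,000 contacts), making profiles comparable across viewpoints and
#' invariant to overall sequencing depth.
#'
#' @param cm A [contact_matrix()].
#' @param chrom,start,end Viewpoint span (0-based half-open).
#' @param exclude_flank Cis exclusion zone beyond the viewpoint, in bins
#'   (default 50).
#' @return Tibble `bin_id`, `chrom`, `start`, `end`, `signal` (`NA` in the
#'   masked zone), with the viewpoint recorded in attribute `viewpoint`. A
#'   viewpoint with zero total unmasked contacts yields an all-`NA` profile
#'   with a warning.
#' @export
virtual_4c <- function(cm, chrom, start, end, exclude_flank = 50) {
  bins <- cm$bins
  vp <- which(bins$chrom == chrom & bins$start >= start & bins$end <= end)
  if (length(vp) == 0) stop("viewpoint contains no bins", call. = FALSE)
  signal <- as.numeric(Matrix::colSums(cm$mat[vp, , drop = FALSE]))
  cis <- which(bins$chrom == chrom)
  mask <- cis[cis >= min(vp) - exclude_flank & cis <= max(vp) + exclude_flank]
  signal[mask] <- NA_real_
  tot <- sum(signal, na.rm = TRUE)
  if (tot == 0) {
    warning("viewpoint has zero unmasked contacts; returning an empty profile")
    signal[] <- NA_real_
  } else {
    signal <- signal / tot * 1e4
  }
  out <- dplyr::mutate(
    dplyr::select(bins, "bin_id", "chrom", "start", "end"),
    signal = signal
  )
  attr(out, "viewpoint") <- list(chrom = chrom, start = start, end = end)
  out
}

# Binomial window test shared by far-cis and trans calling: binarized
# coverage k out of n non-missing bins against a background covered
# fraction p_bg.
#' @keywords internal
window_binom <- function(k, n, p_bg) {
  z <- (k - n * p_bg) / sqrt(n * p_bg * (1 - p_bg))
  p <- stats::pbinom(k - 1, n, p_bg, lower.tail = FALSE)
  bad <- n == 0 | p_bg <= 0 | p_bg >= 1
  z[bad] <- NA_real_
  p[bad] <- NA_real_
  list(z = z, p = p)
}

# Rolling sums of a 0/1/NA vector: covered count and non-missing count per
# window of `w` starting at each index.
#' @keywords internal
roll_cover <- function(cover, w, starts) {
  cs <- cumsum(c(0, ifelse(is.na(cover), 0, cover)))
  ck <- cumsum(c(0, !is.na(cover)))
  list(k = cs[starts + w] - cs[starts], n = ck[starts + w] - ck[starts])
}

#' Call significant far-cis interactions of a viewpoint
#'
#' Binarizes the cis profile (coverage = signal > 0) and slides a test window
#' of `w` bins (step 1) along the viewpoint chromosome. Each window's covered
#' count is tested against the covered fraction `p_bg` of a background window
#' of `W` bins centered on it (test window excluded, truncated at chromosome
#' ends) with a one-sided upper-tail binomial test; the normal
#' approximation `z = (k - n p_bg) / sqrt(n p_bg (1 - p_bg))` is reported
#' alongside. Windows with degenerate background (`p_bg` of 0 or 1) are
#' marked missing and excluded from FDR control. Benjamini-Hochberg
#' adjustment is applied across windows, and adjacent or overlapping
#' significant windows (`q <= fdr`) are merged into interaction intervals.
#'
#' @param profile A [virtual_4c()] profile (or any tibble with `chrom`,
#'   `start`, `end`, `signal` on one chromosome after filtering to cis).
#' @param w Test window size in bins (default 50).
#' @param W Background window size in bins (default 1200; must exceed `w`).
#' @param fdr Benjamini-Hochberg threshold (default 0.01).
#' @param chrom Chromosome to test; default the viewpoint chromosome.
#' @return An `interaction_calls` object: list with `windows` (per-window
#'   tibble `chrom`, `start`, `end`, `k`, `n`, `p_bg`, `z`, `p`, `q`,
#'   `significant`), `intervals` (merged significant spans) and `n_calls`.
#' @export
far_cis_calls <- function(profile, w = 50, W = 1200, fdr = 0.01,
                          chrom = NULL) {
  if (W <= w) stop("`W` must be > `w`", call. = FALSE)
  chrom <- chrom %||% attr(profile, "viewpoint")$chrom
  cis <- profile[profile$chrom == chrom, ]
  n_bins <- nrow(cis)
  if (n_bins < w) stop("fewer cis bins than the test window", call. = FALSE)
  cover <- ifelse(is.na(cis$signal), NA, as.numeric(cis$signal > 0))

  starts <- seq_len(n_bins - w + 1)
  test <- roll_cover(cover, w, starts)
  # centered background: W bins around the test window, minus the window
  half <- ceiling((W - w) / 2)
  bg_lo <- pmax(starts - half, 1)
  bg_hi <- pmin(starts + w - 1 + half, n_bins)
  cs <- cumsum(c(0, ifelse(is.na(cover), 0, cover)))
  ck <- cumsum(c(0, !is.na(cover)))
  bg_k <- (cs[bg_hi + 1] - cs[bg_lo]) - test$k
  bg_n <- (ck[bg_hi + 1] - ck[bg_lo]) - test$n
  p_bg <- ifelse(bg_n == 0, NA_real_, bg_k / bg_n)

  bt <- window_binom(test$k, test$n, p_bg)
  windows <- tibble::tibble(
    chrom = chrom,
    start = cis$start[starts],
    end = cis$end[starts + w - 1],
    k = test$k, n = test$n, p_bg = p_bg, z = bt$z, p = bt$p
  )
  finish_calls(windows, fdr)
}

#' Call significant trans (interchromosomal) interactions of a viewpoint
#'
#' Applies the same binarized binomial window test as [far_cis_calls()] to
#' every non-viewpoint chromosome, with windows of `window` bins tiled at
#' half-window steps and the background covered fraction taken from the
#' viewpoint's genome-wide trans coverage. Benjamini-Hochberg adjustment is
#' applied across all trans windows; the number of merged significant
#' intervals is the viewpoint's trans interaction count.
#'
#' @inheritParams far_cis_calls
#' @param window Window size in bins (default 250).
#' @param step Window step in bins (default half the window).
#' @return An `interaction_calls` object (see [far_cis_calls()]).
#' @export
trans_calls <- function(profile, window = 250, fdr = 0.01, step = NULL,
                        chrom = NULL) {
  step <- step %||% max(1, floor(window / 2))
  chrom <- chrom %||% attr(profile, "viewpoint")$chrom
  trans <- profile[profile$chrom != chrom, ]
  if (nrow(trans) == 0) stop("no trans bins", call. = FALSE)
  cover_all <- ifelse(is.na(trans$signal), NA,
                      as.numeric(trans$signal > 0))
  if (all(is.na(cover_all))) stop("no scored trans bins", call. = FALSE)
  p_bg <- mean(cover_all, na.rm = TRUE)

  windows <- trans |>
    dplyr::mutate(cover = cover_all) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      n_bins <- nrow(d)
      if (n_bins < window) return(tibble::tibble())
      starts <- seq(1, n_bins - window + 1, by = step)
      rc <- roll_cover(d$cover, window, starts)
      tibble::tibble(start = d$start[starts],
                     end = d$end[starts + window - 1],
                     k = rc$k, n = rc$n)
    }) |>
    dplyr::ungroup()
  if (nrow(windows) == 0) stop("no trans chromosome is long enough for the window",
                               call. = FALSE)
  windows$p_bg <- p_bg
  bt <- window_binom(windows$k, windows$n, windows$p_bg)
  windows$z <- bt$z
  windows$p <- bt$p
  finish_calls(windows, fdr)
}

# BH adjustment, significance flag and merged intervals.
#' @keywords internal
finish_calls <- function(windows, fdr) {
  windows$q <- NA_real_
  ok <- !is.na(windows$p)
  windows$q[ok] <- stats::p.adjust(windows$p[ok], method = "BH")
  windows$significant <- !is.na(windows$q) & windows$q <= fdr
  intervals <- merge_intervals(windows[windows$significant, ])
  structure(
    list(windows = windows, intervals = intervals,
         n_calls = nrow(intervals), fdr = fdr),
    class = "interaction_calls"
  )
}

#' @keywords internal
merge_intervals <- function(d) {
  if (nrow(d) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  d |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(g, key) {
      grp <- cumsum(c(TRUE, g$start[-1] > cummax(g$end[-nrow(g)])))
      dplyr::summarise(dplyr::group_by(g, grp = grp),
                       start = min(.data$start), end = max(.data$end),
                       .groups = "drop")[c("start", "end")]
    }) |>
    dplyr::ungroup()
}

#' @export
print.interaction_calls <- function(x, ...) {
  cat("<interaction_calls> ", sum(x$windows$significant), " significant of ",
      nrow(x$windows), " windows; ", x$n_calls,
      " merged intervals (FDR ", x$fdr, ")\n", sep = "")
  invisible(x)
}

#' @rdname far_cis_calls
#' @param x An `interaction_calls` object.
#' @param ... Unused.
#' @export
tidy.interaction_calls <- function(x, ...) x$windows

#' Average z scores onto coarser bins
#'
#' Arithmetic mean of non-missing values per non-overlapping target bin
#' (e.g. 5-kb window z scores onto 400-kb bins).
#'
#' @param data Tibble `chrom`, `start`, `end` plus the value column.
#' @param target Target bin size in bp (multiple of the source resolution).
#' @param value Name of the value column (default `"z"`).
#' @return Tibble `chrom`, `start`, `end` and the rebinned value column.
#' @export
rebin_z <- function(data, target = 4e5, value = "z") {
  src <- stats::median(data$end - data$start)
  if (target %% src != 0) {
    stop("`target` must be a multiple of the source resolution", call. = FALSE)
  }
  data |>
    dplyr::group_by(chrom = .data$chrom,
                    start = floor(.data$start / target) * target) |>
    dplyr::summarise(
      end = .data$start[1] + target,
      !!value := if (all(is.na(.data[[value]]))) NA_real_ else
        mean(.data[[value]], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(factor(.data$chrom, levels = unique(data$chrom)),
                   .data$start)
}

#' Aggregate contact submatrices around pairs of bins
#'
#' For every ordered pair (a, b) of distinct bins in `bin_ids`, extracts the
#' `(2 flank + 1)` x `(2 flank + 1)` contact submatrix centered at (a, b) and
#' averages them elementwise (missing-aware). Pairs whose submatrix falls off
#' the matrix edge are skipped. A central enrichment relative to the corners
#' larger than 1 indicates focal interactions between the bins of the set
#' (e.g. SD-SD hotspots); a random bin set on a homogeneous matrix gives a
#' ratio near 1.
#'
#' @param cm A [contact_matrix()] (aggregate analyses typically use a coarse
#'   resolution, e.g. 250 kb).
#' @param bin_ids Bin ids of the set (length >= 2).
#' @param flank Flank width in bins (default 5).
#' @return A `(2 flank + 1)` square matrix of mean contact counts, with the
#'   number of contributing pairs in attribute `n_pairs`.
#' @export
aggregate_pairs <- function(cm, bin_ids, flank = 5) {
  if (length(bin_ids) < 2) stop("need at least 2 bins", call. = FALSE)
  n <- nrow(cm$bins)
  size <- 2 * flank + 1
  acc <- matrix(0, size, size)
  cnt <- matrix(0, size, size)
  n_pairs <- 0
  for (a in bin_ids) {
    for (b in bin_ids) {
      if (a == b) next
      if (a - flank < 1 || a + flank > n || b - flank < 1 || b + flank > n) next
      sub <- as.matrix(cm$mat[(a - flank):(a + flank),
                              (b - flank):(b + flank)])
      ok <- !is.na(sub)
      acc[ok] <- acc[ok] + sub[ok]
      cnt <- cnt + ok
      n_pairs <- n_pairs + 1
    }
  }
  if (n_pairs == 0) stop("all pairs fall off the matrix edge", call. = FALSE)
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Center/corner enrichment of an aggregate submatrix
#'
#' @param m A matrix from [aggregate_pairs()].
#' @return Center value divided by the mean of the four corner values.
#' @export
center_corner_ratio <- function(m) {
  c0 <- (nrow(m) + 1) / 2
  corners <- c(m[1, 1], m[1, ncol(m)], m[nrow(m), 1], m[nrow(m), ncol(m)])
  m[c0, c0] / mean(corners, na.rm = TRUE)
}

#' Compare trans interaction counts between RT classes
#'
#' Summarizes per-viewpoint trans interaction counts by RT class and runs
#' one-sided pairwise Wilcoxon rank-sum tests with Bonferroni correction
#' (factor = number of pairwise comparisons performed). Each pair is oriented
#' so the alternative is "the class with the higher median has greater
#' counts"; classes with no viewpoints are skipped.
#'
#' @param data Tibble with one row per viewpoint: a class label column and a
#'   trans-count column.
#' @param label,n_trans Column names (defaults `"label"`, `"n_trans"`).
#' @return List with `summary` (class, n, median) and `tests` (class_a,
#'   class_b, p, p_adj), where `class_a` is the class tested as greater.
#' @export
trans_counts_by_class <- function(data, label = "label", n_trans = "n_trans") {
  d <- tibble::tibble(label = data[[label]], n = data[[n_trans]])
  d <- d[!is.na(d$label) & !is.na(d$n), ]
  summary <- d |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), median = stats::median(.data$n),
                     .groups = "drop")
  classes <- summary$label[summary$n > 0]
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    xa <- d$n[d$label == pr[1]]
    xb <- d$n[d$label == pr[2]]
    if (stats::median(xb) > stats::median(xa)) pr <- rev(pr)
    xa <- d$n[d$label == pr[1]]
    xb <- d$n[d$label == pr[2]]
    p <- suppressWarnings(
      stats::wilcox.test(xa, xb, alternative = "greater")$p.value
    )
    tibble::tibble(class_a = pr[1], class_b = pr[2], p = p)
  })
  tests$p_adj <- pmin(tests$p * nrow(tests), 1)
  list(summary = summary, tests = tests)
}
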