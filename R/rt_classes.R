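#' Classify ESC-to-NSC replication-timing changes per bin
#'
#' Four-way classification of differentiation RT regulation from
#' replicate-mean, quantile-normalized RT profiles of the stem-cell (ESC) and
#' differentiated (NSC) state:
#'
#' * `EtoE`: RT > 0 in both;
#' * `LtoL`: RT < 0 in both;
#' * `EtoL`: ESC > 0, NSC < 0 and `esc - nsc > switch_delta`;
#' * `LtoE`: ESC < 0, NSC > 0 and `nsc - esc > switch_delta`;
#' * sign change with difference at or below `switch_delta`, or an exact-zero
#'   RT, -> `unclassified`; any missing input -> `filtered`.
#'
#' All inequalities are strict.
#'
#' @param data Tibble with `chrom`, `start`, `end` and the two RT columns.
#' @param esc,nsc Names of the ESC and NSC RT columns.
#' @param switch_delta Minimum RT difference for a switch call (default 0.5).
#' @return Tibble `chrom`, `start`, `end`, `label`.
#' @export
classify_differentiation <- function(data, esc = "rt_esc", nsc = "rt_nsc",
                                     switch_delta = 0.5) {
  e <- data[[esc]]
  n <- data[[nsc]]
  label <- dplyr::case_when(
    is.na(e) | is.na(n) ~ "filtered",
    e > 0 & n > 0 ~ "EtoE",
    e < 0 & n < 0 ~ "LtoL",
    e > 0 & n < 0 & (e - n) > switch_delta ~ "EtoL",
    e < 0 & n > 0 & (n - e) > switch_delta ~ "LtoE",
    .default = "unclassified"
  )
  dplyr::mutate(dplyr::select(data, "chrom", "start", "end"), label = label)
}

#' Classify SmcHD1 dependence of replication timing per bin
#'
#' Combines the differentiation classes (WT ESC vs WT NSC) with the RT shift
#' in the SmcHD1-mutant NSC. A bin is SmcHD1-"affected" when the mutant
#' replicates it earlier by more than `affected_delta`
#' (`rt_ko - rt_wt > affected_delta`, signed; set `absolute = TRUE` to use
#' `|rt_ko - rt_wt|`). Classes:
#'
#' * `SD`: EtoL and affected (SmcHD1-dependent late replication);
#' * `SI`: EtoL and not affected;
#' * `CL`: LtoL and not affected (constitutively late);
#' * `CE`: EtoE and not affected (constitutively early);
#' * affected but not EtoL -> `affected_other`;
#' * `LtoE` and `unclassified` pass through; missing input -> `filtered`.
#'
#' @param data Tibble with `chrom`, `start`, `end` and the three RT columns.
#' @param esc,wt_nsc,ko_nsc Names of the ESC, WT-NSC and mutant-NSC RT
#'   columns.
#' @param switch_delta Differentiation switch threshold (default 0.5).
#' @param affected_delta RT-reversal threshold (default 0.4).
#' @param absolute Use `|rt_ko - rt_wt|` instead of the signed difference.
#' @return Tibble `chrom`, `start`, `end`, `label`.
#' @export
classify_smchd1 <- function(data, esc = "rt_esc", wt_nsc = "rt_wt_nsc",
                            ko_nsc = "rt_ko_nsc", switch_delta = 0.5,
                            affected_delta = 0.4, absolute = FALSE) {
  diff_track <- classify_differentiation(data, esc = esc, nsc = wt_nsc,
                                         switch_delta = switch_delta)
  delta <- data[[ko_nsc]] - data[[wt_nsc]]
  if (absolute) delta <- abs(delta)
  affected <- delta > affected_delta
  base <- diff_track$label
  label <- dplyr::case_when(
    base == "filtered" | is.na(data[[ko_nsc]]) ~ "filtered",
    base == "EtoL" & affected ~ "SD",
    base == "EtoL" ~ "SI",
    affected ~ "affected_other",
    base == "LtoL" ~ "CL",
    base == "EtoE" ~ "CE",
    .default = base  # LtoE, unclassified
  )
  dplyr::mutate(dplyr::select(data, "chrom", "start", "end"), label = label)
}

#' Summarize class spans
#'
#' Counts bins per class label and reports the genomic span each class
#' covers, `span_mb = bin_count * bin_size / 1e6` (exact arithmetic on the
#' fixed bin width).
#'
#' @param track Class track from [classify_differentiation()] or
#'   [classify_smchd1()].
#' @param bin_size Bin width in bp; default inferred from the track.
#' @return Tibble `label`, `bin_count`, `span_mb`.
#' @export
class_spans <- function(track, bin_size = NULL) {
  bin_size <- bin_size %||% bin_size_of(track)
  track |>
    dplyr::count(.data$label, name = "bin_count") |>
    dplyr::mutate(span_mb = .data$bin_count * bin_size / 1e6)
}
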