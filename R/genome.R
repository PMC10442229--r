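#' Build a binned genome model
#'
#' Tiles each chromosome with fixed-width, non-overlapping bins in 0-based
#' half-open coordinates. A terminal partial bin (chromosome length not a
#' multiple of `bin_size`) is dropped, so every bin has exactly `bin_size`
#' width. Bin order is (chromosome order as given, start ascending), and
#' `bin_id` numbers bins consecutively in that order.
#'
#' @param chromosomes A data frame with columns `chrom` (character) and
#'   `length` (bp), one row per chromosome, in the desired order. A named
#'   numeric vector of lengths is also accepted.
#' @param bin_size Bin width in bp (positive integer).
#' @param x_chrom Name(s) of the X chromosome(s); matching bins get
#'   `is_x = TRUE`. Default `"chrX"`.
#'
#' @return A tibble with columns `bin_id`, `chrom`, `start`, `end`, `is_x`,
#'   carrying the bin size in attribute `bin_size`.
#' @examples
#' make_genome(c(chr1 = 4e6, chrX = 2e6), bin_size = 4e5)
#' @export
make_genome <- function(chromosomes, bin_size, x_chrom = "chrX") {
  if (!is.data.frame(chromosomes)) {
    chromosomes <- tibble::tibble(
      chrom = names(chromosomes) %||% paste0("chr", seq_along(chromosomes)),
      length = as.numeric(chromosomes)
    )
  }
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  bin_size <- as.numeric(bin_size)
  if (length(bin_size) != 1 || !is.finite(bin_size) || bin_size <= 0) {
    stop("`bin_size` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(chromosomes$length) | chromosomes$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (any(chromosomes$length < bin_size)) {
    stop("every chromosome must be at least one bin long", call. = FALSE)
  }
  bins <- purrr::pmap_dfr(chromosomes, function(chrom, length, ...) {
    n <- floor(length / bin_size)
    tibble::tibble(
      chrom = chrom,
      start = bin_size * (seq_len(n) - 1),
      end = bin_size * seq_len(n)
    )
  })
  bins <- dplyr::mutate(bins,
    bin_id = dplyr::row_number(),
    is_x = .data$chrom %in% x_chrom,
    .before = 1
  )
  attr(bins, "bin_size") <- bin_size
  bins
}

#' @keywords internal
bin_size_of <- function(bins) {
  bs <- attr(bins, "bin_size")
  if (is.null(bs)) bs <- stats::median(bins$end - bins$start)
  bs
}

# Shared-grid check used by every pairwise-profile operation.
#' @keywords internal
check_same_grid <- function(a, b) {
  if (nrow(a) != nrow(b) ||
      !identical(as.character(a$chrom), as.character(b$chrom)) ||
      !identical(as.numeric(a$start), as.numeric(b$start)) ||
      !identical(as.numeric(a$end), as.numeric(b$end))) {
    stop("inputs are not on the same bin grid", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
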