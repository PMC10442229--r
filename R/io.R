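#' Binned contact matrix
#'
#' A symmetric, non-negative counts matrix over a bin index. Constructed
#' either from a dense/sparse matrix or from triplet records
#' `(bin_id_1, bin_id_2, count)`. Triplets are symmetrized: if both triangles
#' are supplied they must agree (otherwise the elementwise maximum is taken
#' with a warning); a single triangle is mirrored; duplicate `(i, j)` entries
#' are summed with a warning.
#'
#' @param bins Bin table from [make_genome()] (columns `bin_id`, `chrom`,
#'   `start`, `end`).
#' @param triplets Tibble with columns `bin_id_1`, `bin_id_2`, `count`.
#' @param mat Alternatively, an `n x n` matrix (dense or `Matrix` sparse).
#' @return A `contact_matrix` object: list with `bins` and sparse `mat`.
#' @export
contact_matrix <- function(bins, triplets = NULL, mat = NULL) {
  n <- nrow(bins)
  if (is.null(mat)) {
    stopifnot(!is.null(triplets))
    i <- as.integer(triplets$bin_id_1)
    j <- as.integer(triplets$bin_id_2)
    x <- as.numeric(triplets$count)
    if (any(is.na(i) | is.na(j) | i < 1 | i > n | j < 1 | j > n)) {
      stop("unknown bin id in triplets", call. = FALSE)
    }
    if (any(x < 0)) stop("counts must be >= 0", call. = FALSE)
    df <- tibble::tibble(i = i, j = j, x = x)
    if (anyDuplicated(df[c("i", "j")]) > 0) {
      warning("duplicate (i, j) triplet entries summed")
      df <- dplyr::summarise(dplyr::group_by(df, .data$i, .data$j),
                             x = sum(.data$x), .groups = "drop")
    }
    # canonicalize to the upper triangle; entries mirrored across the
    # diagonal must agree, otherwise take the maximum with a warning
    df$tri <- ifelse(df$i == df$j, "d", ifelse(df$i < df$j, "u", "l"))
    canon <- tibble::tibble(i = pmin(df$i, df$j), j = pmax(df$i, df$j),
                            x = df$x, tri = df$tri)
    merged <- canon |>
      dplyr::group_by(.data$i, .data$j) |>
      dplyr::summarise(
        mismatch = dplyr::n_distinct(.data$x) > 1 && all(c("u", "l") %in% .data$tri),
        x = max(.data$x), .groups = "drop"
      )
    if (any(merged$mismatch)) {
      warning("mismatching upper/lower triangle entries; taking the maximum")
    }
    up <- Matrix::sparseMatrix(i = merged$i, j = merged$j, x = merged$x,
                               dims = c(n, n))
    mat <- up + Matrix::t(Matrix::triu(up, 1))
  } else {
    stopifnot(nrow(mat) == n, ncol(mat) == n)
    if (!isTRUE(Matrix::isSymmetric(mat, tol = 0))) {
      stop("contact matrix must be symmetric", call. = FALSE)
    }
    mat <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix")
  }
  structure(list(bins = bins, mat = mat), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", nrow(x$bins), " bins, ",
      format(sum(x$mat) / 2, big.mark = ","), " total contacts\n", sep = "")
  invisible(x)
}

#' Tidy a contact matrix into triplet records
#'
#' @param x A [contact_matrix()].
#' @param ... Unused.
#' @return Tibble `bin_id_1`, `bin_id_2`, `count` (upper triangle incl.
#'   diagonal, nonzero entries only).
#' @export
tidy.contact_matrix <- function(x, ...) {
  tm <- methods::as(Matrix::triu(x$mat), "TsparseMatrix")
  tibble::tibble(bin_id_1 = tm@i + 1L, bin_id_2 = tm@j + 1L,
                 count = tm@x) |>
    dplyr::filter(.data$count != 0) |>
    dplyr::arrange(.data$bin_id_1, .data$bin_id_2)
}

#' Read and write bedGraph tracks
#'
#' bedGraph records are 4-column, tab-separated, 0-based half-open
#' `(chrom, start, end, value)`. Reading validates every line and reports the
#' first malformed one by number; records are sorted by `(chrom, start)` but
#' otherwise preserved (overlaps are not merged). Missing values are written
#' as the sentinel `NA` and read back as missing.
#'
#' @param path File path.
#' @param data Tibble with columns `chrom`, `start`, `end` and one value
#'   column (default the 4th column).
#' @param value Name of the value column to write (default: 4th column).
#' @return `read_bedgraph()`: a tibble `chrom`, `start`, `end`, `value`.
#'   `write_bedgraph()`: `path`, invisibly.
#' @export
read_bedgraph <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) != 4)
  if (length(bad) > 0) {
    stop(sprintf("malformed bedGraph line %d: expected 4 tab-separated fields",
                 bad[1]), call. = FALSE)
  }
  m <- matrix(unlist(fields), ncol = 4, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(ifelse(m[, 4] == "NA", NA, m[, 4])))
  bad <- which(is.na(start) | is.na(end) | (is.na(value) & m[, 4] != "NA"))
  if (length(bad) > 0) {
    stop(sprintf("malformed bedGraph line %d: non-numeric field", bad[1]),
         call. = FALSE)
  }
  tibble::tibble(chrom = m[, 1], start = start, end = end, value = value) |>
    dplyr::arrange(factor(.data$chrom, levels = unique(.data$chrom)),
                   .data$start)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(data, path, value = NULL) {
  value <- value %||% names(data)[4]
  out <- dplyr::arrange(data,
                        factor(.data$chrom, levels = unique(.data$chrom)),
                        .data$start)
  lines <- sprintf("%s\t%s\t%s\t%s", out$chrom,
                   format(out$start, scientific = FALSE, trim = TRUE),
                   format(out$end, scientific = FALSE, trim = TRUE),
                   ifelse(is.na(out[[value]]), "NA",
                          format(out[[value]], scientific = FALSE, trim = TRUE,
                                 digits = 10)))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write triplet contact matrices
#'
#' On-disk format: a bin table TSV (`bin_id`, `chrom`, `start`, `end`) plus a
#' triplet TSV (`bin_id_1`, `bin_id_2`, `count`). See [contact_matrix()] for
#' the symmetrization rules applied on read.
#'
#' @param triplet_path,bins_path File paths.
#' @param x A [contact_matrix()].
#' @return `read_contact_matrix()`: a [contact_matrix()].
#'   `write_contact_matrix()`: `triplet_path`, invisibly.
#' @export
read_contact_matrix <- function(triplet_path, bins_path) {
  bins <- readr::read_tsv(bins_path, col_types = "icdd")
  trip <- readr::read_tsv(triplet_path, col_types = "iid")
  contact_matrix(bins, triplets = trip)
}

#' @rdname read_contact_matrix
#' @export
write_contact_matrix <- function(x, triplet_path, bins_path) {
  readr::write_tsv(dplyr::select(x$bins, "bin_id", "chrom", "start", "end"),
                   bins_path)
  readr::write_tsv(tidy.contact_matrix(x), triplet_path)
  invisible(triplet_path)
}

#' Read and write BED feature files
#'
#' Minimal BED support: 3-6 columns, 0-based half-open; column 4 (if present)
#' is the feature name, column 5 a score or category.
#'
#' @param path File path.
#' @param data Tibble with at least `chrom`, `start`, `end`; optional `name`
#'   and `category`.
#' @export
read_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"))
  out <- tibble::tibble(chrom = raw$X1, start = as.numeric(raw$X2),
                        end = as.numeric(raw$X3))
  if (ncol(raw) >= 4) out$name <- raw$X4
  if (ncol(raw) >= 5) out$category <- raw$X5
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(data, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "category"),
                    names(data))
  readr::write_tsv(data[cols], path, col_names = FALSE)
  invisible(path)
}
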