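#' Fit chromosome replication kinetics (T10-90%)
#'
#' Models a chromosome's percentage-replication score as a function of the
#' whole-genome percentage replication across single cells. Cells are ranked
#' by genome score and split into `n_groups` equal-count groups (remainder
#' cells go to the earliest groups; ties keep input order); group means form
#' the fitted points, to which the two pseudo points (0, 0) and (100, 100)
#' are appended to pin the start and end of S. Two models are available:
#'
#' * `linear`: `y = a x + b` by least squares (Xa/autosome-like gradual
#'   kinetics);
#' * `sigmoid`: `y = 100 / (1 + exp(-k (x - x0)))` by Levenberg-Marquardt
#'   least squares (Xi-like abrupt kinetics).
#'
#' T10-90% is the S-phase time taken to go from 10% to 90% fitted
#' replication, `(x(90) - x(10)) / 100 * s_hours`, clamped to `[0, s_hours]`.
#' For the sigmoid this equals `(2 log(9) / k) / 100 * s_hours`.
#'
#' @param data Tibble of cells with the genome and chromosome
#'   percentage-replication columns.
#' @param x,y Column names: genome score (x) and chromosome score (y).
#' @param model `"linear"` or `"sigmoid"`.
#' @param n_groups Number of equal-count cell groups (default 18). With fewer
#'   cells than groups, each cell forms its own group.
#' @param s_hours S-phase duration in hours (default 10).
#' @param pseudo_points Append (0, 0) and (100, 100) (default `TRUE`).
#' @return A `kinetics_fit` object; see [tidy.kinetics_fit()] and
#'   [glance.kinetics_fit()].
#' @export
fit_t1090 <- function(data, x = "genome_pct", y = "chrom_pct",
                      model = c("linear", "sigmoid"), n_groups = 18,
                      s_hours = 10, pseudo_points = TRUE) {
  model <- match.arg(model)
  xv <- data[[x]]
  yv <- data[[y]]
  stopifnot(!anyNA(xv), !anyNA(yv))
  n <- length(xv)
  g <- min(n_groups, n)
  ord <- order(xv)  # stable: ties keep input (cell id) order
  sizes <- rep(n %/% g, g) + (seq_len(g) <= n %% g)
  grp <- rep(seq_len(g), sizes)
  points <- tibble::tibble(
    x = tapply(xv[ord], grp, mean),
    y = tapply(yv[ord], grp, mean),
    pseudo = FALSE
  )
  if (pseudo_points) {
    points <- dplyr::bind_rows(
      tibble::tibble(x = 0, y = 0, pseudo = TRUE),
      points,
      tibble::tibble(x = 100, y = 100, pseudo = TRUE)
    )
  }
  if (nrow(points) < 3) stop("need at least 3 points to fit", call. = FALSE)

  if (model == "linear") {
    fit <- stats::lm(y ~ x, data = points)
    a <- unname(stats::coef(fit)[2])
    b <- unname(stats::coef(fit)[1])
    if (a <= 0) stop("non-increasing linear fit; cannot place 10%/90% crossings",
                     call. = FALSE)
    t1090 <- ((90 - b) / a - (10 - b) / a) / 100 * s_hours
    pars <- c(slope = a, intercept = b)
  } else {
    starts <- sigmoid_starts(points$x, points$y)
    fit <- NULL
    errs <- character(0)
    for (start in starts) {
      fit <- tryCatch(
        minpack.lm::nlsLM(y ~ 100 / (1 + exp(-k * (x - x0))),
                          data = points, start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) {
          errs <<- c(errs, sprintf("start (k = %.3g, x0 = %.3g): %s",
                                   start$k, start$x0, conditionMessage(e)))
          NULL
        }
      )
      if (!is.null(fit)) break
    }
    if (is.null(fit)) {
      stop("sigmoid fit did not converge; attempts:\n  ",
           paste(errs, collapse = "\n  "), call. = FALSE)
    }
    k <- unname(stats::coef(fit)["k"])
    x0 <- unname(stats::coef(fit)["x0"])
    if (k <= 0) stop("non-increasing sigmoid fit (k <= 0)", call. = FALSE)
    t1090 <- (2 * log(9) / k) / 100 * s_hours
    pars <- c(k = k, x0 = x0)
  }
  structure(
    list(model = model, fit = fit, parameters = pars, points = points,
         n_cells = n, n_groups = g, pseudo_points = pseudo_points,
         s_hours = s_hours,
         t1090 = min(max(t1090, 0), s_hours)),
    class = "kinetics_fit"
  )
}

# Start values for the sigmoid fit: logit linearization, the slope at the
# 50% crossing (sharp transitions), then fixed fallbacks.
#' @keywords internal
sigmoid_starts <- function(x, y) {
  x05 <- x[which.min(abs(y - 50))]
  yc <- pmin(pmax(y, 0.5), 99.5)
  z <- log(yc / (100 - yc))
  cf <- stats::coef(stats::lm(z ~ x))
  k_lin <- unname(cf[2])
  x0_lin <- if (is.finite(k_lin) && k_lin > 0) -unname(cf[1]) / k_lin else x05
  if (!is.finite(k_lin) || k_lin <= 0) k_lin <- 0.1
  ord <- order(x)
  dz <- diff(z[ord]) / diff(x[ord])
  k_steep <- max(dz[is.finite(dz)], 0.05)
  starts <- c(
    list(list(k = k_lin, x0 = clamp01(x0_lin)),
         list(k = k_steep, x0 = x05)),
    lapply(c(0.05, 0.2, 1, 5), function(k) list(k = k, x0 = x05))
  )
  starts
}

#' @keywords internal
clamp01 <- function(x0) min(max(x0, 0), 100)

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit> ", x$model, " model, ", x$n_cells, " cells in ",
      x$n_groups, " groups\n", sep = "")
  cat("  T10-90% = ", sprintf("%.2f", x$t1090), " h (S = ", x$s_hours,
      " h)\n", sep = "")
  invisible(x)
}

#' Tidy a kinetics fit
#'
#' @param x A [fit_t1090()] result.
#' @param ... Unused.
#' @return One row per model parameter (`term`, `estimate`).
#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble::tibble(term = names(x$parameters),
                 estimate = unname(x$parameters))
}

#' @rdname tidy.kinetics_fit
#' @importFrom generics glance
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble::tibble(model = x$model, t1090 = x$t1090, s_hours = x$s_hours,
                 n_cells = x$n_cells, n_groups = x$n_groups,
                 sigma = summary_sigma(x$fit))
}

#' @keywords internal
summary_sigma <- function(fit) {
  out <- tryCatch(stats::sigma(fit), error = function(e) NA_real_)
  as.numeric(out)
}

#' Plot a kinetics fit
#'
#' Grouped (and pseudo) points with the fitted replication-kinetics curve.
#'
#' @param object A [fit_t1090()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.kinetics_fit <- function(object, ...) {
  grid <- tibble::tibble(x = seq(0, 100, by = 0.5))
  grid$y <- stats::predict(object$fit, newdata = grid)
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_line(data = grid, color = "red") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$pseudo)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::labs(
      x = "genome replication (%)", y = "chromosome replication (%)",
      shape = "pseudo point",
      title = sprintf("%s fit: T10-90%% = %.2f h", object$model, object$t1090)
    ) +
    ggplot2::theme_minimal()
}

#' Single-cell RT values from per-bin percentage replication
#'
#' Ranks bins from the highest (earliest-replicating) to the lowest
#' percentage replication, splits them into one-percentile equal-count groups
#' (tied values share a group), assigns each group its mean percentage
#' replication, and converts that to an S-phase time
#' `scrt = (100 - mean_p) / 100 * s_hours`, rounded half-up to 0.1 h. The
#' result is a non-increasing step function of `p` with range in
#' `[0, s_hours]`.
#'
#' @param data Tibble with a per-bin percentage-replication column (`NA`
#'   rows pass through as `NA`).
#' @param p Name of the percentage column (values in \[0, 100\]).
#' @param s_hours S-phase duration (default 10).
#' @param n_groups Number of percentile groups (default 100; capped at the
#'   number of scored bins).
#' @return `data` with an added `scrt` column (hours).
#' @export
scrt_values <- function(data, p = "p", s_hours = 10, n_groups = 100) {
  pv <- data[[p]]
  ok <- !is.na(pv)
  if (!any(ok)) stop("no non-missing percentage values", call. = FALSE)
  if (any(pv[ok] < 0 | pv[ok] > 100)) {
    stop("percentage values must lie in [0, 100]", call. = FALSE)
  }
  n <- sum(ok)
  g <- min(n_groups, n)
  # ties.method = "min" puts tied p values into the same percentile group
  rk <- rank(-pv[ok], ties.method = "min")
  grp <- ceiling(rk * g / n)
  mean_p <- tapply(pv[ok], grp, mean)
  scrt <- rep(NA_real_, length(pv))
  scrt[ok] <- round_half_up((100 - mean_p[as.character(grp)]) / 100 * s_hours, 1)
  dplyr::mutate(data, scrt = scrt)
}

#' @keywords internal
round_half_up <- function(x, digits) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}
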