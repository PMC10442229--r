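#' Binarize a single cell's binned counts against a G1 reference
#'
#' Computes the library-size-scaled per-bin ratio of the cell's counts to the
#' G1 reference, log2-transforms it (with a 0.5 pseudocount on both counts),
#' and segments the values along each chromosome with a two-state Gaussian
#' hidden Markov model (fixed sticky self-transition probability, emission
#' means/sds re-estimated by EM, posterior decoding). The state with the
#' higher mean log-ratio is called replicated (doubled copy number).
#'
#' The FACS gate supplies a prior on which state should be the majority
#' state: `early` cells are mostly unreplicated, `mid`/`late` cells mostly
#' replicated. A real unreplicated/replicated split sits ~1 log2 unit apart
#' (doubled copy number); when the two fitted state means are closer than
#' `min_sep`, the split is noise rather than copy number, and the gate
#' constraint relabels the cell: every scored bin is assigned to the gate's
#' majority state. With clearly separated states the emission means decide
#' which state is replicated and the gate is not needed.
#'
#' Bins with zero G1 coverage are returned as missing. A degenerate HMM fit
#' (a state collapsing to zero weight) falls back to a two-means threshold
#' with a warning; constant input is assigned entirely to the gate's
#' majority state.
#'
#' @param data Tibble with `chrom`, `start`, `end` and the two count columns.
#' @param gate FACS gate of the cell: `"early"`, `"mid"` or `"late"`.
#' @param count,g1 Names of the cell and G1-reference count columns.
#' @param self_trans HMM self-transition probability (default 0.99).
#' @param min_sep Minimum state-mean separation (log2 units) for a credible
#'   two-somy split (default 0.6).
#' @return Tibble `chrom`, `start`, `end`, `state` (0, 1 or `NA`).
#' @export
binarize_cell <- function(data, gate = c("early", "mid", "late"),
                          count = "count", g1 = "g1", self_trans = 0.99,
                          min_sep = 0.6) {
  gate <- match.arg(gate)
  cnt <- data[[count]]
  ref <- data[[g1]]
  ok <- !is.na(ref) & ref > 0 & !is.na(cnt)
  y <- rep(NA_real_, nrow(data))
  y[ok] <- log2(((cnt[ok] + 0.5) / sum(cnt[ok] + 0.5)) /
                  ((ref[ok] + 0.5) / sum(ref[ok] + 0.5)))
  state <- rep(NA_integer_, nrow(data))
  state[ok] <- decode_two_state(y[ok], as.character(data$chrom)[ok],
                                gate, self_trans, min_sep)
  dplyr::mutate(dplyr::select(data, "chrom", "start", "end"), state = state)
}

# Two-state Gaussian HMM fit + decoding shared by binarize_cell.
#' @keywords internal
decode_two_state <- function(y, chrom, gate, self_trans, min_sep) {
  n <- length(y)
  majority_should_be <- if (gate == "early") 0L else 1L
  if (stats::sd(y) < 1e-8) {
    warning("constant log-ratio input; assigning all bins to the gate's majority state")
    return(rep(majority_should_be, n))
  }
  runs <- split(seq_len(n), factor(chrom, levels = unique(chrom)))
  trans <- matrix(c(self_trans, 1 - self_trans,
                    1 - self_trans, self_trans), 2, 2, byrow = TRUE)
  med <- stats::median(y)
  # deterministic restarts covering early (mostly-low), mid and late
  # (mostly-high) cells; a doubled copy number is +1 in log2
  inits <- list(unname(stats::quantile(y, c(0.25, 0.75))),
                c(med, med + 1), c(med - 1, med))

  best <- NULL
  for (mu0 in inits) {
    if (diff(mu0) < 1e-6) mu0 <- mu0 + c(-0.1, 0.1)
    fit <- em_two_state(y, runs, mu0,
                        rep(max(stats::sd(y) / 2, 1e-3), 2), trans)
    if (!fit$degenerate && (is.null(best) || fit$loglik > best$loglik)) {
      best <- fit
    }
  }
  degenerate <- is.null(best)
  if (!degenerate) {
    mu <- best$mu
    gam <- best$gam
  }
  if (degenerate) {
    warning("degenerate HMM fit; falling back to a two-means threshold")
    cent <- two_means(y)
    if (abs(diff(cent)) < min_sep) return(rep(majority_should_be, n))
    return(as.integer(y > mean(cent)))
  }
  if (abs(diff(mu)) < min_sep) {
    # no credible copy-number split: single-state cell, labeled by the gate
    return(rep(majority_should_be, n))
  }
  hi <- which.max(mu)
  as.integer(max.col(gam) == hi)
}

# EM on the emission parameters with fixed transitions; returns posteriors,
# fitted means and the data log-likelihood.
#' @keywords internal
em_two_state <- function(y, runs, mu, sigma, trans, max_iter = 100) {
  n <- length(y)
  gam <- NULL
  loglik <- -Inf
  for (iter in seq_len(max_iter)) {
    gam <- matrix(NA_real_, n, 2)
    loglik <- 0
    for (idx in runs) {
      fb <- fb_posterior(y[idx], mu, sigma, trans)
      gam[idx, ] <- fb$gamma
      loglik <- loglik + fb$loglik
    }
    w <- colSums(gam)
    if (any(w < 1e-8)) {
      return(list(degenerate = TRUE, loglik = -Inf))
    }
    mu_new <- colSums(gam * y) / w
    sigma_new <- pmax(sqrt(colSums(gam * (outer(y, mu_new, "-"))^2) / w), 1e-3)
    done <- max(abs(mu_new - mu)) < 1e-6
    mu <- mu_new
    sigma <- sigma_new
    if (done) break
  }
  list(degenerate = abs(diff(mu)) < 1e-6, mu = mu, sigma = sigma,
       gam = gam, loglik = loglik)
}

# Scaled forward-backward posterior for one chromosome.
#' @keywords internal
fb_posterior <- function(y, mu, sigma, trans) {
  n <- length(y)
  em <- cbind(stats::dnorm(y, mu[1], sigma[1]),
              stats::dnorm(y, mu[2], sigma[2])) + 1e-300
  alpha <- matrix(0, n, 2)
  beta <- matrix(0, n, 2)
  norms <- numeric(n)
  a1 <- 0.5 * em[1, ]
  norms[1] <- sum(a1)
  alpha[1, ] <- a1 / norms[1]
  if (n > 1) {
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% trans) * em[t, ]
      norms[t] <- sum(a)
      alpha[t, ] <- a / norms[t]
    }
  }
  beta[n, ] <- 1
  if (n > 1) {
    for (t in (n - 1):1) {
      b <- trans %*% (em[t + 1, ] * beta[t + 1, ])
      beta[t, ] <- b / sum(b)
    }
  }
  g <- alpha * beta
  list(gamma = g / rowSums(g), loglik = sum(log(norms)))
}

# Deterministic Lloyd 2-means on a vector (quantile-initialized).
#' @keywords internal
two_means <- function(y) {
  cent <- unname(stats::quantile(y, c(0.25, 0.75)))
  for (i in seq_len(50)) {
    assign <- y > mean(cent)
    if (all(assign) || !any(assign)) return(cent)
    new <- c(mean(y[!assign]), mean(y[assign]))
    if (max(abs(new - cent)) < 1e-10) break
    cent <- new
  }
  cent
}

#' Binarize many cells at once
#'
#' Applies [binarize_cell()] to each row of a cells x bins count matrix.
#'
#' @param counts Cells x bins integer matrix.
#' @param bins Bin table from [make_genome()].
#' @param g1 G1-reference counts per bin.
#' @param gates Per-cell gate labels (recycled).
#' @param ... Passed on to [binarize_cell()].
#' @return Cells x bins matrix of states (0, 1, `NA`).
#' @export
binarize_cells <- function(counts, bins, g1, gates, ...) {
  gates <- rep_len(gates, nrow(counts))
  out <- matrix(NA_integer_, nrow(counts), ncol(counts))
  for (i in seq_len(nrow(counts))) {
    df <- dplyr::mutate(dplyr::select(bins, "chrom", "start", "end"),
                        count = counts[i, ], g1 = g1)
    out[i, ] <- binarize_cell(df, gate = gates[i], ...)$state
  }
  out
}

#' Percentage replication of one cell
#'
#' `100 * replicated / non-missing` over the bins selected by `mask`
#' (logical; default all). Use the mask to exclude the X chromosome when
#' scoring whole-genome S-phase progression.
#'
#' @param states Per-bin states (0, 1, `NA`).
#' @param mask Optional logical vector selecting the bins to score.
#' @return Percentage in \[0, 100\].
#' @export
percent_replication <- function(states, mask = NULL) {
  if (!is.null(mask)) states <- states[mask]
  ok <- !is.na(states)
  if (!any(ok)) stop("no non-missing bins in mask", call. = FALSE)
  100 * sum(states[ok]) / sum(ok)
}

#' Per-bin percentage replication across cells
#'
#' For each bin, the percentage of cells (with a non-missing state) that have
#' replicated it.
#'
#' @param states Cells x bins matrix of states (0, 1, `NA`).
#' @param bins Optional bin table; if given, returned as a tibble column `p`.
#' @return Numeric vector `p` (or tibble `chrom`, `start`, `end`, `p`), `NA`
#'   for bins missing in every cell.
#' @export
per_bin_percent_replication <- function(states, bins = NULL) {
  if (nrow(states) < 1) stop("need >= 1 cell", call. = FALSE)
  n_ok <- colSums(!is.na(states))
  p <- ifelse(n_ok == 0, NA_real_,
              100 * colSums(states == 1, na.rm = TRUE) / n_ok)
  if (is.null(bins)) return(p)
  dplyr::mutate(dplyr::select(bins, "chrom", "start", "end"), p = p)
}
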