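#' Replication programs
#'
#' A replication program assigns every bin of a genome a latent replication
#' time (hours into S phase) and describes its cell-to-cell variability. Two
#' kinds are supported:
#'
#' * `graded_program()`: the ordinary autosomal/Xa-like program. Each bin has
#'   a mean replication time `t` and a logistic onset jitter with scale
#'   `noise_sd`, so a cell at S-phase fraction `f` has replicated the bin with
#'   probability `plogis((f * s_hours - t) / noise_sd)`.
#' * `xi_program()`: the inactive-X-like program. Each cell draws a single
#'   chromosome-wide onset `o` from a Normal(onset_mean, onset_sd) truncated
#'   to the second half of S, and each X bin replicates at `o + u` with
#'   `u ~ Uniform(0, duration)` -- rapid, near-uniform late replication with
#'   cell-to-cell onset jitter. Non-X bins (if present) follow the graded
#'   model with times `autosome_t`.
#'
#' @param genome A bin table from [make_genome()].
#' @param t,autosome_t Per-bin mean replication times in hours. Default: an
#'   even gradient across the (non-X) bins spanning most of S.
#' @param s_hours S-phase duration in hours (default 10).
#' @param noise_sd Logistic onset-jitter scale in hours (>= 0).
#' @param onset_mean,onset_sd Mean and sd (hours) of the per-cell Xi onset;
#'   the draw is truncated to `[s_hours/2, s_hours]`.
#' @param duration Xi replication duration `d` in hours (>= 0): within one
#'   cell, all Xi bins replicate inside `[o, o + d]`.
#'
#' @return A `replication_program` object (a list of parameters plus the
#'   per-bin time vector, `NA` for Xi-model bins).
#' @name replication-programs
NULL

#' @rdname replication-programs
#' @export
graded_program <- function(genome, t = NULL, s_hours = 10, noise_sd = 0.5) {
  n <- nrow(genome)
  if (is.null(t)) t <- seq(0.05, 0.95, length.out = n) * s_hours
  stopifnot(length(t) == n)
  if (any(t < 0 | t > s_hours)) {
    stop("bin replication times must lie in [0, s_hours]", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(kind = "graded", s_hours = s_hours, noise_sd = noise_sd, t = t),
    class = "replication_program"
  )
}

#' @rdname replication-programs
#' @export
xi_program <- function(genome, onset_mean = 7, onset_sd = 0.75, duration = 2,
                       s_hours = 10, autosome_t = NULL, noise_sd = 0.5) {
  if (onset_sd < 0 || duration < 0 || noise_sd < 0) {
    stop("`onset_sd`, `duration` and `noise_sd` must be >= 0", call. = FALSE)
  }
  if (onset_mean < 0 || onset_mean > s_hours) {
    stop("`onset_mean` must lie in [0, s_hours]", call. = FALSE)
  }
  n_auto <- sum(!genome$is_x)
  t <- rep(NA_real_, nrow(genome))
  if (n_auto > 0) {
    if (is.null(autosome_t)) {
      autosome_t <- seq(0.05, 0.95, length.out = n_auto) * s_hours
    }
    stopifnot(length(autosome_t) == n_auto)
    t[!genome$is_x] <- autosome_t
  }
  structure(
    list(
      kind = "xi_uniform_late", s_hours = s_hours, noise_sd = noise_sd, t = t,
      onset_mean = onset_mean, onset_sd = onset_sd, duration = duration
    ),
    class = "replication_program"
  )
}

# Truncated-normal sampler via inverse CDF (no extra dependency).
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  p <- stats::runif(n, stats::pnorm(lower, mean, sd), stats::pnorm(upper, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Population replication curve and true T10-90% of an Xi program
#'
#' For an Xi-like program the latent replication time of a bin in a cell is
#' `o + u` with `o ~ TruncNormal(onset_mean, onset_sd; [S/2, S])` and
#' `u ~ Uniform(0, duration)`. The population fraction-replicated curve is
#' the CDF of `o + u`; `xi_program_t1090()` returns the time between its 10%
#' and 90% quantiles -- the true T10-90% against which fitted kinetics can be
#' compared.
#'
#' @param program An `xi_program()` object.
#' @return T10-90% in hours.
#' @export
xi_program_t1090 <- function(program) {
  stopifnot(program$kind == "xi_uniform_late")
  qs <- xi_latent_quantiles(program, c(0.1, 0.9))
  qs[2] - qs[1]
}

#' @keywords internal
xi_latent_quantiles <- function(program, probs) {
  s <- program$s_hours
  d <- program$duration
  mu <- program$onset_mean
  sd <- program$onset_sd
  lo <- s / 2
  hi <- s
  # CDF of o + u by averaging the onset CDF over the uniform duration.
  ponset <- function(t) {
    if (sd == 0) return(as.numeric(t >= pmin(pmax(mu, lo), hi)))
    (stats::pnorm(pmin(pmax(t, lo), hi), mu, sd) - stats::pnorm(lo, mu, sd)) /
      (stats::pnorm(hi, mu, sd) - stats::pnorm(lo, mu, sd))
  }
  cdf <- function(t) {
    if (d == 0) return(ponset(t))
    vapply(t, function(ti) {
      stats::integrate(function(u) ponset(ti - u), 0, d,
                       rel.tol = 1e-9)$value / d
    }, numeric(1))
  }
  vapply(probs, function(p) {
    stats::uniroot(function(t) cdf(t) - p, c(lo - 1e-9, hi + d + 1e-9),
                   tol = 1e-8)$root
  }, numeric(1))
}

#' Solve the Xi duration that yields a target true T10-90%
#'
#' Inverts [xi_program_t1090()] in the duration parameter, holding onset mean
#' and sd fixed. Used to set up kinetics-recovery experiments where the
#' ground-truth T10-90% is prescribed.
#'
#' @inheritParams replication-programs
#' @param target Desired true T10-90% in hours.
#' @return The duration `d` in hours.
#' @export
xi_duration_for_t1090 <- function(target, onset_mean = 7, onset_sd = 0.75,
                                  s_hours = 10) {
  f <- function(d) {
    prog <- structure(
      list(kind = "xi_uniform_late", s_hours = s_hours,
           onset_mean = onset_mean, onset_sd = onset_sd, duration = d),
      class = "replication_program"
    )
    xi_program_t1090(prog) - target
  }
  stats::uniroot(f, c(1e-6, 2 * s_hours), tol = 1e-6)$root
}
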