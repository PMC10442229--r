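# Shared fixtures built in code.

# Spatially smooth replication landscape (sinusoidal domains), the structure
# the sticky HMM assumes of real genomes.
smooth_landscape <- function(genome, amplitude = 4.3, cycles = 2.5,
                             s_hours = 10) {
  chrom_len <- tapply(genome$end, genome$chrom, max)
  phase <- (match(genome$chrom, names(chrom_len)) - 1) * 1.3
  s_hours / 2 + amplitude *
    sin(2 * pi * cycles * genome$start / chrom_len[genome$chrom] + phase)
}

# Independent brute-force oracle for the far-cis window test: explicit
# per-window enumeration, no rolling sums.
brute_far_cis_windows <- function(cover, w, W) {
  n <- length(cover)
  half <- ceiling((W - w) / 2)
  out <- data.frame(k = rep(NA_real_, n - w + 1), n = NA_real_,
                    p_bg = NA_real_, z = NA_real_, p = NA_real_)
  for (i in seq_len(n - w + 1)) {
    win <- i:(i + w - 1)
    bg <- setdiff(max(1, i - half):min(n, i + w - 1 + half), win)
    k <- sum(cover[win], na.rm = TRUE)
    ne <- sum(!is.na(cover[win]))
    bg_n <- sum(!is.na(cover[bg]))
    p_bg <- if (bg_n == 0) NA_real_ else sum(cover[bg], na.rm = TRUE) / bg_n
    out$k[i] <- k
    out$n[i] <- ne
    out$p_bg[i] <- p_bg
    if (!is.na(p_bg) && p_bg > 0 && p_bg < 1 && ne > 0) {
      out$z[i] <- (k - ne * p_bg) / sqrt(ne * p_bg * (1 - p_bg))
      out$p[i] <- stats::pbinom(k - 1, ne, p_bg, lower.tail = FALSE)
    }
  }
  out
}

# Bernoulli-coverage profile on one chromosome for null calibration.
bernoulli_profile <- function(n, p_cover, chrom = "chrX", res = 5e3) {
  tibble::tibble(chrom = chrom, start = (seq_len(n) - 1) * res,
                 end = seq_len(n) * res,
                 signal = stats::rbinom(n, 1, p_cover))
}
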