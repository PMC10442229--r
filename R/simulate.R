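#' Simulate single-cell replication data
#'
#' Draws cells at S-phase fractions `f` (uniform on (0,1) unless fixed),
#' derives per-bin replicated states from a single latent replication time per
#' bin per cell (so replication is irreversible within a cell), and samples
#' observed read counts with expectation `depth * (1 + state)` -- replicated
#' bins carry twice the copy number of unreplicated ones.
#'
#' * graded program: latent time `t_b + Logistic(0, noise_sd)`, so the state
#'   probability at fraction `f` is `plogis((f * S - t_b) / noise_sd)`.
#' * Xi program: per cell one onset `o`, per bin `o + Uniform(0, duration)`
#'   for X bins; non-X bins follow the graded model.
#'
#' Counts are Poisson by default; `overdispersion > 0` switches to a
#' Gamma-mixed Poisson (negative binomial) with that squared coefficient of
#' variation on the rate.
#'
#' @param genome Bin table from [make_genome()].
#' @param program A [replication-programs] object.
#' @param n_cells Number of cells (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @param s_fraction Optional fixed S-phase fraction(s), recycled to
#'   `n_cells`; default uniform draws.
#' @param depth Expected reads per unreplicated bin.
#' @param overdispersion Extra-Poisson rate variance (0 = Poisson).
#'
#' @return An object of class `sc_sim`: list with `bins`, `cells` (tibble of
#'   `cell_id`, `f`, `gate`), `states`, `counts` and `latent` (cells x bins
#'   matrices; `latent` holds the underlying per-bin replication times in
#'   hours). Gates split S into thirds: early (f < 1/3), mid, late.
#' @export
simulate_cells <- function(genome, program, n_cells, seed = NULL,
                           s_fraction = NULL, depth = 50, overdispersion = 0) {
  stopifnot(inherits(program, "replication_program"), n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  n_bins <- nrow(genome)
  s <- program$s_hours
  f <- if (is.null(s_fraction)) stats::runif(n_cells) else
    rep_len(s_fraction, n_cells)

  latent <- matrix(NA_real_, n_cells, n_bins)
  grad <- !is.na(program$t)
  if (any(grad)) {
    tb <- matrix(program$t[grad], n_cells, sum(grad), byrow = TRUE)
    jit <- if (program$noise_sd > 0) {
      matrix(stats::rlogis(n_cells * sum(grad), 0, program$noise_sd),
             n_cells, sum(grad))
    } else 0
    latent[, grad] <- tb + jit
  }
  if (program$kind == "xi_uniform_late" && any(!grad)) {
    nx <- sum(!grad)
    onset <- rtruncnorm(n_cells, program$onset_mean, program$onset_sd,
                        s / 2, s)
    u <- matrix(stats::runif(n_cells * nx, 0, program$duration), n_cells, nx)
    latent[, !grad] <- onset + u
  }
  states <- (f * s >= latent) * 1L

  lambda <- depth * (1 + states)
  if (overdispersion > 0) {
    shape <- 1 / overdispersion
    lambda <- lambda * matrix(stats::rgamma(length(lambda), shape, shape),
                              n_cells, n_bins)
  }
  counts <- matrix(stats::rpois(length(lambda), lambda), n_cells, n_bins)

  gate <- cut(f, c(0, 1 / 3, 2 / 3, 1), labels = c("early", "mid", "late"),
              include.lowest = TRUE)
  structure(
    list(
      bins = genome,
      cells = tibble::tibble(
        cell_id = sprintf("cell_%03d", seq_len(n_cells)),
        f = f, gate = as.character(gate)
      ),
      states = states, counts = counts, latent = latent
    ),
    class = "sc_sim"
  )
}

#' @export
print.sc_sim <- function(x, ...) {
  cat("<sc_sim> ", nrow(x$cells), " cells x ", nrow(x$bins), " bins\n", sep = "")
  invisible(x)
}

#' Tidy a single-cell replication simulation
#'
#' @param x An `sc_sim` object.
#' @param ... Unused.
#' @return A long tibble with one row per cell-bin pair (`cell_id`, `f`,
#'   `gate`, `chrom`, `start`, `end`, `state`, `count`).
#' @importFrom generics tidy
#' @export
tidy.sc_sim <- function(x, ...) {
  nb <- nrow(x$bins)
  nc <- nrow(x$cells)
  tibble::tibble(
    cell_id = rep(x$cells$cell_id, each = nb),
    f = rep(x$cells$f, each = nb),
    gate = rep(x$cells$gate, each = nb),
    chrom = rep(x$bins$chrom, nc),
    start = rep(x$bins$start, nc),
    end = rep(x$bins$end, nc),
    state = as.integer(t(x$states)),
    count = as.integer(t(x$counts))
  )
}

#' Simulate bulk early/late BrdU-IP replication-timing counts
#'
#' Emulates population Repli-seq: cells are drawn across S, sorted into an
#' early fraction (`f < 0.5`) and a late fraction (`f >= 0.5`), and per-bin
#' read counts for each fraction are Poisson draws around the fraction's mean
#' replicated state scaled to `depth` reads per fully replicated bin.
#'
#' @inheritParams simulate_cells
#' @param depth Expected reads in a bin replicated in every cell of a
#'   fraction.
#' @return A tibble `chrom`, `start`, `end`, `early`, `late`.
#' @export
simulate_bulk <- function(genome, program, n_cells, depth = 50, seed = NULL) {
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  if (depth < 0) stop("`depth` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_cells(genome, program, n_cells, seed = NULL, depth = 0)
  early_cells <- sim$cells$f < 0.5
  frac_mean <- function(keep) {
    if (!any(keep)) rep(0, nrow(genome)) else
      colMeans(sim$states[keep, , drop = FALSE])
  }
  early <- stats::rpois(nrow(genome), depth * frac_mean(early_cells))
  late <- stats::rpois(nrow(genome), depth * frac_mean(!early_cells))
  dplyr::mutate(dplyr::select(genome, "chrom", "start", "end"),
                early = early, late = late)
}

#' Layered contact model for a structured X chromosome
#'
#' Parameterizes a synthetic genome-wide contact matrix in which cis contacts
#' decay with genomic distance by a power law and trans (interchromosomal)
#' contact rates depend on the layer label of the X bin involved -- emulating
#' a layered Xi in which one class of domains (for example SD) sits at the
#' chromosome surface and contacts other chromosomes at an elevated rate.
#' Optionally, cis contacts between pairs of bins of one layer are boosted
#' (`pair_boost`), planting the kind of long-range same-class hotspot seen
#' between protruding domains.
#'
#' @param layers Per-bin layer label (e.g. `"SD"`, `"SI"`, `"CL"`, `"CE"`),
#'   `NA` for bins outside the layered chromosome.
#' @param cis_scale Expected counts at 1-bin separation in cis.
#' @param cis_decay Power-law decay exponent for cis distance.
#' @param trans_rate Named vector of per-layer trans contact rates.
#' @param base_trans Trans rate for unlabeled (autosomal) bins.
#' @param boost_layer,pair_boost Layer whose same-layer cis pairs are
#'   multiplied by `pair_boost` (default: no boost).
#' @param hotspot_frac,hotspot_boost Fraction of unlabeled (autosomal) bins
#'   lying in contact-permissive blocks, and the factor by which contacts
#'   between the layered chromosome and those blocks are boosted. Real trans
#'   contacts concentrate at such regions; without them every viewpoint's
#'   trans coverage would be spatially flat and no window could be enriched
#'   over its own background. Blocks of `hotspot_block` consecutive bins are
#'   placed evenly along each unlabeled chromosome.
#' @param hotspot_block Width of a contact-permissive block in bins.
#' @return A `layered_contact_model` object.
#' @export
layered_contact_model <- function(layers, cis_scale = 20, cis_decay = 1,
                                  trans_rate = c(SD = 0.05, SI = 0.01,
                                                 CL = 0.01, CE = 0.01),
                                  base_trans = 0.01,
                                  boost_layer = NULL, pair_boost = 1,
                                  hotspot_frac = 0.1, hotspot_boost = 6,
                                  hotspot_block = 25) {
  if (any(c(cis_scale, trans_rate, base_trans, pair_boost,
            hotspot_boost) < 0)) {
    stop("contact rates must be >= 0", call. = FALSE)
  }
  structure(
    list(layers = layers, cis_scale = cis_scale, cis_decay = cis_decay,
         trans_rate = trans_rate, base_trans = base_trans,
         boost_layer = boost_layer, pair_boost = pair_boost,
         hotspot_frac = hotspot_frac, hotspot_boost = hotspot_boost,
         hotspot_block = hotspot_block),
    class = "layered_contact_model"
  )
}

#' Simulate a symmetric binned contact matrix
#'
#' Draws Poisson counts for every bin pair: cis pairs around
#' `cis_scale * distance^(-cis_decay)` (with the same-layer boost if
#' configured), trans pairs around `r_i * r_j / base_trans`, where `r` is the
#' per-layer trans rate for layered bins and `base_trans` otherwise. The
#' upper triangle is drawn and mirrored, so the result is exactly symmetric.
#'
#' @inheritParams simulate_cells
#' @param model A [layered_contact_model()].
#' @return A [contact_matrix()] object.
#' @export
simulate_contacts <- function(genome, model, seed = NULL) {
  stopifnot(inherits(model, "layered_contact_model"))
  if (length(unique(genome$chrom)) < 2) {
    stop("need >= 2 chromosomes for trans structure", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genome)
  stopifnot(length(model$layers) == n)
  r <- ifelse(is.na(model$layers), model$base_trans,
              unname(c(model$trans_rate, base = model$base_trans)[
                ifelse(model$layers %in% names(model$trans_rate),
                       model$layers, "base")]))
  chrom <- as.integer(factor(genome$chrom, levels = unique(genome$chrom)))
  idx <- seq_len(n)

  lam <- outer(r, r) / max(model$base_trans, 1e-12)
  # contact-permissive autosomal blocks: boost X-to-hotspot trans pairs
  layered <- !is.na(model$layers)
  if (any(!layered) && model$hotspot_frac > 0 && model$hotspot_boost != 1) {
    hot <- rep(FALSE, n)
    for (ch in unique(genome$chrom[!layered])) {
      ix <- which(genome$chrom == ch & !layered)
      n_blocks <- max(1, round(length(ix) * model$hotspot_frac /
                                 model$hotspot_block))
      starts <- round(seq(1, length(ix) - model$hotspot_block + 1,
                          length.out = n_blocks))
      for (s in starts) hot[ix[s:(s + model$hotspot_block - 1)]] <- TRUE
    }
    xh <- outer(layered, hot, "&") | outer(hot, layered, "&")
    lam[xh] <- lam[xh] * model$hotspot_boost
  }
  same <- outer(chrom, chrom, "==")
  dist_bins <- abs(outer(idx, idx, "-"))
  cis_lam <- model$cis_scale * pmax(dist_bins, 1)^(-model$cis_decay)
  if (!is.null(model$boost_layer) && model$pair_boost != 1) {
    in_layer <- !is.na(model$layers) & model$layers == model$boost_layer
    boost_pair <- outer(in_layer, in_layer, "&")
    cis_lam[boost_pair] <- cis_lam[boost_pair] * model$pair_boost
  }
  lam[same] <- cis_lam[same]

  upper <- upper.tri(lam, diag = TRUE)
  counts <- matrix(0, n, n)
  counts[upper] <- stats::rpois(sum(upper), lam[upper])
  counts <- counts + t(counts) - diag(diag(counts))
  contact_matrix(genome, mat = Matrix::Matrix(counts, sparse = TRUE))
}
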