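test_that("noiseless two-level counts binarize exactly", {
  g <- make_genome(c(chr1 = 8e6), 1e5)
  truth <- rep(c(0L, 1L), each = 40)
  d <- dplyr::mutate(dplyr::select(g, chrom, start, end),
                     count = 100 * (1 + truth), g1 = 100)
  expect_equal(binarize_cell(d, gate = "mid")$state, truth)
})

test_that("a G1 control yields almost no replicated calls", {
  g <- make_genome(c(chr1 = 20e6, chr2 = 20e6), 1e5)
  set.seed(2)
  g1 <- rpois(nrow(g), 50)
  d <- dplyr::mutate(dplyr::select(g, chrom, start, end), count = g1, g1 = g1)
  st <- suppressWarnings(binarize_cell(d, gate = "early"))
  expect_lte(mean(st$state, na.rm = TRUE), 0.01)
})

test_that("a simulated mid-S cell is recovered at >= 99% state agreement", {
  g <- make_genome(c(chr1 = 20e6, chr2 = 20e6), 1e5)
  t <- smooth_landscape(g)
  prog <- graded_program(g, t = t, noise_sd = 0)  # Poisson noise only
  sim <- simulate_cells(g, prog, 1, seed = 77, s_fraction = 0.55, depth = 50)
  set.seed(78)
  g1 <- rpois(nrow(g), 50)
  d <- dplyr::mutate(dplyr::select(g, chrom, start, end),
                     count = sim$counts[1, ], g1 = g1)
  st <- binarize_cell(d, gate = "mid")
  expect_gte(mean(st$state == sim$states[1, ]), 0.99)
})

test_that("binarization ignores uniform count scaling and missing G1 bins", {
  g <- make_genome(c(chr1 = 20e6), 1e5)
  t <- smooth_landscape(g)
  sim <- simulate_cells(g, graded_program(g, t = t, noise_sd = 0), 1,
                        seed = 5, s_fraction = 0.4, depth = 60)
  set.seed(6)
  g1 <- rpois(nrow(g), 60)
  g1[c(3, 50)] <- 0
  d <- dplyr::mutate(dplyr::select(g, chrom, start, end),
                     count = sim$counts[1, ], g1 = g1)
  st1 <- binarize_cell(d, gate = "mid")
  st3 <- binarize_cell(dplyr::mutate(d, count = count * 3), gate = "mid")
  expect_equal(st1$state, st3$state)
  expect_true(all(is.na(st1$state[c(3, 50)])))
})

test_that("percentage replication is a masked ratio of non-missing bins", {
  states <- c(1, 1, 0, 0, NA, 1)
  expect_equal(percent_replication(states), 60)
  expect_equal(percent_replication(rep(1, 4)), 100)
  expect_equal(percent_replication(c(1, 0)), 50)
  # excluding chrX removes its bins from both numerator and denominator
  is_x <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  expect_equal(percent_replication(states, mask = !is_x), 50)
  expect_error(percent_replication(c(NA, NA)), "non-missing")
})

test_that("per-bin percentage replication counts replicated cells", {
  m <- rbind(c(1, 1, NA), c(0, 1, NA), c(1, 1, NA), c(0, 1, NA))
  m <- m[rep(1:4, length.out = 94), ]  # 94 cells, half replicated in bin 1
  p <- per_bin_percent_replication(m)
  expect_equal(p[1], 50)
  expect_equal(p[2], 100)
  expect_true(is.na(p[3]))
  expect_error(per_bin_percent_replication(m[0, , drop = FALSE]), "cell")
})

test_that("identity-line kinetics give T10-90% of exactly 0.8 S", {
  cells <- tibble::tibble(genome_pct = seq(1, 99, length.out = 54),
                          chrom_pct = seq(1, 99, length.out = 54))
  fit <- fit_t1090(cells, model = "linear")
  expect_equal(fit$t1090, 8.0, tolerance = 1e-10)
  expect_equal(nrow(fit$points), 20)  # 18 groups + 2 pseudo points
  expect_equal(unname(fit$parameters["slope"]), 1, tolerance = 1e-10)
})

test_that("sigmoid T10-90% follows the 2 log(9) / k closed form", {
  x <- seq(2, 98, length.out = 18)
  y <- 100 / (1 + exp(-0.2 * (x - 50)))
  fit <- fit_t1090(tibble::tibble(genome_pct = x, chrom_pct = y),
                   model = "sigmoid", pseudo_points = FALSE)
  expect_equal(unname(fit$parameters["k"]), 0.2, tolerance = 1e-6)
  expect_equal(fit$t1090, 2 * log(9) / 0.2 / 100 * 10, tolerance = 1e-6)
  expect_equal(fit$t1090, 2.197, tolerance = 1e-3)
})

test_that("a step-like chromosome fits to a very fast sigmoid", {
  x <- seq(2.5, 97.5, length.out = 18)
  y <- ifelse(x < 65, 0, 100)
  fit <- fit_t1090(tibble::tibble(genome_pct = x, chrom_pct = y),
                   model = "sigmoid")
  expect_lt(fit$t1090, diff(x)[1])  # faster than the inter-group spacing
})

test_that("kinetics fits validate their inputs and expose broom methods", {
  expect_error(fit_t1090(tibble::tibble(genome_pct = c(10, 60),
                                        chrom_pct = c(10, 60)),
                         model = "linear", pseudo_points = FALSE),
               "3 points")
  cells <- tibble::tibble(genome_pct = seq(5, 95, length.out = 30),
                          chrom_pct = seq(5, 95, length.out = 30))
  fit <- fit_t1090(cells, model = "linear")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$t1090, fit$t1090)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("scRT maps percentage replication onto S-phase time", {
  d <- tibble::tibble(p = c(100, 0, 37))
  out <- scrt_values(d, n_groups = 3)
  expect_equal(out$scrt, c(0, 10, 6.3))

  # non-increasing step function of p, range within [0, S]
  set.seed(31)
  d2 <- tibble::tibble(p = round(runif(500, 0, 100)))
  out2 <- scrt_values(d2)
  ord <- order(d2$p, decreasing = TRUE)
  expect_true(all(diff(out2$scrt[ord]) >= 0))
  expect_true(all(out2$scrt >= 0 & out2$scrt <= 10))
  # equal p always maps to equal scrt
  expect_equal(length(unique(out2$scrt[d2$p == 50])), 1)

  expect_error(scrt_values(tibble::tibble(p = NA_real_)), "non-missing")
  expect_error(scrt_values(tibble::tibble(p = 120)), "0, 100")
})

test_that("simulate -> binarize -> percentage -> scRT recovers the program", {
  g <- make_genome(c(chr1 = 20e6, chr2 = 20e6), 1e5)
  t <- smooth_landscape(g)
  prog <- graded_program(g, t = t, noise_sd = 0.5)
  sim <- simulate_cells(g, prog, 120, seed = 42, depth = 50)
  set.seed(43)
  g1 <- rpois(nrow(g), 50)
  states <- suppressWarnings(
    binarize_cells(sim$counts, g, g1, sim$cells$gate)
  )
  p <- per_bin_percent_replication(states)
  scrt <- scrt_values(tibble::tibble(p = p))$scrt
  expect_lte(sqrt(mean((scrt - t)^2)), 0.6)
})
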