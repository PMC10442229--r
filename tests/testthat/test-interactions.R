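test_that("allele assignment demands a perfect prefix match", {
  tab <- tibble::tibble(allele = c("B6", "JF1"),
                        prefix = c("ACGTACGT", "ACGTACGA"))
  expect_equal(assign_allele(c("ACGTACGT", "ACGTACGA"), tab), c("B6", "JF1"))
  expect_equal(assign_allele("ACGTACGG", tab), "unassigned")  # one mismatch
  expect_equal(assign_allele("TTTT", tab), "unassigned")
  expect_error(
    assign_allele("ACGT", tibble::tibble(allele = c("B6", "JF1"),
                                         prefix = c("AC", "AC"))),
    "ambiguous"
  )
})

test_that("fragment smoothing is a truncated centered running mean", {
  expect_equal(smooth_fragments(rep(2.5, 500), 201), rep(2.5, 500))

  imp <- rep(0, 1001)
  imp[501] <- 1
  sm <- smooth_fragments(imp, 201)
  expect_equal(sm[401:601], rep(1 / 201, 201))
  expect_equal(sm[300], 0)

  toy <- c(1, 4, 2, 8, 5)
  expect_equal(smooth_fragments(toy, 3),
               c(mean(c(1, 4)), mean(c(1, 4, 2)), mean(c(4, 2, 8)),
                 mean(c(2, 8, 5)), mean(c(8, 5))))
  expect_error(smooth_fragments(toy, 4), "odd")
})

test_that("virtual 4C sums viewpoint rows and normalizes to 10,000", {
  g <- make_genome(c(chrX = 2e6, chr1 = 1e6), 5e3, x_chrom = "chrX")
  n <- nrow(g)
  set.seed(21)
  m <- matrix(rpois(n * n, 2), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  cm <- contact_matrix(g, mat = m)

  prof <- virtual_4c(cm, "chrX", 4e5, 8e5, exclude_flank = 10)
  vp_rows <- which(g$chrom == "chrX" & g$start >= 4e5 & g$end <= 8e5)
  expect_length(vp_rows, 80)  # 400-kb viewpoint at 5-kb resolution
  expect_equal(sum(prof$signal, na.rm = TRUE), 1e4)
  # unmasked values are the scaled row sums of the viewpoint rows
  raw <- colSums(m[vp_rows, ])
  ok <- !is.na(prof$signal)
  expect_equal(prof$signal[ok], raw[ok] / sum(raw[ok]) * 1e4)
  # masked: viewpoint span +/- flank, in cis only
  expect_true(all(is.na(prof$signal[(min(vp_rows) - 10):(max(vp_rows) + 10)])))
  expect_false(anyNA(prof$signal[g$chrom == "chr1"]))

  # invariant to global depth scaling
  prof3 <- virtual_4c(contact_matrix(g, mat = m * 3L), "chrX", 4e5, 8e5,
                      exclude_flank = 10)
  expect_equal(prof3$signal, prof$signal)

  # contacts only inside the masked zone -> empty profile
  m0 <- matrix(0, n, n)
  m0[vp_rows, vp_rows] <- 5
  expect_warning(
    p0 <- virtual_4c(contact_matrix(g, mat = m0), "chrX", 4e5, 8e5),
    "empty"
  )
  expect_true(all(is.na(p0$signal)))
})

test_that("far-cis calls equal the brute-force per-window enumeration", {
  for (seed in c(101, 202)) {
    set.seed(seed)
    n <- 2000
    sig <- rbinom(n, 1, 0.15) * runif(n)
    sig[800:860] <- runif(61, 0.1, 1)
    sig[sample(n, 20)] <- NA
    prof <- tibble::tibble(chrom = "chrX", start = (1:n - 1) * 5e3,
                           end = (1:n) * 5e3, signal = sig)
    calls <- far_cis_calls(prof, w = 50, W = 1200, fdr = 0.01, chrom = "chrX")
    cover <- ifelse(is.na(sig), NA, as.numeric(sig > 0))
    oracle <- brute_far_cis_windows(cover, 50, 1200)
    expect_equal(calls$windows$k, oracle$k)
    expect_equal(calls$windows$p_bg, oracle$p_bg)
    expect_equal(calls$windows$z, oracle$z)
    expect_equal(calls$windows$p, oracle$p)
  }
})

test_that("windows matching their background are not significant", {
  prof <- tibble::tibble(chrom = "chrX", start = (1:500 - 1) * 5e3,
                         end = (1:500) * 5e3,
                         signal = rep(c(1, 0), 250))  # uniform 50% coverage
  calls <- far_cis_calls(prof, w = 50, W = 200, fdr = 0.01, chrom = "chrX")
  expect_equal(calls$n_calls, 0)
  expect_true(all(abs(calls$windows$z) < 3, na.rm = TRUE))
})

test_that("degenerate backgrounds are excluded from FDR control", {
  sig <- c(rep(0, 300), rep(1, 50), rep(0, 950))
  prof <- tibble::tibble(chrom = "chrX", start = (1:1300 - 1) * 5e3,
                         end = (1:1300) * 5e3, signal = sig)
  calls <- far_cis_calls(prof, w = 50, W = 400, fdr = 0.01, chrom = "chrX")
  # far from the block the background coverage is exactly 0: undefined z
  expect_true(anyNA(calls$windows$z))
  expect_true(all(is.na(calls$windows$q[is.na(calls$windows$p)])))
  # the planted block is found
  expect_equal(calls$n_calls, 1)
  expect_lte(abs(calls$intervals$start - 300 * 5e3), 50 * 5e3)
})

test_that("a planted trans block is called, and only that block", {
  set.seed(99)
  n1 <- 1500
  sig1 <- rbinom(n1, 1, 0.1)
  sig1[601:850] <- rbinom(250, 1, 0.9)  # planted 250-bin enriched block
  prof <- dplyr::bind_rows(
    tibble::tibble(chrom = "chrX", start = 0, end = 5e3, signal = 0),
    tibble::tibble(chrom = "chr1", start = (1:n1 - 1) * 5e3,
                   end = (1:n1) * 5e3, signal = sig1),
    tibble::tibble(chrom = "chr2", start = (1:n1 - 1) * 5e3,
                   end = (1:n1) * 5e3, signal = rbinom(n1, 1, 0.1))
  )
  calls <- trans_calls(prof, window = 250, fdr = 0.01, chrom = "chrX")
  expect_equal(calls$n_calls, 1)
  expect_equal(calls$intervals$chrom, "chr1")
  # boundaries within one window of the planted block
  expect_lte(abs(calls$intervals$start - 600 * 5e3), 250 * 5e3)
  expect_lte(abs(calls$intervals$end - 850 * 5e3), 250 * 5e3)

  expect_error(trans_calls(prof[prof$chrom == "chrX", ], chrom = "chrX"),
               "trans")
})

test_that("block-structured matrices give reciprocal viewpoint calls", {
  g <- make_genome(c(chrX = 5e6, chr1 = 1e6), 5e3, x_chrom = "chrX")
  n <- nrow(g)
  m <- matrix(0, n, n)
  a <- 101:180  # 400-kb block A
  b <- 601:680  # 400-kb block B, same chromosome
  m[a, b] <- 4
  m[b, a] <- 4
  bg <- matrix(rpois(n * n, 0.02), n, n)
  bg[lower.tri(bg)] <- t(bg)[lower.tri(bg)]
  m <- m + bg
  cm <- contact_matrix(g, mat = m)

  pa <- virtual_4c(cm, "chrX", g$start[min(a)], g$end[max(a)],
                   exclude_flank = 50)
  pb <- virtual_4c(cm, "chrX", g$start[min(b)], g$end[max(b)],
                   exclude_flank = 50)
  ca <- far_cis_calls(pa, w = 50, W = 400, fdr = 0.01)
  cb <- far_cis_calls(pb, w = 50, W = 400, fdr = 0.01)
  hit_b <- ca$intervals$start <= g$start[max(b)] &
    ca$intervals$end >= g$end[min(b)]
  hit_a <- cb$intervals$start <= g$start[max(a)] &
    cb$intervals$end >= g$end[min(a)]
  expect_true(any(hit_b))
  expect_true(any(hit_a))
})

test_that("z rebinning averages non-missing fine bins", {
  d <- tibble::tibble(chrom = "chrX", start = (0:159) * 5e3,
                      end = (1:160) * 5e3, z = rep(c(0, 1), 80))
  out <- rebin_z(d, target = 4e5)
  expect_equal(out$z, c(0.5, 0.5))

  d$z[1:80] <- 2
  d$z[c(5, 10)] <- NA
  out2 <- rebin_z(d, target = 4e5)
  expect_equal(out2$z[1], 2)
  expect_equal(out2$z[2], 0.5)
  expect_equal(rebin_z(dplyr::mutate(d, z = 1.3), target = 4e5)$z,
               c(1.3, 1.3))
  expect_error(rebin_z(d, target = 12e3), "multiple")
})

test_that("pair aggregation averages centered submatrices", {
  g <- make_genome(c(chrX = 10e6, chr1 = 2e6), 25e4, x_chrom = "chrX")
  n <- nrow(g)
  m <- matrix(1, n, n)
  cm <- contact_matrix(g, mat = m)

  # single valid pair: the submatrix itself (here all ones)
  one <- aggregate_pairs(cm, c(10, 25), flank = 2)
  expect_equal(one, matrix(1, 5, 5), ignore_attr = TRUE)
  expect_equal(attr(one, "n_pairs"), 2)

  # random bins on a homogeneous matrix: center/corner ratio ~ 1
  set.seed(17)
  rnd <- sample(5:(n - 5), 8)
  expect_equal(center_corner_ratio(aggregate_pairs(cm, rnd, flank = 3)), 1)

  expect_error(aggregate_pairs(cm, c(1, 2), flank = 5), "edge")
  expect_error(aggregate_pairs(cm, 3), "2 bins")
})

test_that("per-class trans counts are summarized and ordered by rank tests", {
  d <- tibble::tibble(label = rep(c("SD", "CL"), each = 8),
                      n_trans = c(5:12, 0:7))
  res <- trans_counts_by_class(d)
  expect_equal(sort(res$summary$label), c("CL", "SD"))
  expect_equal(nrow(res$tests), 1)  # Bonferroni factor = number of pairs
  expect_equal(res$tests$p_adj, res$tests$p * 1)
  expect_equal(res$tests$class_a, "SD")
  expect_lt(res$tests$p, 0.05)

  same <- tibble::tibble(label = rep(c("A", "B"), each = 10),
                         n_trans = rep(1:10, 2))
  res2 <- trans_counts_by_class(same)
  expect_gt(res2$tests$p, 0.4)

  three <- tibble::tibble(label = rep(c("A", "B", "C"), each = 5),
                          n_trans = rep(1:5, 3))
  expect_equal(nrow(trans_counts_by_class(three)$tests), 3)
  expect_equal(trans_counts_by_class(three)$tests$p_adj,
               pmin(trans_counts_by_class(three)$tests$p * 3, 1))
})
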