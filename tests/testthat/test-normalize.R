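test_that("pearson_r matches the direct product-moment formula", {
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  by_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), by_hand)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, c(5, 5, 5)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  expect_error(pearson_r(1:4, 1:3), "equal length")
})

test_that("factor table computes the candidate normalizers", {
  tiny <- tiny_experiment()
  # hk_mean needs Histone H3 and S6 by name: absent here -> NA + warnings
  ws <- capture_warnings(
    ft2 <- build_factor_table(tiny$counts, tiny$panel, tiny$roi_table))
  expect_match(ws, "absent", all = TRUE)
  expect_length(ws, 3L)  # Histone H3, S6, GAPDH all missing
  expect_true(all(is.na(ft2$hk_mean)))
  expect_equal(unname(ft2$igg_mean), c(100, 100, 100))
  expect_equal(ft2$area, tiny$roi_table$area)

  # with the real housekeepers present the means are as defined
  sim <- simulate_counts(simulation_design(seed = 2))
  panel <- make_default_panel()
  ft3 <- build_factor_table(sim$counts, panel, sim$roi_table)
  expect_equal(ft3$hk_mean,
               unname((sim$counts[, "Histone H3"] + sim$counts[, "S6"]) / 2))
  expect_equal(ft3$igg_mean,
               rowMeans(sim$counts[, igg_probes(panel)]),
               ignore_attr = TRUE)
})

test_that("housekeeper and IgG factors correlate on simulated data", {
  sim <- simulate_counts(simulation_design(seed = 12))
  ft <- build_factor_table(sim$counts, make_default_panel(), sim$roi_table)
  expect_gt(pearson_r(ft$hk_mean, ft$igg_mean), 0.8)
})

test_that("normalizer assessment matches element-wise pearson_r", {
  set.seed(9)
  ft <- data.frame(roi_id = paste0("R", 1:4),
                   gapdh = c(100, 150, 220, 90),
                   histone_h3 = c(200, 260, 400, 210),
                   s6 = c(150, 210, 300, 140))
  ft$hk_mean <- (ft$histone_h3 + ft$s6) / 2
  ft$igg_mean <- c(80, 110, 160, 85)
  ft$area <- c(1000, 1400, 2100, 950)
  ft$nuclei <- c(12, 15, 30, 11)
  a <- assess_normalizers(ft)
  cand <- setdiff(names(ft), "roi_id")
  for (i in cand) for (j in cand) {
    expected <- if (i == j) 1 else pearson_r(ft[[i]], ft[[j]])
    expect_equal(a$r[i, j], expected, info = paste(i, j))
  }
  expect_true(isSymmetric(a$r))
  expect_true(a$recommended %in% c("hk_mean", "histone_h3", "s6", "gapdh"))
})

test_that("constant area is excluded from the recommendation", {
  ft <- data.frame(roi_id = paste0("R", 1:5),
                   histone_h3 = c(200, 260, 400, 210, 300),
                   s6 = c(150, 210, 300, 140, 220))
  ft$hk_mean <- (ft$histone_h3 + ft$s6) / 2
  ft$igg_mean <- c(80, 110, 160, 85, 120)
  ft$area <- rep(282743, 5)  # every ROI at maximum geometry
  expect_warning(a <- assess_normalizers(ft), "constant")
  expect_true("area" %in% a$excluded)
  expect_true(all(is.na(a$r["area", ])))
  expect_false(is.na(a$recommended))
})

test_that("housekeeper normalization behaves as an anchored rescale", {
  tiny <- tiny_experiment()
  # identical factors: output equals input
  cts <- tiny$counts
  cts[, "HK1"] <- 100; cts[, "HK2"] <- 300
  nm <- normalize_hk(cts, tiny$panel, probes = c("HK1", "HK2"))
  expect_equal(nm$values, cts)
  # ROI A factor twice ROI B's with identical raw counts -> A half of B
  c2 <- matrix(c(400, 200, 100,
                 200, 100, 100), nrow = 2, byrow = TRUE,
               dimnames = list(c("RA", "RB"), c("HK1", "HK2", "T1")))
  p2 <- as_dsp_panel(data.frame(
    probe_id = c("HK1", "HK2", "T1"),
    probe_class = c("housekeeper", "housekeeper", "target"),
    module = "Controls"))
  n2 <- normalize_hk(c2, p2, probes = c("HK1", "HK2"))
  expect_equal(unname(n2$values["RA", "T1"] / n2$values["RB", "T1"]), 0.5)
  # grand geometric mean of factors preserved as the anchor
  expect_equal(exp(mean(log(n2$factors))),
               exp(mean(log(c(300, 150)))))
})

test_that("housekeeper normalization is idempotent", {
  sim <- simulate_counts(simulation_design(seed = 3))
  panel <- make_default_panel()
  n1 <- normalize_hk(sim$counts, panel)
  n2 <- normalize_hk(n1$values, panel)
  expect_equal(n2$values, n1$values, tolerance = 1e-10)
})

test_that("normalization reduces between-ROI CV of null probes", {
  sim <- simulate_counts(simulation_design(seed = 19))
  panel <- make_default_panel()
  nm <- normalize_hk(sim$counts, panel)
  tum <- sim$roi_table$roi_id[sim$roi_table$compartment == "Tumour"]
  cv <- function(m) apply(m[tum, target_probes(panel)], 2,
                          function(v) sd(v) / mean(v))
  expect_lt(median(cv(nm$values)), median(cv(sim$counts)))
})

test_that("recovered housekeeper factors track the true size factors", {
  sim <- simulate_counts(simulation_design(seed = 23))
  nm <- normalize_hk(sim$counts, make_default_panel())
  expect_gt(pearson_r(unname(nm$factors), sim$truth$roi$size_factor), 0.9)
})

test_that("RLE factors follow the closed form and multiply to one", {
  A <- c(100, 400, 50, 900)
  m <- rbind(RA = A, RB = 2 * A)
  colnames(m) <- paste0("P", 1:4)
  f <- rle_factors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)))
  expect_equal(prod(f), 1, tolerance = 1e-10)
  # identical ROIs: both factors 1
  m2 <- rbind(RA = A, RB = A)
  colnames(m2) <- paste0("P", 1:4)
  expect_equal(unname(rle_factors(m2)), c(1, 1))
  expect_equal(unname(tmm_factors(m2)), c(1, 1))
})

test_that("TMM and RLE factors agree with reference implementations", {
  skip_if_not_installed("edgeR")
  skip_if_not_installed("DESeq2")
  set.seed(77)
  counts <- matrix(rnbinom(5 * 40, mu = 300 * rep(exp(rnorm(5, 0, 0.4)),
                                                  40), size = 10),
                   nrow = 5,
                   dimnames = list(paste0("R", 1:5), paste0("P", 1:40)))
  f_tmm <- tmm_factors(counts)
  ref_tmm <- edgeR::calcNormFactors(t(counts), method = "TMM")
  expect_equal(unname(f_tmm), unname(ref_tmm), tolerance = 1e-8)
  f_rle <- rle_factors(counts)
  ref_rle <- DESeq2::estimateSizeFactorsForMatrix(t(counts))
  ref_rle <- ref_rle / exp(mean(log(ref_rle)))
  expect_equal(unname(f_rle), unname(ref_rle), tolerance = 1e-10)
})

test_that("global normalization drops all-zero probes with a warning", {
  set.seed(5)
  counts <- matrix(rpois(4 * 20, 200), nrow = 4,
                   dimnames = list(paste0("R", 1:4), paste0("P", 1:20)))
  counts[, 3] <- 0
  expect_warning(f <- tmm_factors(counts), "all-zero")
  expect_equal(prod(f), 1, tolerance = 1e-10)
  nm <- suppressWarnings(normalize_global(counts, "rle"))
  expect_equal(prod(attr(nm, "method_factors")), 1, tolerance = 1e-10)
})

test_that("normalization is equivariant to ROI and probe reordering", {
  sim <- simulate_counts(simulation_design(n_patients = 10,
                                           compartments = "Tumour",
                                           panel = small_panel(10),
                                           seed = 31))
  panel <- small_panel(10)
  n1 <- normalize_hk(sim$counts, panel)
  perm_r <- sample(nrow(sim$counts)); perm_c <- sample(ncol(sim$counts))
  n2 <- normalize_hk(sim$counts[perm_r, perm_c], panel)
  expect_equal(n2$values, n1$values[perm_r, perm_c])
  f1 <- rle_factors(sim$counts)
  f2 <- rle_factors(sim$counts[perm_r, ])
  expect_equal(f2, f1[perm_r])
})

test_that("log2 transform applies the pseudo-count and records it", {
  m <- matrix(c(0, 3, 1023, 7), 2, 2,
              dimnames = list(c("R1", "R2"), c("A", "B")))
  lt <- log2_transform(m, pseudo_count = 1)
  expect_equal(unname(lt$values[, "A"]), c(0, 2))
  expect_equal(unname(lt$values["R1", "B"]), 10)
  expect_true(lt$log2)
  expect_equal(lt$pseudo_count, 1)
  expect_error(log2_transform(lt), "already")
  expect_error(log2_transform(matrix(-1)), "nonnegative")
})
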