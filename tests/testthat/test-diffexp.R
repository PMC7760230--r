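test_that("paired t matches hand arithmetic", {
  # differences (1, 1.2, 0.8): mean 1, sd 0.2, t = 1/(0.2/sqrt(3))
  a <- c(2, 3.2, 1.8); b <- c(1, 2, 1)
  tt <- paired_t(a, b)
  expect_equal(tt$t, 1 / (0.2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(tt$t, 8.660, tolerance = 1e-3)
  expect_equal(tt$df, 2)
  expect_equal(tt$mean_diff, 1)
  expect_equal(tt$p, 2 * pt(tt$t, df = 2, lower.tail = FALSE))
})

test_that("paired t handles degenerate inputs and antisymmetry", {
  a <- c(1, 2, 3)
  expect_warning(t0 <- paired_t(a, a), "zero variance")
  expect_true(is.na(t0$t) && is.na(t0$p))
  expect_warning(t1 <- paired_t(1, 2), "fewer than 2")
  expect_true(is.na(t1$p))
  b <- c(0.5, 2.5, 2.0)
  fwd <- paired_t(a, b); rev <- paired_t(b, a)
  expect_equal(fwd$t, -rev$t)
  expect_equal(fwd$p, rev$p)
  expect_equal(fwd$mean_diff, -rev$mean_diff)
  # shift invariance
  sh <- paired_t(a + 100, b + 100)
  expect_equal(sh$t, fwd$t)
})

test_that("Mann-Whitney exact p matches full enumeration", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_true(mw$exact)
  # all C(4,2)=6 label arrangements; U=0 and U=4 are the two tails
  expect_equal(mw$p, 2 / 6)
  # identical multisets: U = n1*n2/2
  expect_warning(mw2 <- mann_whitney(c(5, 5), c(5, 5)), "identical")
  expect_equal(mw2$U, 2)
  expect_equal(mw2$p, 1)
  mw3 <- mann_whitney(c(1, 4), c(2, 3))
  expect_equal(mw3$U, 2)  # n1*n2/2 for interleaved symmetric data
})

test_that("Mann-Whitney approximate p agrees with a permutation oracle", {
  set.seed(41)
  a <- rnorm(30, 0.45); b <- rnorm(30)
  mw <- mann_whitney(a, b)
  expect_false(mw$exact)
  p_perm <- perm_mw_p(a, b, nperm = 1e5, seed = 2)
  # tolerance: 4 Monte-Carlo se plus the normal-approximation slack
  expect_lt(abs(mw$p - p_perm),
            4 * sqrt(p_perm * (1 - p_perm) / 1e5) + 0.005)
})

test_that("Mann-Whitney is invariant under monotone transforms", {
  set.seed(10)
  a <- rlnorm(12); b <- rlnorm(9, 0.5)
  m1 <- mann_whitney(a, b)
  m2 <- mann_whitney(log(a), log(b))
  m3 <- mann_whitney(a + 5, b + 5)
  expect_equal(m1$U, m2$U); expect_equal(m1$p, m2$p)
  expect_equal(m1$U, m3$U); expect_equal(m1$p, m3$p)
})

test_that("BH adjustment applies the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  p <- c(0.001, 0.2, 0.8, 0.04)
  # direct step-up computed by hand
  o <- order(p); m <- 4
  q_sorted <- rev(cummin(rev(sort(p) * m / seq_len(m))))
  expect_equal(bh_adjust(p)[o], pmin(q_sorted, 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH handles NA and is permutation invariant", {
  p <- c(0.01, NA, 0.03, 0.5)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[-2], bh_adjust(p[-2]))  # NA excluded from family size
  set.seed(3)
  p2 <- runif(20)
  perm <- sample(20)
  expect_equal(bh_adjust(p2)[perm], bh_adjust(p2[perm]))
  expect_true(all(bh_adjust(p2) >= p2))
})

test_that("paired comparison pairs patients and averages duplicate ROIs", {
  panel <- small_panel(4)
  d <- simulation_design(n_patients = 10,
                         compartments = c("Tumour", "TME"),
                         panel = panel, rois_per_compartment = 2L,
                         seed = 55)
  sim <- simulate_counts(d)
  nm <- log2_transform(normalize_hk(sim$counts, panel))
  res <- run_comparison(nm, sim$roi_table, c("TME", "Tumour"), "paired",
                        probes = target_probes(panel))
  expect_equal(unique(res$n), 10L)
  expect_true(all(res$p_adj >= res$p_raw, na.rm = TRUE))
  # hand-check one probe: duplicate ROIs averaged before pairing
  p <- res$probe_id[1]
  rt <- sim$roi_table
  pats <- sort(unique(rt$patient_id))
  av <- function(comp) vapply(pats, function(pp) {
    mean(nm$values[rt$roi_id[rt$patient_id == pp &
                               rt$compartment == comp], p])
  }, 1)
  expect_equal(res$effect[res$probe_id == p],
               mean(av("TME") - av("Tumour")))
  # swapping groups negates effects, keeps p
  swp <- run_comparison(nm, sim$roi_table, c("Tumour", "TME"), "paired",
                        probes = target_probes(panel))
  expect_equal(swp$effect, -res$effect)
  expect_equal(swp$p_raw, res$p_raw)
})

test_that("unpaired comparison uses medians and includes unmatched ROIs", {
  panel <- small_panel(4)
  d <- simulation_design(seed = 61, panel = panel)
  sim <- simulate_counts(d)
  nm <- log2_transform(normalize_hk(sim$counts, panel))
  res <- run_comparison(nm, sim$roi_table, c("NAT", "TME"), "unpaired",
                        probes = target_probes(panel))
  expect_equal(unique(res$n), 19L + 32L)
  rt <- sim$roi_table
  p <- res$probe_id[2]
  expect_equal(
    res$effect[res$probe_id == p],
    median(nm$values[rt$roi_id[rt$compartment == "NAT"], p]) -
      median(nm$values[rt$roi_id[rt$compartment == "TME"], p]))
})

test_that("correlation matrix equals element-wise pearson_r", {
  panel <- small_panel(4)
  sim <- simulate_counts(simulation_design(seed = 66, panel = panel))
  nm <- log2_transform(normalize_hk(sim$counts, panel))
  cm <- correlation_matrix(nm, sim$roi_table, "TME",
                           probes = target_probes(panel))
  rt <- sim$roi_table
  rois <- rt$roi_id[rt$compartment == "TME"]
  tg <- target_probes(panel)
  for (i in tg) for (j in tg) {
    if (i != j) {
      expect_equal(cm$r[i, j],
                   pearson_r(nm$values[rois, i], nm$values[rois, j]))
    }
  }
  expect_true(isSymmetric(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, length(tg)))
  # duplicated probe correlates at exactly 1 and p ~ 0
  v2 <- cbind(nm$values, DUP = nm$values[, tg[1]])
  nm2 <- nm; nm2$values <- v2
  cm2 <- correlation_matrix(nm2, sim$roi_table, "TME",
                            probes = c(tg, "DUP"))
  expect_equal(cm2$r[tg[1], "DUP"], 1)
  expect_true(cm2$significant[tg[1], "DUP"])
})

test_that("null correlation significance rate is near alpha", {
  set.seed(99)
  reps <- 40
  hits <- 0; pairs <- 0
  for (r in seq_len(reps)) {
    v <- matrix(rnorm(30 * 10), 30, 10,
                dimnames = list(paste0("R", 1:30), paste0("P", 1:10)))
    nm <- dspforge:::new_normalized_matrix(v, "none", NULL)
    rt <- data.frame(roi_id = rownames(v), patient_id = NA,
                     compartment = "TME")
    cm <- correlation_matrix(nm, rt, "TME", alpha = 0.001)
    hits <- hits + sum(cm$significant) / 2
    pairs <- pairs + choose(10, 2)
  }
  expect_lt(hits / pairs, 0.01)
})
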