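# Independent oracle implementations used to check the package's
# statistics. These deliberately use direct definitions (enumeration,
# brute force, generic optimisation), not the code paths they verify.

# Two-sided Mann-Whitney p by Monte-Carlo permutation of group labels.
perm_mw_p <- function(a, b, nperm = 1e5, seed = 1) {
  set.seed(seed)
  z <- c(a, b); n1 <- length(a)
  u_of <- function(lab) {
    r <- rank(z)
    sum(r[lab]) - n1 * (n1 + 1) / 2
  }
  obs <- u_of(seq_len(n1))
  mu <- n1 * length(b) / 2
  dev <- abs(obs - mu)
  hits <- 0L
  for (i in seq_len(nperm)) {
    lab <- sample(length(z), n1)
    if (abs(u_of(lab) - mu) >= dev - 1e-12) hits <- hits + 1L
  }
  hits / nperm
}

# Brute-force Ward clustering: at every step recompute the Ward.D2
# criterion D(A,B) = 2|A||B|/(|A|+|B|) * ||mean_A - mean_B||^2 over all
# cluster pairs and merge the minimum; heights are sqrt(D).
brute_ward <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  active <- seq_along(clusters)
  merges <- list()
  heights <- numeric(0)
  # node ids follow hclust convention: -i for singletons, step for merges
  node_id <- as.list(-seq_len(nrow(x)))
  while (length(active) > 1L) {
    best <- NULL; best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_len(ii - 1L)) {
        A <- clusters[[active[ii]]]; B <- clusters[[active[jj]]]
        mA <- colMeans(x[A, , drop = FALSE])
        mB <- colMeans(x[B, , drop = FALSE])
        d <- 2 * length(A) * length(B) / (length(A) + length(B)) *
          sum((mA - mB)^2)
        if (d < best_d) { best_d <- d; best <- c(active[jj], active[ii]) }
      }
    }
    k <- length(clusters) + 1L
    clusters[[k]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    merges[[length(merges) + 1L]] <-
      sort(c(node_id[[best[1]]], node_id[[best[2]]]))
    node_id[[k]] <- length(merges)
    heights <- c(heights, sqrt(best_d))
    active <- c(setdiff(active, best), k)
  }
  list(merge = do.call(rbind, merges), height = heights)
}

# Efron-ties Cox partial log-likelihood, maximized by generic 1-d
# optimisation.
efron_loglik <- function(beta, time, event, x) {
  eta <- beta * x
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(event == 1 & time == t)
    R <- which(time >= t)
    d <- length(D)
    sum_r <- sum(exp(eta[R])); sum_d <- sum(exp(eta[D]))
    ll <- ll + sum(eta[D]) -
      sum(log(sum_r - (seq_len(d) - 1) / d * sum_d))
  }
  ll
}

oracle_cox_beta <- function(time, event, x, interval = c(-10, 10)) {
  stats::optimize(function(b) efron_loglik(b, time, event, x),
                  interval = interval, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab))); sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Small panel for fast simulations: n targets + 3 IgG + 3 housekeepers.
small_panel <- function(n_targets = 30) {
  full <- make_default_panel()
  as_dsp_panel(rbind(full[full$probe_class != "target", ],
                     full[full$probe_class == "target", ][seq_len(n_targets), ]))
}

# A tiny deterministic experiment used across io/qc tests.
tiny_experiment <- function() {
  panel <- as_dsp_panel(data.frame(
    probe_id = c("IgG1", "IgG2", "HK1", "HK2", "A", "B"),
    probe_class = c("igg_control", "igg_control", "housekeeper",
                    "housekeeper", "target", "target"),
    module = c("Controls", "Controls", "Controls", "Controls",
               "M1", "M1")))
  counts <- matrix(
    c(50, 150, 200, 400, 100, 300,
      80, 120, 300, 500, 200, 100,
      100, 100, 250, 450, 50, 600),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("R1", "R2", "R3"), panel$probe_id))
  roi_table <- data.frame(
    roi_id = c("R1", "R2", "R3"),
    patient_id = c("P1", "P1", "P2"),
    compartment = c("Tumour", "TME", "NAT"),
    area = c(1000, 2000, 1500), nuclei = c(10, 25, 18),
    shape = "custom", stringsAsFactors = FALSE)
  list(panel = panel, counts = counts, roi_table = roi_table)
}
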