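test_that("relative distance and its delta-method variance", {
  eq <- relative_distance(list(d = 0.2, var_d = 0), list(d = 0.2, var_d = 0))
  expect_equal(eq$r, 1)
  expect_equal(eq$var_r, 0)

  rd <- relative_distance(list(d = 0.10, var_d = 0.0004),
                          list(d = 0.20, var_d = 0.0005))
  expect_equal(rd$r, 0.5)
  expect_equal(rd$var_r, 0.0004 / 0.04 + 0.01 * 0.0005 / 0.0016,
               tolerance = 1e-12)
  expect_equal(rd$var_r, 0.013125, tolerance = 1e-12)

  expect_error(relative_distance(list(d = 0.1, var_d = 1e-4),
                                 list(d = 0, var_d = 0)),
               "degenerate background")
})

test_that("relative distance is invariant under doubling all counts", {
  r1 <- relative_distance(poisson_estimate(10, 100), poisson_estimate(20, 100))
  r2 <- relative_distance(poisson_estimate(20, 200), poisson_estimate(40, 200))
  expect_equal(r1$r, r2$r)
  expect_equal(r1$var_r / r2$var_r, 2, tolerance = 1e-12)
})

test_that("group comparison z is antisymmetric", {
  ri <- list(r = 0.8, var_r = 0.01)
  rj <- list(r = 1.1, var_r = 0.02)
  ct <- compare_groups(ri, rj)
  expect_equal(ct$z, (0.8 - 1.1) / sqrt(0.03))
  ct2 <- compare_groups(rj, ri)
  expect_equal(ct2$z, -ct$z)
  expect_equal(ct2$p_value, ct$p_value)
  expect_equal(compare_groups(ri, ri)$z, 0)
  expect_error(compare_groups(list(r = 1, var_r = 0), list(r = 2, var_r = 0)),
               "variances")
})

test_that("TSPS analytic values, classes, and scale invariance", {
  for (n in c(2, 5, 32)) {
    u <- tsps(rep(3.7, n))
    expect_identical(u$tsps, 0)
    expect_equal(u$class, "facilitator")
  }
  s <- tsps(c(9, rep(0, 31)))
  expect_identical(s$tsps, 5)
  expect_equal(s$class, "specifier")

  half <- tsps(c(4, 4, 0, 0))
  expect_equal(half$tsps, 1, tolerance = 1e-12)
  expect_equal(half$class, "specifier")

  v <- runif(10)
  expect_equal(tsps(v * 1000)$tsps, tsps(v)$tsps, tolerance = 1e-12)

  expect_error(tsps(rep(0, 5)), "all-zero")
  expect_error(tsps(c(-1, 2)), "negative")
  expect_error(tsps(5), "at least 2")
})

test_that("TSPS strictly increases as expression mass concentrates", {
  set.seed(303)
  for (i in 1:20) {
    v <- rgamma(8, 1) + 0.05
    hi <- which.max(v)
    lo <- which.min(v)
    w <- v
    eps <- v[lo] / 2
    w[hi] <- w[hi] + eps
    w[lo] <- w[lo] - eps
    expect_gt(tsps(w)$tsps, tsps(v)$tsps)
  }
})

test_that("TSPS bounded by log2(number of tissues)", {
  set.seed(304)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    v <- rgamma(n, 0.3)
    v[v < 0] <- 0
    if (sum(v) == 0) v[1] <- 1
    score <- tsps(v)$tsps
    expect_gte(score, 0)
    expect_lte(score, log2(n) + 1e-12)
  }
})

test_that("tsps_table excludes all-zero proteins with a warning", {
  m <- rbind(P1 = c(1, 1, 1, 1), P2 = c(0, 0, 0, 0), P3 = c(5, 0, 0, 0))
  colnames(m) <- paste0("t", 1:4)
  expect_warning(tt <- tsps_table(m), "P2")
  expect_equal(tt$protein_id, c("P1", "P3"))
  expect_equal(tt$tsps, c(0, 2))
})

test_that("degrees count distinct partners; hubs are degree > 20 strictly", {
  # duplicated edge in both orientations counts once
  e <- data.frame(protein_a = c("A", "B", "A"), protein_b = c("B", "A", "A"))
  dh <- degree_and_hubs(e)
  expect_equal(dh$degree[dh$protein_id == "A"], 1L)  # self-loop removed too
  expect_equal(dh$degree[dh$protein_id == "B"], 1L)

  # isolated protein via the universe argument
  dh2 <- degree_and_hubs(e, proteins = c("A", "B", "Z"))
  expect_equal(dh2$degree[dh2$protein_id == "Z"], 0L)
  expect_false(dh2$is_hub[dh2$protein_id == "Z"])

  # star with 21 leaves: center is a hub (21 > 20), leaves are not;
  # a 20-degree center is not a hub
  star <- data.frame(protein_a = "hub", protein_b = paste0("L", 1:21))
  dh3 <- degree_and_hubs(star)
  expect_true(dh3$is_hub[dh3$protein_id == "hub"])
  expect_false(any(dh3$is_hub[dh3$protein_id != "hub"]))
  star20 <- data.frame(protein_a = "c20", protein_b = paste0("L", 1:20))
  dh4 <- degree_and_hubs(star20)
  expect_false(dh4$is_hub[dh4$protein_id == "c20"])
})

test_that("a planted fast-site category is recovered by the vs-rest contrast", {
  cfg <- simulation_config(
    n_proteins = 80, protein_length_range = c(150, 200),
    sites_per_protein = 4,
    category_labels = c("fast_cat", "other1", "other2"),
    category_site_multipliers = c(fast_cat = 3),
    seed = 61)
  b <- simulate_dataset(cfg)
  obs <- rbind(site_observations(b), flank_observations(b))
  kegg <- b$annotations[b$annotations$namespace == "kegg",
                        c("protein_id", "category")]
  names(kegg)[2] <- "group"
  suppressWarnings(
    res <- partition_and_compare(obs, kegg, b$organism_order,
                                 contrast = "vs_rest"))
  comb <- res$contrasts[res$contrasts$organism == "combined" &
                          res$contrasts$group_i == "fast_cat", ]
  expect_equal(comb$group_j, "not_fast_cat")
  expect_gt(comb$z, 0)          # faster sites: larger relative distance
  expect_lt(comb$p_value, 0.01)
})

test_that("vs-rest complements exclude multi-annotated proteins", {
  b <- toy_bundle()
  obs <- rbind(site_observations(b), flank_observations(b))
  groups <- data.frame(protein_id = c("PX", "PX", "PY"),
                       group = c("g1", "g2", "g2"))
  suppressWarnings(
    res <- partition_and_compare(obs, groups, b$organism_order,
                                 contrast = "vs_rest"))
  est <- res$estimates
  # complement of g2 is empty (both proteins carry g2): only g1's rest = PY
  expect_true(all(est$group != "not_g2"))
  expect_true(any(est$group == "not_g1"))
})

test_that("a whole-protein category effect is removed by the relative distance", {
  cfg <- simulation_config(
    n_proteins = 80, protein_length_range = c(150, 200),
    sites_per_protein = 4,
    category_labels = c("slow_proteins", "normal"),
    category_protein_multipliers = c(slow_proteins = 0.4),
    seed = 62)
  b <- simulate_dataset(cfg)
  obs <- rbind(site_observations(b), flank_observations(b))
  kegg <- b$annotations[b$annotations$namespace == "kegg",
                        c("protein_id", "category")]
  names(kegg)[2] <- "group"
  suppressWarnings(
    res <- partition_and_compare(obs, kegg, b$organism_order,
                                 contrast = "pairwise"))
  est <- res$estimates
  deep <- est[est$organism == "S.pombe", ]
  # raw distances separate strongly, the ratio does not
  expect_lt(deep$d_site[deep$group == "slow_proteins"],
            deep$d_site[deep$group == "normal"] * 0.8)
  comb <- res$contrasts[res$contrasts$organism == "combined", ]
  expect_gt(comb$p_value, 0.001)
})
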