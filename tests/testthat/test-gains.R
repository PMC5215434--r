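test_that("gain epochs follow the first-appearance rule on the default ladder", {
  ord <- default_organism_order()
  all_k <- setNames(rep("K", 14), ord$names)
  g <- infer_gain_epoch(all_k, ord)
  expect_equal(g$boundary, 14L)
  expect_equal(g$epoch, "eukaryote")

  vert <- all_k
  vert[8:14] <- "R"
  g2 <- infer_gain_epoch(vert, ord)
  expect_equal(g2$boundary, 7L)
  expect_equal(g2$epoch, "vertebrate")

  none <- setNames(rep("R", 14), ord$names)
  g3 <- infer_gain_epoch(none, ord)
  expect_equal(g3$boundary, 0L)
  expect_equal(g3$epoch, "human")

  # missing organisms are uninformative
  sparse <- all_k
  sparse[c(3, 9)] <- NA
  expect_equal(infer_gain_epoch(sparse, ord)$boundary, 14L)

  expect_error(infer_gain_epoch(all_k, ord, human_residue = "R"), "'K'")
})

test_that("strict mode marks lossy profiles unresolved instead of mistiming", {
  ord <- default_organism_order()
  prof <- setNames(c(rep("K", 7), rep("S", 7)), ord$names)
  prof["M.musculus"] <- "R"  # a loss interior to the conserved span
  default <- infer_gain_epoch(prof, ord)
  expect_equal(default$epoch, "vertebrate")
  strict <- infer_gain_epoch(prof, ord, mode = "strict")
  expect_false(strict$resolved)
  expect_equal(strict$epoch, "unresolved")
  # a gap interior to the span is also evidence against a clean gain
  prof2 <- setNames(c(rep("K", 7), rep("S", 7)), ord$names)
  prof2["G.gallus"] <- "-"
  expect_false(infer_gain_epoch(prof2, ord, mode = "strict")$resolved)
  # but a missing ortholog is not
  prof3 <- setNames(c(rep("K", 7), rep("S", 7)), ord$names)
  prof3["G.gallus"] <- NA
  expect_true(infer_gain_epoch(prof3, ord, mode = "strict")$resolved)
})

test_that("low-coverage sites get the youngest consistent epoch, flagged", {
  ord <- default_organism_order()
  prof <- setNames(c(rep("K", 4), rep(NA, 10)), ord$names)
  g <- infer_gain_epoch(prof, ord)
  expect_equal(g$boundary, 4L)
  expect_equal(g$epoch, "mammalian")
  expect_true(g$low_coverage)
  full <- setNames(c(rep("K", 4), rep("R", 10)), ord$names)
  expect_false(infer_gain_epoch(full, ord)$low_coverage)
})

test_that("losing the most distant lysine never makes the epoch older", {
  ord <- default_organism_order()
  set.seed(55)
  for (i in 1:50) {
    prof <- setNames(sample(c("K", "R", "A", "-", NA), 14, replace = TRUE,
                            prob = c(0.4, 0.2, 0.2, 0.1, 0.1)), ord$names)
    b0 <- infer_gain_epoch(prof, ord)$boundary
    if (b0 == 0L) next
    mutated <- prof
    mutated[b0] <- "R"
    b1 <- infer_gain_epoch(mutated, ord)$boundary
    expect_lte(b1, b0)
  }
})

test_that("per-epoch counts partition the resolved sites", {
  ord <- default_organism_order()
  cfg <- simulation_config(n_proteins = 20, protein_length_range = c(60, 90),
                           sites_per_protein = 3,
                           site_rate_multiplier = 0, flank_rate_multiplier = 0,
                           planted_gain_epochs = c(vertebrate = 10, primate = 5),
                           seed = 71)
  cfg0 <- cfg
  cfg0$organisms <- organism_order(ord$names, rep(0, 14), ord$epochs)
  b <- simulate_dataset(cfg0)
  g <- gain_table(b)
  counts <- count_gains_per_epoch(g, b$organism_order)
  expect_equal(sum(counts$count), sum(g$resolved))
  expect_equal(counts$count[counts$epoch == "vertebrate"], 10L)
  expect_equal(counts$count[counts$epoch == "primate"], 5L)
  # unplanted sites stay lysine everywhere: ancestral eukaryote gains
  expect_equal(counts$count[counts$epoch == "eukaryote"], 60L - 15L)

  empty <- count_gains_per_epoch(g[0, ], b$organism_order)
  expect_true(all(empty$count == 0L))
})

test_that("planted gain epochs are recovered exactly without losses", {
  cfg <- simulation_config(
    n_proteins = 50, protein_length_range = c(60, 90), sites_per_protein = 5,
    planted_gain_epochs = c(primate = 20, mammalian = 20, vertebrate = 20,
                            animal = 20, eukaryote = 20),
    seed = 72)
  b <- simulate_dataset(cfg)
  g <- gain_table(b)
  truth <- b$ground_truth$sites
  planted <- !is.na(truth$gain_epoch)
  m <- merge(g, truth[planted, ], by = c("protein_id", "position"))
  expect_equal(nrow(m), 100L)
  expect_true(all(m$resolved))
  expect_equal(mean(m$epoch == m$gain_epoch), 1)
})

test_that("with secondary losses, default mode recovers and strict abstains", {
  cfg <- simulation_config(
    n_proteins = 50, protein_length_range = c(60, 90), sites_per_protein = 5,
    planted_gain_epochs = c(mammalian = 25, vertebrate = 25, animal = 25,
                            eukaryote = 25),
    gain_loss_rate = 0.1, seed = 73)
  b <- simulate_dataset(cfg)
  truth <- b$ground_truth$sites
  planted <- truth[!is.na(truth$gain_epoch), ]
  lossy <- planted[!is.na(planted$loss_organism), ]
  expect_gt(nrow(lossy), 0)

  g_def <- gain_table(b, mode = "first_appearance")
  m_def <- merge(g_def, planted, by = c("protein_id", "position"))
  expect_gte(mean(m_def$epoch == m_def$gain_epoch), 0.9)

  g_str <- gain_table(b, mode = "strict")
  m_str <- merge(g_str, planted, by = c("protein_id", "position"))
  is_lossy <- !is.na(m_str$loss_organism)
  # every lossy profile is abstained from, never assigned a wrong epoch
  expect_true(all(!m_str$resolved[is_lossy]))
  expect_true(all(m_str$epoch[m_str$resolved] ==
                    m_str$gain_epoch[m_str$resolved]))
})

test_that("hypergeometric tails match the summation oracle everywhere small", {
  set.seed(91)
  for (i in 1:200) {
    N <- sample(2:25, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k_lo <- max(0, n + K - N)
    k <- sample(k_lo:min(n, K), 1)
    ours <- hypergeom_tails(k, K, N, n)
    oracle <- hyper_tail_oracle(k, K, N, n)
    expect_equal(ours$p_enrich, oracle$p_enrich, tolerance = 1e-10)
    expect_equal(ours$p_deplete, oracle$p_deplete, tolerance = 1e-10)
  }
})

test_that("enrichment matches brute-force enumeration and handles edge cases", {
  # N=20, K=5, n=8, k=5: compare against enumeration of all C(20,8) draws
  bg <- sprintf("P%02d", 1:20)
  cats <- data.frame(protein_id = bg[1:5], category = "c1")
  gained <- c(bg[1:5], bg[6:8])
  res <- enrichment(gained, bg, cats)
  expect_equal(res$observed, 5)
  expect_equal(res$expected, 8 * 5 / 20)
  expect_equal(res$p_enrich, hyper_upper_enumeration(5, 5, 20, 8),
               tolerance = 1e-10)
  expect_equal(res$direction, "enriched")

  # category equal to the background: observed = n = expected, p = 1
  all_cat <- data.frame(protein_id = bg, category = "everything")
  res2 <- enrichment(gained, bg, all_cat)
  expect_equal(res2$observed, length(gained))
  expect_equal(res2$expected, length(gained))
  expect_equal(res2$p_value, 1)

  expect_error(enrichment("X", character(), cats), "empty background")
  expect_error(enrichment("nope", bg, cats), "subset")
})

test_that("Bonferroni keeps null enrichment calls super-uniform", {
  set.seed(92)
  bg <- sprintf("P%03d", 1:300)
  cats <- do.call(rbind, lapply(1:10, function(j)
    data.frame(protein_id = sample(bg, 30), category = paste0("c", j))))
  hits <- 0L
  for (rep in 1:200) {
    gained <- sample(bg, 40)
    res <- enrichment(gained, bg, cats)
    if (any(res$corrected_p < 0.05)) hits <- hits + 1L
  }
  # family-wise error across categories should be at most ~5% (conservative)
  expect_lte(hits / 200, 0.07)
})
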