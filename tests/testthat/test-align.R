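blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

test_that("identical sequences align gapless with the diagonal score", {
  s <- "MKTAYIAKQR"
  a <- global_align(s, s)
  expect_equal(a$aligned_human, s)
  expect_equal(a$aligned_ortholog, s)
  letters_s <- strsplit(s, "")[[1]]
  expect_equal(a$score, sum(diag(blosum62[letters_s, letters_s])))
})

test_that("classic short pair matches the independent DP oracle", {
  a <- global_align("HEAGAWGHEE", "PAWHEAE")
  expect_equal(a$score, nw_score_oracle("HEAGAWGHEE", "PAWHEAE", blosum62))
  # the alignment must be consistent: equal lengths, ungapping restores input
  expect_equal(nchar(a$aligned_human), nchar(a$aligned_ortholog))
  expect_equal(gsub("-", "", a$aligned_human), "HEAGAWGHEE")
  expect_equal(gsub("-", "", a$aligned_ortholog), "PAWHEAE")
})

test_that("alignment scores equal the DP oracle on random short pairs", {
  set.seed(101)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:40) {
    la <- sample(1:30, 1)
    lb <- sample(1:30, 1)
    sa <- paste(sample(aa, la, replace = TRUE), collapse = "")
    sb <- paste(sample(aa, lb, replace = TRUE), collapse = "")
    res <- global_align(sa, sb)
    expect_equal(res$score, nw_score_oracle(sa, sb, blosum62),
                 info = paste(sa, sb))
    # realized alignment must actually achieve the reported score
    ca <- strsplit(res$aligned_human, "")[[1]]
    cb <- strsplit(res$aligned_ortholog, "")[[1]]
    gap_runs <- function(g) {
      r <- rle(g)
      sum(r$lengths[r$values]) + 10 * sum(r$values)
    }
    mcols <- ca != "-" & cb != "-"
    realized <- sum(blosum62[cbind(ca[mcols], cb[mcols])]) -
      gap_runs(ca == "-") - gap_runs(cb == "-")
    expect_equal(realized, res$score)
  }
})

test_that("alignment agrees with an independent library implementation", {
  set.seed(77)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:10) {
    sa <- paste(sample(aa, sample(10:40, 1), replace = TRUE), collapse = "")
    sb <- paste(sample(aa, sample(10:40, 1), replace = TRUE), collapse = "")
    ours <- global_align(sa, sb)$score
    ref <- Biostrings::pairwiseAlignment(sa, sb, type = "global",
                                         substitutionMatrix = blosum62,
                                         gapOpening = 10, gapExtension = 1,
                                         scoreOnly = TRUE)
    expect_equal(ours, ref)
  }
})

test_that("swapping the arguments preserves the optimal score", {
  a <- global_align("HEAGAWGHEE", "PAWHEAE")
  b <- global_align("PAWHEAE", "HEAGAWGHEE")
  expect_equal(a$score, b$score)
})

test_that("illegal characters and empty sequences are rejected", {
  expect_error(global_align("MKT", ""), "nonempty")
  expect_error(global_align("MKT1", "MKT"), "illegal character")
})

test_that("map_site reads the orthologous residue through the column map", {
  s <- "MAAAAAAAAKAAAAAAAAAA"
  p_id <- aligned_pair("P1", "org", s, s)
  expect_equal(map_site(p_id, 10), "K")

  # ortholog with a deletion spanning the site
  orth <- paste0(substr(s, 1, 8), "---", substr(s, 12, 20))
  p_del <- aligned_pair("P1", "org", s, orth)
  expect_equal(map_site(p_del, 10), "-")

  # missing ortholog
  expect_true(is.na(map_site(NULL, 10)))
  expect_error(map_site(p_id, 21), "outside")
  expect_error(map_site(p_id, 0), "outside")
})

test_that("aligned_pair validates lengths and keeps a strictly increasing map", {
  expect_error(aligned_pair("P", "o", "AAA", "AA"), "lengths differ")
  p <- aligned_pair("P", "o", "AA--CD", "AAGGCD")
  expect_equal(human_sequence(p), "AACD")
  expect_true(all(diff(p$column_of_position) > 0))
  expect_equal(p$column_of_position, c(1L, 2L, 5L, 6L))
})

test_that("flank positions are ten residues centered on the site", {
  expect_equal(flank_positions(100, 50), c(45:49, 51:55))
  expect_equal(flank_positions(100, 2), c(1L, 3L, 4L, 5L, 6L, 7L))
  expect_equal(flank_positions(100, 100), 95:99)
  expect_error(flank_positions(100, 101), "outside")
  # optional exclusion of flank lysines
  s <- paste0(strrep("A", 4), "K", strrep("A", 15))  # K at 5
  expect_equal(flank_positions(20, 7, sequence = s, exclude_lysines = TRUE),
               c(2:4, 6, 8:12))
})

test_that("site profiles stack the ladder and mark missing orthologs", {
  b <- toy_bundle()
  ord <- b$organism_order
  pairs_px <- lapply(b$alignments, `[[`, "PX")
  prof <- site_profile(pairs_px, 10, ord)
  expect_equal(unname(prof), c("K", "K", "R", "-"))

  pairs_py <- lapply(b$alignments, `[[`, "PY")
  prof_py <- site_profile(pairs_py, 6, ord)
  expect_equal(unname(prof_py), c("K", "K", "K", NA))

  # mixed human ids are rejected
  mixed <- list(orgA = b$alignments$orgA$PX, orgB = b$alignments$orgB$PY)
  expect_error(site_profile(mixed, 5, ord), "different human proteins")
})

test_that("map_site recovers ground-truth residues on indel-free data", {
  cfg <- simulation_config(n_proteins = 4, protein_length_range = c(60, 90),
                           sites_per_protein = 3, seed = 11)
  b <- simulate_dataset(cfg)
  for (org in b$organism_order$names) {
    for (i in seq_len(nrow(b$site_table))) {
      pid <- b$site_table$protein_id[i]
      pos <- b$site_table$position[i]
      pair <- b$alignments[[org]][[pid]]
      oid <- b$ortholog_map$ortholog_id[b$ortholog_map$human_id == pid &
                                          b$ortholog_map$organism == org]
      expect_equal(map_site(pair, pos),
                   substr(b$orthologs[[org]][[oid]], pos, pos))
    }
  }
})

test_that("re-alignment of indel-bearing orthologs restores site mapping", {
  full <- default_organism_order()
  ord3 <- organism_order(full$names[1:3], full$depths[1:3])
  cfg <- simulation_config(n_proteins = 3, protein_length_range = c(80, 120),
                           sites_per_protein = 2, site_rate_multiplier = 0,
                           flank_rate_multiplier = 0.2, indel_rate = 0.02,
                           organisms = ord3, seed = 23)
  b <- simulate_dataset(cfg)
  hits <- 0L; total <- 0L
  for (org in b$organism_order$names) {
    for (i in seq_len(nrow(b$site_table))) {
      pid <- b$site_table$protein_id[i]
      pos <- b$site_table$position[i]
      truth <- map_site(b$alignments[[org]][[pid]], pos)
      oid <- b$ortholog_map$ortholog_id[b$ortholog_map$human_id == pid &
                                          b$ortholog_map$organism == org]
      re <- global_align(b$sequences[[pid]], b$orthologs[[org]][[oid]],
                         ids = c(pid, org))
      total <- total + 1L
      if (identical(map_site(re, pos), truth)) hits <- hits + 1L
    }
  }
  # sites kept at rate 0 sit in conserved context; re-alignment recovers them
  expect_gte(hits / total, 0.9)
})
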