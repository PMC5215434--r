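# Hand-built fixtures used across test files.

toy_order <- function() {
  organism_order(
    names = c("orgA", "orgB", "orgC", "orgD"),
    depths = c(0.1, 0.3, 0.6, 1.0),
    epochs = c(young = 1L, mid = 2L, old = 4L))
}

# A 2-protein bundle with fully hand-specified alignments: protein PX has a
# K site at 10 conserved everywhere except a substitution in orgC and a gap
# in orgD; protein PY has a K site at 6 conserved everywhere and no ortholog
# in orgD.
toy_bundle <- function() {
  ord <- toy_order()
  seq_px <- "MAAAAAAAAKAAAAAAAAAAAAAAAAAAAA"  # K at 10, length 30
  seq_py <- "MCCCCKCCCCCCCCCCCCCCCCCCCCCCCC"  # K at 6, length 30
  sequences <- c(PX = seq_px, PY = seq_py)
  site_table <- data.frame(protein_id = c("PX", "PY"), position = c(10L, 6L),
                           residue = "K", modification = "ubiquitination",
                           stringsAsFactors = FALSE)
  sub_at <- function(s, pos, res) {
    substr(s, pos, pos) <- res
    s
  }
  aln <- list(
    orgA = list(PX = aligned_pair("PX", "orgA", seq_px, seq_px),
                PY = aligned_pair("PY", "orgA", seq_py, seq_py)),
    orgB = list(PX = aligned_pair("PX", "orgB", seq_px, sub_at(seq_px, 12, "W")),
                PY = aligned_pair("PY", "orgB", seq_py, seq_py)),
    orgC = list(PX = aligned_pair("PX", "orgC", seq_px, sub_at(seq_px, 10, "R")),
                PY = aligned_pair("PY", "orgC", seq_py, seq_py)),
    orgD = list(PX = aligned_pair("PX", "orgD", seq_px,
                                  sub_at(sub_at(seq_px, 10, "-"), 11, "-"))))
  orthologs <- lapply(aln, function(x)
    vapply(x, function(p) gsub("-", "", p$aligned_ortholog, fixed = TRUE),
           character(1)))
  map_rows <- do.call(rbind, lapply(names(aln), function(org)
    data.frame(human_id = names(aln[[org]]), organism = org,
               ortholog_id = paste0(names(aln[[org]]), "_", org),
               stringsAsFactors = FALSE)))
  expression <- rbind(PX = rep(2, 4), PY = c(10, 0, 0, 0))
  colnames(expression) <- paste0("tissue_", 1:4)
  list(sequences = sequences,
       orthologs = orthologs,
       site_table = site_table,
       ortholog_map = map_rows,
       alignments = aln,
       annotations = data.frame(protein_id = c("PX", "PY"),
                                namespace = "kegg",
                                category = c("catA", "catB"),
                                stringsAsFactors = FALSE),
       expression = expression,
       edges = data.frame(protein_a = "PX", protein_b = "PY",
                          stringsAsFactors = FALSE),
       organism_order = ord)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
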