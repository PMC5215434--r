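# One strict table dialect throughout: TSV, UTF-8, header row, '#' comments.
.read_tsv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
}

#' Read / write protein sequences in FASTA
#'
#' Thin wrappers around Biostrings returning plain named character vectors,
#' the in-memory sequence representation used everywhere in this package.
#'
#' @param path File path.
#' @param sequences Named character vector for writing.
#' @return `read_fasta()`: named character vector.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(sequences), path,
                              width = 70L)
  invisible(path)
}

#' Read a ubiquitination-site table and validate it against the sequences
#'
#' Columns `protein_id`, `position` (1-based), `residue`; an optional
#' `modification` column defaults to `"ubiquitination"`. Every record is
#' checked against the protein sequence: unknown protein, out-of-range
#' position, residue mismatch and duplicated records are rejected with the
#' protein and position named in the message.
#'
#' @param path TSV path.
#' @param sequences Named character vector of protein sequences.
#' @return Data frame of validated site records.
#' @export
read_site_table <- function(path, sequences) {
  df <- .read_tsv(path, c("protein_id", "position", "residue"))
  if (is.null(df$modification)) df$modification <- "ubiquitination"
  validate_site_table(df, sequences)
}

#' @rdname read_site_table
#' @param sites Site data frame to validate (same columns as above).
#' @export
validate_site_table <- function(sites, sequences) {
  sites$position <- as.integer(sites$position)
  key <- paste(sites$protein_id, sites$position)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop(sprintf("duplicate site record: protein %s", d))
  }
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]
    pos <- sites$position[i]
    if (!pid %in% names(sequences))
      stop(sprintf("site table: unknown protein %s", pid))
    seq <- sequences[[pid]]
    if (is.na(pos) || pos < 1L || pos > nchar(seq))
      stop(sprintf("site table: protein %s position %s outside sequence (length %d)",
                   pid, pos, nchar(seq)))
    actual <- substr(seq, pos, pos)
    if (actual != sites$residue[i])
      stop(sprintf("site table: protein %s position %d holds '%s', not '%s'",
                   pid, pos, actual, sites$residue[i]))
  }
  sites
}

#' Read an ortholog pairing table
#'
#' Columns `human_id`, `organism`, `ortholog_id`. Duplicate pairings for one
#' (human protein, organism) — e.g. co-orthologs — keep the first record
#' with a warning.
#'
#' @param path TSV path.
#' @return Data frame of pairings.
#' @export
read_ortholog_map <- function(path) {
  df <- .read_tsv(path, c("human_id", "organism", "ortholog_id"))
  key <- paste(df$human_id, df$organism)
  if (anyDuplicated(key)) {
    warning(sprintf("%s: %d duplicate (human, organism) pairings, keeping the first",
                    path, sum(duplicated(key))))
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df
}

#' Read an aligned human/ortholog pair from a two-record aligned FASTA
#'
#' The first record is the gapped human sequence, the second the gapped
#' ortholog; both must have equal aligned length.
#'
#' @param path Aligned FASTA path.
#' @param human_id,organism Labels stored on the returned pair; default to
#'   the record names.
#' @return An [aligned_pair()].
#' @export
read_aligned_pair <- function(path, human_id = NULL, organism = NULL) {
  x <- read_fasta(path)
  if (length(x) != 2L)
    stop(sprintf("%s: an aligned pair must hold exactly 2 records, found %d",
                 path, length(x)))
  aligned_pair(human_id %||% names(x)[1], organism %||% names(x)[2],
               x[[1]], x[[2]])
}

#' @rdname read_aligned_pair
#' @param pair An `aligned_pair` to write.
#' @export
write_aligned_pair <- function(pair, path) {
  write_fasta(stats::setNames(c(pair$aligned_human, pair$aligned_ortholog),
                              c(pair$human_id, paste0(pair$human_id, "_",
                                                      gsub("[^A-Za-z]", "", pair$organism)))),
              path)
}

#' Read protein -> category annotations
#'
#' Columns `protein_id`, `namespace`, `category`; proteins may carry many
#' categories. An empty file yields an empty mapping, not an error.
#'
#' @param path TSV path.
#' @return Data frame (possibly zero rows).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L)
    return(data.frame(protein_id = character(), namespace = character(),
                      category = character(), stringsAsFactors = FALSE))
  .read_tsv(path, c("protein_id", "namespace", "category"))
}

#' Read a proteins x tissues expression matrix
#'
#' First column `protein_id`, remaining header names are tissue names.
#' Negative values are rejected.
#'
#' @param path TSV path.
#' @return Numeric matrix with protein row names and tissue column names.
#' @export
read_expression <- function(path) {
  df <- .read_tsv(path, "protein_id")
  m <- as.matrix(df[, setdiff(names(df), "protein_id"), drop = FALSE])
  if (!is.numeric(m)) stop(sprintf("%s: non-numeric expression values", path))
  rownames(m) <- df$protein_id
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: negative expression for protein %s, tissue %s",
                 path, rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  m
}

#' Read an undirected interaction edge list
#'
#' Columns `protein_a`, `protein_b`. Orientation is normalized; self-loops
#' and duplicated edges are retained here and handled by
#' [degree_and_hubs()].
#'
#' @param path TSV path.
#' @return Data frame of edges.
#' @export
read_edges <- function(path) {
  .read_tsv(path, c("protein_a", "protein_b"))
}

#' Write a dataset bundle to a directory of plain-text files
#'
#' Layout: `sequences.fasta` (human), `orthologs_<organism>.fasta`,
#' `sites.tsv`, `ortholog_map.tsv`, `alignments/<organism>/<protein>.afa`,
#' `annotations.tsv`, `expression.tsv`, `edges.tsv`, `organisms.tsv`, and
#' ground-truth tables under `ground_truth/`.
#'
#' @param bundle A dataset bundle from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  org_short <- function(x) gsub("[^A-Za-z]", "", x)
  write_fasta(bundle$sequences, file.path(dir, "sequences.fasta"))
  for (org in names(bundle$orthologs)) {
    if (length(bundle$orthologs[[org]]) == 0L) next
    write_fasta(bundle$orthologs[[org]],
                file.path(dir, sprintf("orthologs_%s.fasta", org_short(org))))
  }
  .write_tsv(bundle$site_table, file.path(dir, "sites.tsv"))
  .write_tsv(bundle$ortholog_map, file.path(dir, "ortholog_map.tsv"))
  for (org in names(bundle$alignments)) {
    adir <- file.path(dir, "alignments", org_short(org))
    dir.create(adir, recursive = TRUE, showWarnings = FALSE)
    for (pid in names(bundle$alignments[[org]]))
      write_aligned_pair(bundle$alignments[[org]][[pid]],
                         file.path(adir, paste0(pid, ".afa")))
  }
  .write_tsv(bundle$annotations, file.path(dir, "annotations.tsv"))
  expr <- data.frame(protein_id = rownames(bundle$expression),
                     bundle$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
  .write_tsv(expr, file.path(dir, "expression.tsv"))
  .write_tsv(bundle$edges, file.path(dir, "edges.tsv"))
  ord <- bundle$organism_order
  epoch_at <- rep("", length(ord$names))
  if (length(ord$epochs)) {
    keep <- ord$epochs >= 1L
    epoch_at[ord$epochs[keep]] <- names(ord$epochs)[keep]
  }
  .write_tsv(data.frame(organism = ord$names, depth = ord$depths,
                        epoch_after = epoch_at, stringsAsFactors = FALSE),
             file.path(dir, "organisms.tsv"))
  gdir <- file.path(dir, "ground_truth")
  dir.create(gdir, showWarnings = FALSE)
  .write_tsv(bundle$ground_truth$proteins, file.path(gdir, "proteins.tsv"))
  .write_tsv(bundle$ground_truth$sites, file.path(gdir, "sites.tsv"))
  invisible(dir)
}

#' Read a dataset bundle back from a directory
#'
#' Inverse of [write_bundle()]; every reader applies its validation, so a
#' round-trip is lossless for the analysis-relevant content.
#'
#' @param dir Directory written by [write_bundle()].
#' @return A dataset bundle (without `config`; `ground_truth` only if
#'   present on disk).
#' @export
read_bundle <- function(dir) {
  org_tab <- .read_tsv(file.path(dir, "organisms.tsv"), c("organism", "depth"))
  epochs <- integer()
  if (!is.null(org_tab$epoch_after)) {
    has <- nzchar(org_tab$epoch_after) & !is.na(org_tab$epoch_after)
    epochs <- stats::setNames(which(has), org_tab$epoch_after[has])
  }
  ord <- organism_order(org_tab$organism, org_tab$depth, epochs)
  org_short <- function(x) gsub("[^A-Za-z]", "", x)
  sequences <- read_fasta(file.path(dir, "sequences.fasta"))
  site_table <- read_site_table(file.path(dir, "sites.tsv"), sequences)
  ortholog_map <- read_ortholog_map(file.path(dir, "ortholog_map.tsv"))
  orthologs <- stats::setNames(vector("list", length(ord$names)), ord$names)
  alignments <- stats::setNames(vector("list", length(ord$names)), ord$names)
  for (org in ord$names) {
    ofa <- file.path(dir, sprintf("orthologs_%s.fasta", org_short(org)))
    orthologs[[org]] <- if (file.exists(ofa)) read_fasta(ofa) else character(0)
    adir <- file.path(dir, "alignments", org_short(org))
    aln <- list()
    if (dir.exists(adir)) {
      for (f in list.files(adir, pattern = "\\.afa$", full.names = TRUE)) {
        pid <- sub("\\.afa$", "", basename(f))
        aln[[pid]] <- read_aligned_pair(f, human_id = pid, organism = org)
      }
    }
    alignments[[org]] <- aln
  }
  bundle <- list(sequences = sequences, orthologs = orthologs,
                 site_table = site_table, ortholog_map = ortholog_map,
                 alignments = alignments,
                 annotations = read_annotations(file.path(dir, "annotations.tsv")),
                 expression = read_expression(file.path(dir, "expression.tsv")),
                 edges = read_edges(file.path(dir, "edges.tsv")),
                 organism_order = ord)
  gdir <- file.path(dir, "ground_truth")
  if (dir.exists(gdir)) {
    bundle$ground_truth <- list(
      proteins = .read_tsv(file.path(gdir, "proteins.tsv"), "protein_id"),
      sites = .read_tsv(file.path(gdir, "sites.tsv"), c("protein_id", "position")))
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a
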