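#' @useDynLib ubisitevol, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.aa_alphabet <- "ACDEFGHIKLMNPQRSTVWY"

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Construct an aligned human/ortholog pair
#'
#' Validates the two gapped sequences (equal length, no all-gap columns
#' required) and precomputes the map from 1-based human positions to
#' alignment columns.
#'
#' @param human_id,organism Identifiers.
#' @param aligned_human,aligned_ortholog Gapped sequences (`-` for gaps), of
#'   equal length.
#' @return An object of class `aligned_pair` with a strictly increasing
#'   `column_of_position` map.
#' @export
aligned_pair <- function(human_id, organism, aligned_human, aligned_ortholog) {
  if (nchar(aligned_human) != nchar(aligned_ortholog))
    stop(sprintf("aligned_pair %s/%s: aligned lengths differ", human_id, organism))
  cols_h <- strsplit(aligned_human, "", fixed = TRUE)[[1]]
  structure(list(human_id = human_id, organism = organism,
                 aligned_human = aligned_human,
                 aligned_ortholog = aligned_ortholog,
                 column_of_position = which(cols_h != "-")),
            class = "aligned_pair")
}

#' Ungapped human sequence of an aligned pair
#' @param pair An `aligned_pair`.
#' @return Character scalar.
#' @export
human_sequence <- function(pair) {
  gsub("-", "", pair$aligned_human, fixed = TRUE)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch with affine gap penalties (Gotoh recursion): a gap of
#' length L costs `gap_open + L * gap_extend`. The default scoring matrix is
#' BLOSUM62 with gap open 10 and gap extend 1. Ties in the traceback are
#' broken deterministically by preferring a match column, then a gap in the
#' second sequence, then a gap in the first. Downstream statistics use only
#' residue identity at aligned positions, so any fixed, documented
#' convention serves; this one is stated so runs are reproducible.
#'
#' @param seq_a,seq_b Nonempty sequences over the 20 standard amino acids.
#' @param matrix Substitution matrix with residue dimnames; defaults to
#'   BLOSUM62 as distributed with Biostrings.
#' @param gap_open,gap_extend Nonnegative gap penalties.
#' @param ids Optional `c(human_id, organism)` labels for the returned pair.
#' @return An `aligned_pair` with an extra `score` element.
#' @export
global_align <- function(seq_a, seq_b, matrix = NULL,
                         gap_open = 10, gap_extend = 1,
                         ids = c("seq_a", "seq_b")) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("global_align: sequences must be nonempty")
  if (is.null(matrix)) matrix <- blosum62_matrix()
  letters_m <- rownames(matrix)
  if (is.null(letters_m) || any(nchar(letters_m) != 1L))
    stop("global_align: scoring matrix needs one-letter dimnames")
  alphabet <- paste(letters_m, collapse = "")
  res <- .nw_align_cpp(seq_a, seq_b, matrix, alphabet, gap_open, gap_extend)
  pair <- aligned_pair(ids[1], ids[2], res$aligned_a, res$aligned_b)
  pair$score <- res$score
  pair
}

#' Orthologous residue at a human site position
#'
#' Looks up the alignment column of a 1-based human position and returns the
#' ortholog residue there: a one-letter amino acid, `"-"` when the ortholog
#' has a gap, or `NA` when `pair` itself is `NULL` (no ortholog in that
#' organism).
#'
#' @param pair An `aligned_pair`, or `NULL` for a missing ortholog.
#' @param position 1-based position in the ungapped human sequence.
#' @return Character scalar (or `NA_character_`).
#' @export
map_site <- function(pair, position) {
  if (is.null(pair)) return(NA_character_)
  cols <- pair$column_of_position
  if (position < 1L || position > length(cols))
    stop(sprintf("map_site: position %d outside protein %s (length %d)",
                 position, pair$human_id, length(cols)))
  substr(pair$aligned_ortholog, cols[position], cols[position])
}

#' Flanking-background positions of a site
#'
#' The evolutionary background of a site is the ten residues centered on it:
#' up to `half_width` positions on each side, excluding the site itself and
#' truncated at the protein termini. With `exclude_lysines = TRUE` flank
#' positions holding a lysine in the human sequence are dropped (the
#' alternative reading of using non-lysine flanks only); by default lysines
#' in the flank are retained.
#'
#' @param protein_length Protein length in residues.
#' @param site_position 1-based site position.
#' @param half_width Residues on each side (default 5).
#' @param sequence Human sequence; only needed when `exclude_lysines = TRUE`.
#' @param exclude_lysines Drop flank positions that are lysines in human.
#' @return Integer vector of 1-based positions.
#' @export
flank_positions <- function(protein_length, site_position, half_width = 5L,
                            sequence = NULL, exclude_lysines = FALSE) {
  if (site_position < 1L || site_position > protein_length)
    stop("flank_positions: site outside protein")
  pos <- setdiff(seq(max(1L, site_position - half_width),
                     min(protein_length, site_position + half_width)),
                 site_position)
  if (exclude_lysines) {
    if (is.null(sequence))
      stop("flank_positions: 'sequence' required when exclude_lysines = TRUE")
    res <- substring(sequence, pos, pos)
    pos <- pos[res != "K"]
  }
  as.integer(pos)
}

#' Per-organism residue profile of one site (species ladder)
#'
#' Stacks the human-anchored pairwise alignments of one protein into the
#' per-organism residue vector at a site, ordered along the organism ladder;
#' `NA` marks organisms without an ortholog.
#'
#' @param pairs Named list of `aligned_pair` objects (names = organisms);
#'   organisms absent from the list are reported `NA`.
#' @param position 1-based human site position.
#' @param order An `organism_order`.
#' @return Named character vector over `order$names`.
#' @export
site_profile <- function(pairs, position, order) {
  stopifnot(inherits(order, "organism_order"))
  present <- Filter(Negate(is.null), pairs)
  ids <- unique(vapply(present, function(p) p$human_id, character(1)))
  if (length(ids) > 1L)
    stop("site_profile: pairs reference different human proteins")
  out <- vapply(order$names, function(org) {
    p <- pairs[[org]]
    if (is.null(p)) NA_character_ else map_site(p, position)
  }, character(1))
  names(out) <- order$names
  out
}

#' Site and flank observation tables for a dataset bundle
#'
#' Walks every ubiquitination site of the bundle across every organism and
#' records the orthologous residue at the site ([site_observations()]) or at
#' each flanking position ([flank_observations()]). Overlapping flanks of
#' nearby sites are pooled with repetition: each site contributes its full
#' flank. These long tables are the input of [site_flank_table()] and
#' [partition_and_compare()].
#'
#' @param bundle A dataset bundle (see [simulate_dataset()] /
#'   [read_bundle()]).
#' @param half_width,exclude_lysines Flank definition, see
#'   [flank_positions()].
#' @return Data frame with columns `protein_id`, `site_position`, `position`,
#'   `organism`, `region`, `human_res`, `orth_res`.
#' @export
site_observations <- function(bundle) {
  .observations(bundle, region = "site")
}

#' @rdname site_observations
#' @export
flank_observations <- function(bundle, half_width = 5L, exclude_lysines = FALSE) {
  .observations(bundle, region = "flank", half_width = half_width,
                exclude_lysines = exclude_lysines)
}

.observations <- function(bundle, region, half_width = 5L,
                          exclude_lysines = FALSE) {
  sites <- bundle$site_table
  order <- bundle$organism_order
  by_prot <- split(seq_len(nrow(sites)), sites$protein_id)
  out <- vector("list", length(by_prot) * length(order$names))
  k <- 0L
  for (pid in names(by_prot)) {
    seq_h <- bundle$sequences[[pid]]
    idx <- by_prot[[pid]]
    if (region == "site") {
      pos <- sites$position[idx]
      spos <- pos
    } else {
      fl <- lapply(sites$position[idx], function(p)
        flank_positions(nchar(seq_h), p, half_width, sequence = seq_h,
                        exclude_lysines = exclude_lysines))
      pos <- unlist(fl)
      if (length(pos) == 0L) next
      spos <- rep(sites$position[idx], lengths(fl))
    }
    hres <- substring(seq_h, pos, pos)
    for (org in order$names) {
      pair <- bundle$alignments[[org]][[pid]]
      ores <- if (is.null(pair)) rep(NA_character_, length(pos)) else {
        cols <- pair$column_of_position[pos]
        substring(pair$aligned_ortholog, cols, cols)
      }
      k <- k + 1L
      out[[k]] <- data.frame(protein_id = pid, site_position = spos,
                             position = pos, organism = org, region = region,
                             human_res = hres, orth_res = ores,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out[seq_len(k)], list(make.row.names = FALSE)))
}
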