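#' Infer the emergence epoch of a ubiquitination site
#'
#' Given the per-organism residue vector of a human lysine site along the
#' ladder, places the gain at the boundary just beyond the most distant
#' organism still carrying a lysine ("first appearance" rule). Organisms
#' without an ortholog (`NA`) are uninformative and skipped. In
#' `mode = "strict"` every organism closer than that boundary must also
#' carry a lysine (where observed); a profile violating this — evidence of a
#' secondary loss — is marked unresolved rather than timed. Sites whose
#' coverage is entirely missing beyond the inferred boundary are assigned
#' the youngest consistent epoch and flagged `low_coverage`.
#'
#' @param profile Named character vector over `order$names` (one-letter
#'   residues, `"-"` for gap, `NA` for missing ortholog), as produced by
#'   [site_profile()].
#' @param order An `organism_order`.
#' @param mode `"first_appearance"` (default) or `"strict"`.
#' @param human_residue The human residue at the site; must be `"K"`.
#' @return List with `boundary` (integer, `NA` if unresolved), `epoch`
#'   (label), `resolved`, `low_coverage`.
#' @export
infer_gain_epoch <- function(profile, order,
                             mode = c("first_appearance", "strict"),
                             human_residue = "K") {
  mode <- match.arg(mode)
  stopifnot(inherits(order, "organism_order"))
  if (!identical(human_residue, "K"))
    stop("infer_gain_epoch: human residue must be 'K'")
  profile <- profile[order$names]
  n <- length(profile)
  is_k <- !is.na(profile) & profile == "K"
  b <- if (any(is_k)) max(which(is_k)) else 0L
  if (mode == "strict" && b > 0L) {
    closer <- profile[seq_len(b)]
    if (any(!is.na(closer) & closer != "K"))
      return(list(boundary = NA_integer_, epoch = "unresolved",
                  resolved = FALSE, low_coverage = FALSE))
  }
  low_cov <- b < n && all(is.na(profile[(b + 1L):n]))
  list(boundary = as.integer(b), epoch = epoch_label(b, order),
       resolved = TRUE, low_coverage = low_cov)
}

#' Gain table for every site of a dataset bundle
#'
#' Builds the species-ladder profile of each site from the human-anchored
#' alignments and applies [infer_gain_epoch()].
#'
#' @param bundle A dataset bundle.
#' @param mode Passed to [infer_gain_epoch()].
#' @return Data frame: `protein_id`, `position`, `boundary`, `epoch`,
#'   `resolved`, `low_coverage`.
#' @export
gain_table <- function(bundle, mode = c("first_appearance", "strict")) {
  mode <- match.arg(mode)
  ord <- bundle$organism_order
  sites <- bundle$site_table
  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    pid <- sites$protein_id[i]
    pairs <- lapply(stats::setNames(ord$names, ord$names),
                    function(org) bundle$alignments[[org]][[pid]])
    prof <- vapply(ord$names, function(org) {
      p <- pairs[[org]]
      if (is.null(p)) NA_character_ else map_site(p, sites$position[i])
    }, character(1))
    g <- infer_gain_epoch(prof, ord, mode = mode)
    rows[[i]] <- data.frame(protein_id = pid, position = sites$position[i],
                            boundary = g$boundary, epoch = g$epoch,
                            resolved = g$resolved, low_coverage = g$low_coverage,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Count gained sites per epoch boundary
#'
#' Partitions the resolved sites of a gain table over the epoch boundaries,
#' reported from the most ancient boundary to the youngest (the order in
#' which gain counts are conventionally plotted).
#'
#' @param gains Data frame from [gain_table()].
#' @param order An `organism_order`.
#' @return Data frame: `boundary`, `epoch`, `count`; counts over all rows
#'   sum to the number of resolved sites.
#' @export
count_gains_per_epoch <- function(gains, order) {
  stopifnot(inherits(order, "organism_order"))
  res <- gains[gains$resolved, , drop = FALSE]
  bs <- seq(length(order$names), 0L)
  data.frame(boundary = bs, epoch = epoch_label(bs, order),
             count = vapply(bs, function(b) sum(res$boundary == b), integer(1)),
             stringsAsFactors = FALSE)
}

#' Hypergeometric tail probabilities for a category draw
#'
#' With `N` background proteins of which `K` belong to a category, and `n`
#' drawn proteins of which `k` fall in the category: `p_enrich = P(X >= k)`
#' and `p_deplete = P(X <= k)` for `X` hypergeometric. Vectorized over all
#' arguments.
#'
#' @param k Observed overlap count(s).
#' @param K Category size(s).
#' @param N Background size(s).
#' @param n Draw size(s).
#' @return List of numeric vectors `p_enrich`, `p_deplete`.
#' @export
hypergeom_tails <- function(k, K, N, n) {
  list(p_enrich = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
       p_deplete = stats::phyper(k, K, N - K, n))
}

#' Hypergeometric enrichment of categories among gained-site proteins
#'
#' For each category: with `N` background proteins, `K` of them in the
#' category and `n` gained-site proteins of which `k` fall in the category,
#' the upper hypergeometric tail `P(X >= k)` tests enrichment and the lower
#' tail `P(X <= k)` depletion; the reported direction is the smaller tail
#' and its p-value is Bonferroni-corrected across the categories tested.
#' The random expectation is the hypergeometric mean `n K / N`.
#'
#' @param gained Character vector of gained-site proteins (subset of
#'   `background`).
#' @param background Character vector, the protein universe (by default the
#'   set of all ubiquitinated proteins in the dataset, not the whole
#'   proteome).
#' @param categories Data frame `protein_id`, `category` (many-to-many).
#' @param alpha Significance level applied to `corrected_p` for the
#'   `significant` flag (default 0.05).
#' @return Data frame: `category`, `observed`, `expected`, `p_enrich`,
#'   `p_deplete`, `direction`, `p_value`, `corrected_p`, `significant`.
#' @export
enrichment <- function(gained, background, categories, alpha = 0.05) {
  background <- unique(background)
  gained <- unique(gained)
  if (length(background) == 0L) stop("enrichment: empty background")
  if (!all(gained %in% background))
    stop("enrichment: gained proteins must be a subset of the background")
  categories <- unique(categories[categories$protein_id %in% background,
                                  c("protein_id", "category")])
  labels <- sort(unique(categories$category))
  N <- length(background)
  n <- length(gained)
  m <- length(labels)
  rows <- lapply(labels, function(cat) {
    inc <- unique(categories$protein_id[categories$category == cat])
    K <- length(inc)
    k <- length(intersect(gained, inc))
    tails <- hypergeom_tails(k, K, N, n)
    p_up <- tails$p_enrich
    p_lo <- tails$p_deplete
    enriched <- p_up <= p_lo
    p <- min(p_up, p_lo)
    data.frame(category = cat, observed = k, expected = n * K / N,
               p_enrich = p_up, p_deplete = p_lo,
               direction = if (enriched) "enriched" else "depleted",
               p_value = p, corrected_p = min(1, p * m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$significant <- out$corrected_p < alpha
  out
}
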