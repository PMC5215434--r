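#' Relative Poisson distance of sites to their flanking background
#'
#' The ratio `d_sites / d_flanks` within one protein group and organism. The
#' ratio removes group-level conservation differences (a category whose
#' whole proteins evolve slowly has small `d` for both regions but `r`
#' near the pooled norm), so categories become comparable. The variance is
#' the delta-method expansion of the ratio:
#' `var(r) = var(d)/d'^2 + d^2 var(d')/d'^4`.
#'
#' @param sites,flanks `poisson_estimate` objects for the same group and
#'   organism.
#' @return List with `r`, `var_r`, `d_site`, `d_flank`.
#' @export
relative_distance <- function(sites, flanks) {
  if (flanks$d <= 0)
    stop("relative_distance: degenerate background (flank distance is zero)")
  r <- sites$d / flanks$d
  var_r <- sites$var_d / flanks$d^2 + sites$d^2 * flanks$var_d / flanks$d^4
  list(r = r, var_r = var_r, d_site = sites$d, d_flank = flanks$d)
}

#' z-test between the relative distances of two protein groups
#'
#' `z = (r_i - r_j) / sqrt(var_i + var_j)`, approximately standard normal
#' under equal relative conservation; antisymmetric in the argument order.
#' Per-organism z-scores are combined with [combine_chi_square()].
#'
#' @param r_i,r_j Results of [relative_distance()] for groups i and j in the
#'   same organism.
#' @return List with `z` and two-sided `p_value`.
#' @export
compare_groups <- function(r_i, r_j) {
  v <- r_i$var_r + r_j$var_r
  if (v <= 0) stop("compare_groups: both variances are zero, z undefined")
  z <- (r_i$r - r_j$r) / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Tissue-specificity score (TSPS) of an expression profile
#'
#' Relative entropy (base 2) between the fractional expression of a protein
#' across tissues and the uniform null: `TSPS = sum_j p_j log2(p_j / q_j)`
#' with `p_j = e_j / sum(e)`, `q_j = 1/N` and the convention
#' `0 * log 0 = 0`. TSPS is 0 for uniform expression, `log2(N)` when all
#' expression falls in one tissue (about 5 bits for ~32 tissues), and
#' invariant under scaling. Proteins with `TSPS < 1` are classed
#' "facilitator" (widespread expression), those with `TSPS >= 1`
#' "specifier".
#'
#' @param profile Nonnegative expression vector over tissues (length >= 2),
#'   with positive sum.
#' @param threshold Facilitator/specifier cut (default 1 bit).
#' @return List with `tsps` (bits) and `class`.
#' @export
tsps <- function(profile, threshold = 1) {
  if (any(profile < 0)) stop("tsps: negative expression value")
  if (length(profile) < 2L) stop("tsps: need at least 2 tissues")
  total <- sum(profile)
  if (total <= 0) stop("tsps: all-zero expression vector")
  p <- profile / total
  q <- 1 / length(profile)
  nz <- p > 0
  score <- sum(p[nz] * log2(p[nz] / q))
  list(tsps = score,
       class = if (score < threshold) "facilitator" else "specifier")
}

#' TSPS table for an expression matrix
#'
#' Applies [tsps()] to every row; all-zero proteins are excluded with a
#' warning.
#'
#' @param expression Proteins x tissues matrix.
#' @param threshold Facilitator/specifier cut (default 1 bit).
#' @return Data frame: `protein_id`, `tsps`, `class`.
#' @export
tsps_table <- function(expression, threshold = 1) {
  zero <- rowSums(expression) <= 0
  if (any(zero)) {
    warning(sprintf("tsps_table: excluding %d all-zero protein(s): %s",
                    sum(zero), paste(utils::head(rownames(expression)[zero], 5),
                                     collapse = ", ")))
    expression <- expression[!zero, , drop = FALSE]
  }
  res <- apply(expression, 1L, tsps, threshold = threshold)
  data.frame(protein_id = rownames(expression),
             tsps = vapply(res, `[[`, numeric(1), "tsps"),
             class = vapply(res, `[[`, character(1), "class"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Interaction-network degrees and hub calls
#'
#' Degree is the number of *distinct* interaction partners: the edge list is
#' treated as undirected, duplicate edges (in either orientation) are
#' collapsed and self-loops removed. Hubs are proteins with degree strictly
#' greater than `min_degree_exclusive` (default 20).
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`.
#' @param proteins Optional protein universe; proteins without any edge are
#'   reported with degree 0.
#' @param min_degree_exclusive Hub threshold, exclusive (default 20).
#' @return Data frame: `protein_id`, `degree`, `is_hub`.
#' @export
degree_and_hubs <- function(edges, proteins = NULL, min_degree_exclusive = 20L) {
  verts <- unique(c(edges$protein_a, edges$protein_b, proteins))
  g <- igraph::graph_from_data_frame(edges[, c("protein_a", "protein_b")],
                                     directed = FALSE, vertices = verts)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(g)
  data.frame(protein_id = names(deg), degree = as.integer(deg),
             is_hub = as.integer(deg) > min_degree_exclusive,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare ubiquitination-site conservation between protein groups
#'
#' Partitions the observation tables by a protein grouping (functional
#' category, facilitator/specifier, hub/non-hub, ...), computes per group
#' and organism the pooled site and flank Poisson estimates and the relative
#' distance, and contrasts groups with per-organism z-scores plus the
#' chi-square combination. Proteins annotated to several groups contribute
#' to each. Two contrast modes: `"pairwise"` (every group pair) and
#' `"vs_rest"` (each group against the pool of proteins *not* annotated to
#' it, e.g. "metabolism vs other pathways").
#'
#' @param obs Row-bound [site_observations()] and [flank_observations()]
#'   table.
#' @param groups Data frame `protein_id`, `group` (many-to-many allowed).
#' @param order An `organism_order`.
#' @param contrast `"pairwise"` or `"vs_rest"`.
#' @param gap_as_diff Passed to [count_substitutions()].
#' @return List with `estimates` (one row per group x organism: counts, d,
#'   var_d for both regions, r, var_r) and `contrasts` (one row per group
#'   pair x organism plus a combined row per pair).
#' @export
partition_and_compare <- function(obs, groups, order,
                                  contrast = c("pairwise", "vs_rest"),
                                  gap_as_diff = TRUE) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(order, "organism_order"))
  groups <- unique(groups[, c("protein_id", "group")])
  labels <- sort(unique(groups$group))
  members <- split(groups$protein_id, groups$group)

  cells <- if (contrast == "vs_rest") {
    all_prot <- unique(obs$protein_id)
    out <- list()
    for (g in labels) {
      out[[g]] <- members[[g]]
      out[[paste0("not_", g)]] <- setdiff(all_prot, members[[g]])
    }
    out
  } else members

  # per-cell, per-organism estimates
  est_rows <- list()
  rel <- list()  # rel[[cell]][[organism]] -> relative_distance result
  for (cell in names(cells)) {
    sub <- obs[obs$protein_id %in% cells[[cell]], , drop = FALSE]
    rel[[cell]] <- list()
    for (org in order$names) {
      so <- sub[sub$organism == org & sub$region == "site", , drop = FALSE]
      fo <- sub[sub$organism == org & sub$region == "flank", , drop = FALSE]
      ok <- nrow(so) > 0L && nrow(fo) > 0L &&
        !all(is.na(so$orth_res)) && !all(is.na(fo$orth_res))
      if (!ok) {
        warning(sprintf("partition_and_compare: empty cell %s / %s skipped",
                        cell, org))
        next
      }
      cs <- count_substitutions(so$human_res, so$orth_res, gap_as_diff)
      cf <- count_substitutions(fo$human_res, fo$orth_res, gap_as_diff)
      es <- poisson_estimate(cs$n_diff, cs$n_total)
      ef <- poisson_estimate(cf$n_diff, cf$n_total)
      rd <- if (ef$d > 0) relative_distance(es, ef) else NULL
      if (!is.null(rd)) rel[[cell]][[org]] <- rd
      est_rows[[paste(cell, org)]] <- data.frame(
        group = cell, organism = org,
        n_total_site = cs$n_total, n_total_flank = cf$n_total,
        d_site = es$d, var_d_site = es$var_d,
        d_flank = ef$d, var_d_flank = ef$var_d,
        r = if (is.null(rd)) NA_real_ else rd$r,
        var_r = if (is.null(rd)) NA_real_ else rd$var_r,
        stringsAsFactors = FALSE)
    }
  }
  estimates <- do.call(rbind, c(est_rows, list(make.row.names = FALSE)))

  pairs <- if (contrast == "vs_rest") {
    lapply(labels, function(g) c(g, paste0("not_", g)))
  } else if (length(labels) >= 2L) {
    utils::combn(labels, 2L, simplify = FALSE)
  } else list()

  ctr_rows <- list()
  for (pr in pairs) {
    zs <- numeric()
    for (org in order$names) {
      ri <- rel[[pr[1]]][[org]]
      rj <- rel[[pr[2]]][[org]]
      if (is.null(ri) || is.null(rj)) next
      if (ri$var_r + rj$var_r <= 0) {
        warning(sprintf("partition_and_compare: zero-variance contrast %s vs %s in %s skipped",
                        pr[1], pr[2], org))
        next
      }
      ct <- compare_groups(ri, rj)
      zs <- c(zs, ct$z)
      ctr_rows[[paste(pr[1], pr[2], org)]] <- data.frame(
        group_i = pr[1], group_j = pr[2], organism = org,
        r_i = ri$r, r_j = rj$r, z = ct$z, p_value = ct$p_value,
        stars = significance_stars(ct$p_value), stringsAsFactors = FALSE)
    }
    if (length(zs)) {
      comb <- combine_chi_square(zs)
      ctr_rows[[paste(pr[1], pr[2], "combined")]] <- data.frame(
        group_i = pr[1], group_j = pr[2], organism = "combined",
        r_i = NA_real_, r_j = NA_real_, z = comb$mean_z,
        p_value = comb$p_value, stars = significance_stars(comb$p_value),
        stringsAsFactors = FALSE)
    }
  }
  contrasts <- if (length(ctr_rows))
    do.call(rbind, c(ctr_rows, list(make.row.names = FALSE)))
  else data.frame()
  list(estimates = estimates, contrasts = contrasts)
}
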