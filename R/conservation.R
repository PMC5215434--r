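#' Pooled substitution counts for a group of site or flank observations
#'
#' Counts, across all observations pooled together (never averaged per
#' site), how many orthologous residues differ from the human residue.
#' Observations with a missing ortholog (`NA`) are dropped before counting.
#' An alignment gap at the orthologous position counts as "different" when
#' `gap_as_diff = TRUE` (the default: a deleted lysine cannot be
#' ubiquitinated) and is excluded from both numerator and denominator
#' otherwise.
#'
#' @param human_res Character vector of human residues (one-letter code).
#' @param orth_res Character vector of orthologous residues; `"-"` for an
#'   alignment gap, `NA` for a missing ortholog.
#' @param gap_as_diff Logical; see above.
#' @return A list with elements `n_diff` and `n_total`.
#' @export
count_substitutions <- function(human_res, orth_res, gap_as_diff = TRUE) {
  if (length(human_res) != length(orth_res))
    stop("count_substitutions: residue vectors differ in length")
  keep <- !is.na(orth_res)
  human_res <- human_res[keep]
  orth_res <- orth_res[keep]
  if (!gap_as_diff) {
    keep <- orth_res != "-"
    human_res <- human_res[keep]
    orth_res <- orth_res[keep]
  }
  if (length(orth_res) == 0L) stop("count_substitutions: empty group")
  list(n_diff = sum(orth_res != human_res), n_total = length(orth_res))
}

#' Poisson-corrected evolutionary distance with binomial variance
#'
#' From a pooled substitution count, computes the difference proportion
#' `p = n_diff / n_total`, its binomial variance `p(1 - p) / n_total`, the
#' Poisson-corrected distance `d = -ln(1 - p)` (which corrects for multiple
#' substitutions at a position and is linear in time under a Poisson
#' substitution model) and its variance `var(p) / (1 - p)^2` obtained by the
#' delta method.
#'
#' A saturated group (`p = 1`) has infinite distance; by default it is
#' clamped to `p = (n_total - 0.5) / n_total` with a warning so pooled
#' pipelines keep running on tiny groups; set `saturated = "error"` to fail
#' instead.
#'
#' @param n_diff,n_total Pooled counts, `0 <= n_diff <= n_total`.
#' @param saturated `"clamp"` (default) or `"error"`: behaviour at `p = 1`.
#' @return An object of class `poisson_estimate`: list with `p`, `var_p`,
#'   `d`, `var_d`, `n_diff`, `n_total`.
#' @examples
#' poisson_estimate(50, 100)  # d = ln 2, var_d = 0.01
#' @export
poisson_estimate <- function(n_diff, n_total, saturated = c("clamp", "error")) {
  saturated <- match.arg(saturated)
  if (is.list(n_diff)) {  # accept a count_substitutions() result directly
    n_total <- n_diff$n_total
    n_diff <- n_diff$n_diff
  }
  if (n_total < 1) stop("poisson_estimate: n_total must be >= 1")
  if (n_diff < 0 || n_diff > n_total)
    stop("poisson_estimate: need 0 <= n_diff <= n_total")
  if (n_diff == n_total) {
    if (saturated == "error")
      stop("poisson_estimate: saturated group (p = 1), distance undefined")
    warning(sprintf(
      "poisson_estimate: saturated group (%d/%d), clamping p to (n - 0.5)/n",
      n_diff, n_total))
    n_diff <- n_total - 0.5
  }
  p <- n_diff / n_total
  var_p <- p * (1 - p) / n_total
  d <- -log(1 - p) + 0  # + 0 normalizes IEEE negative zero at p = 0
  var_d <- var_p / (1 - p)^2
  structure(list(p = p, var_p = var_p, d = d, var_d = var_d,
                 n_diff = n_diff, n_total = n_total),
            class = "poisson_estimate")
}

#' @export
print.poisson_estimate <- function(x, ...) {
  cat(sprintf("Poisson distance d = %.4f (var %.3g), p = %.4f [%s/%d]\n",
              x$d, x$var_d, x$p, format(x$n_diff), x$n_total))
  invisible(x)
}

#' Two-sample z-test between two Poisson distances
#'
#' Tests whether ubiquitination sites and their flanking background (or any
#' two groups) evolved at the same rate in one reference organism:
#' `z = (d1 - d2) / sqrt(var_d1 + var_d2)`, approximately standard normal
#' under the null; the reported p-value is two-sided.
#'
#' @param est1,est2 `poisson_estimate` objects (or any lists with `d` and
#'   `var_d`), e.g. sites and flanks of one protein group in one organism.
#' @return List with `z`, `p_value`, and the two distances.
#' @export
z_site_vs_flank <- function(est1, est2) {
  v <- est1$var_d + est2$var_d
  if (v <= 0) stop("z_site_vs_flank: both variances are zero, z undefined")
  z <- (est1$d - est2$d) / sqrt(v)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), d1 = est1$d, d2 = est2$d)
}

#' Combine per-organism z-scores into one chi-square test
#'
#' Across `n` reference organisms the summed squared z-scores follow a
#' chi-square distribution with `n` degrees of freedom under the null of
#' equal rates everywhere. The mean z is reported alongside as the direction
#' of the departure (negative: first group more conserved).
#'
#' @param z Numeric vector of per-organism z-scores (non-finite entries are
#'   an error).
#' @return List with `statistic`, `df`, `p_value`, `mean_z`.
#' @export
combine_chi_square <- function(z) {
  z <- as.numeric(z)
  if (length(z) == 0L) stop("combine_chi_square: empty z list")
  if (any(!is.finite(z))) stop("combine_chi_square: non-finite z-score")
  statistic <- sum(z^2)
  df <- length(z)
  list(statistic = statistic, df = df,
       p_value = stats::pchisq(statistic, df = df, lower.tail = FALSE),
       mean_z = mean(z))
}

#' Significance tiers used in the report tables
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                         ifelse(p < 0.05, "*", ""))))
}

#' Site-versus-flank conservation table across organisms
#'
#' The per-organism core of the analysis: pools site and flank observations
#' of one protein group, estimates Poisson distances for both regions in
#' every organism, tests them against each other with a z-score, and
#' combines the per-organism z-scores into one overall chi-square p-value.
#'
#' @param obs Observation data frame as returned by [site_observations()]
#'   row-bound with [flank_observations()]: columns `organism`, `region`
#'   (`"site"`/`"flank"`), `human_res`, `orth_res`.
#' @param order An `organism_order`; organisms absent from `obs` (or with an
#'   empty region) are skipped with a warning.
#' @param gap_as_diff Passed to [count_substitutions()].
#' @return A list with `per_organism` (data frame: organism, region counts,
#'   p, d, var_d for both regions, z, p_value, stars) and `combined`
#'   (chi-square combination over the contributing organisms).
#' @export
site_flank_table <- function(obs, order, gap_as_diff = TRUE) {
  stopifnot(inherits(order, "organism_order"))
  rows <- list()
  zs <- numeric()
  for (org in order$names) {
    sub <- obs[obs$organism == org, , drop = FALSE]
    s <- sub[sub$region == "site", , drop = FALSE]
    f <- sub[sub$region == "flank", , drop = FALSE]
    if (nrow(s) == 0L || nrow(f) == 0L ||
        all(is.na(s$orth_res)) || all(is.na(f$orth_res))) {
      warning(sprintf("site_flank_table: no usable observations for %s, skipped", org))
      next
    }
    cs <- count_substitutions(s$human_res, s$orth_res, gap_as_diff)
    cf <- count_substitutions(f$human_res, f$orth_res, gap_as_diff)
    es <- poisson_estimate(cs$n_diff, cs$n_total)
    ef <- poisson_estimate(cf$n_diff, cf$n_total)
    if (es$var_d + ef$var_d <= 0) {
      warning(sprintf("site_flank_table: zero-variance contrast in %s skipped", org))
      next
    }
    zt <- z_site_vs_flank(es, ef)
    zs <- c(zs, zt$z)
    rows[[org]] <- data.frame(
      organism = org,
      n_diff_site = cs$n_diff, n_total_site = cs$n_total,
      p_site = es$p, d_site = es$d, var_d_site = es$var_d,
      n_diff_flank = cf$n_diff, n_total_flank = cf$n_total,
      p_flank = ef$p, d_flank = ef$d, var_d_flank = ef$var_d,
      z = zt$z, p_value = zt$p_value,
      stars = significance_stars(zt$p_value),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("site_flank_table: no organism had usable observations")
  list(per_organism = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       combined = combine_chi_square(zs))
}
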