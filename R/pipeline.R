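#' Pipeline configuration
#'
#' One object holds everything a full run needs: either a synthetic-data
#' configuration (`mode = "synthetic"`) or a directory of input files in the
#' bundle layout (`mode = "provided"`), plus all analysis parameters. In
#' provided-data mode the input directory is validated before any
#' computation.
#'
#' @param mode `"synthetic"` or `"provided"`.
#' @param sim A [simulation_config()] (synthetic mode).
#' @param input_dir Directory in [write_bundle()] layout (provided mode).
#' @param out_dir Optional output directory for the stage TSVs.
#' @param gap_as_diff Count an orthologous gap as a substitution.
#' @param flank_half_width Flank residues on each side of a site.
#' @param exclude_flank_lysines Drop lysines from flank backgrounds.
#' @param tsps_threshold Facilitator/specifier cut in bits.
#' @param hub_min_degree Exclusive hub degree threshold.
#' @param gains_mode `"first_appearance"` or `"strict"`.
#' @param enrichment_alpha Significance level for enrichment calls.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "provided"),
                            sim = simulation_config(),
                            input_dir = NULL, out_dir = NULL,
                            gap_as_diff = TRUE,
                            flank_half_width = 5L,
                            exclude_flank_lysines = FALSE,
                            tsps_threshold = 1,
                            hub_min_degree = 20L,
                            gains_mode = c("first_appearance", "strict"),
                            enrichment_alpha = 0.05) {
  mode <- match.arg(mode)
  gains_mode <- match.arg(gains_mode)
  if (mode == "synthetic") {
    if (!inherits(sim, "simulation_config"))
      stop("pipeline_config: synthetic mode needs a simulation_config in 'sim'")
  } else {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("pipeline_config: provided-data mode needs an existing 'input_dir'")
    required <- c("sequences.fasta", "sites.tsv", "ortholog_map.tsv",
                  "annotations.tsv", "expression.tsv", "edges.tsv",
                  "organisms.tsv")
    missing <- required[!file.exists(file.path(input_dir, required))]
    if (length(missing))
      stop(sprintf("pipeline_config: missing input file(s) in %s: %s",
                   input_dir, paste(missing, collapse = ", ")))
  }
  structure(list(mode = mode, sim = sim, input_dir = input_dir,
                 out_dir = out_dir, gap_as_diff = gap_as_diff,
                 flank_half_width = as.integer(flank_half_width),
                 exclude_flank_lysines = exclude_flank_lysines,
                 tsps_threshold = tsps_threshold,
                 hub_min_degree = as.integer(hub_min_degree),
                 gains_mode = gains_mode,
                 enrichment_alpha = enrichment_alpha),
            class = "pipeline_config")
}

#' Run the full ubiquitination-site evolution pipeline
#'
#' Executes, in order: data acquisition (simulate or read), observation
#' extraction, the site-versus-flank conservation table, category contrasts
#' (KEGG-like namespace, each category versus the rest), the
#' facilitator/specifier TSPS split, the hub/non-hub split, gain-epoch
#' timing with per-epoch counts, and hypergeometric enrichment of
#' gained-site proteins per epoch (GO-like namespace, background = all
#' ubiquitinated proteins). Reruns with an identical configuration
#' reproduce identical tables. Each stage logs its record counts; a stage
#' failure aborts with the stage named and, when `out_dir` is set, leaves a
#' `failed_<stage>` marker there.
#'
#' @param config A [pipeline_config()].
#' @return List with `bundle`, `site_flank`, `categories`, `tsps_split`,
#'   `hub_split`, `gains`, `gain_counts`, `enrichment` (per epoch), and
#'   `summary` (per-organism z table with significance tiers); written as
#'   TSVs under `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        writeLines(conditionMessage(e), file.path(out_dir, paste0("failed_", name)))
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) .write_tsv(df, file.path(out_dir, paste0(name, ".tsv")))
  }

  bundle <- stage("data", {
    b <- if (config$mode == "synthetic") simulate_dataset(config$sim)
         else read_bundle(config$input_dir)
    message(sprintf("[data] %d proteins, %d sites, %d organisms",
                    length(b$sequences), nrow(b$site_table),
                    length(b$organism_order$names)))
    b
  })
  ord <- bundle$organism_order

  obs <- stage("observations", {
    o <- rbind(site_observations(bundle),
               flank_observations(bundle,
                                  half_width = config$flank_half_width,
                                  exclude_lysines = config$exclude_flank_lysines))
    message(sprintf("[observations] %d residue observations", nrow(o)))
    o
  })

  site_flank <- stage("conserve", {
    t <- site_flank_table(obs, ord, gap_as_diff = config$gap_as_diff)
    message(sprintf("[conserve] %d organisms, combined chi2 = %.2f (df %d, p = %.3g)",
                    nrow(t$per_organism), t$combined$statistic, t$combined$df,
                    t$combined$p_value))
    emit(t$per_organism, "site_flank")
    t
  })

  categories <- stage("categories", {
    kegg <- bundle$annotations[bundle$annotations$namespace == "kegg",
                               c("protein_id", "category")]
    names(kegg)[2] <- "group"
    res <- partition_and_compare(obs, kegg, ord, contrast = "vs_rest",
                                 gap_as_diff = config$gap_as_diff)
    message(sprintf("[categories] %d group cells, %d contrast rows",
                    nrow(res$estimates), nrow(res$contrasts)))
    emit(res$estimates, "category_estimates")
    emit(res$contrasts, "category_contrasts")
    res
  })

  tsps_split <- stage("tsps", {
    tt <- tsps_table(bundle$expression, threshold = config$tsps_threshold)
    grp <- data.frame(protein_id = tt$protein_id, group = tt$class,
                      stringsAsFactors = FALSE)
    res <- partition_and_compare(obs, grp, ord, contrast = "pairwise",
                                 gap_as_diff = config$gap_as_diff)
    res$tsps <- tt
    message(sprintf("[tsps] %d facilitators, %d specifiers",
                    sum(tt$class == "facilitator"), sum(tt$class == "specifier")))
    emit(tt, "tsps")
    emit(res$contrasts, "tsps_contrasts")
    res
  })

  hub_split <- stage("hubs", {
    dh <- degree_and_hubs(bundle$edges, proteins = names(bundle$sequences),
                          min_degree_exclusive = config$hub_min_degree)
    grp <- data.frame(protein_id = dh$protein_id,
                      group = ifelse(dh$is_hub, "hub", "non_hub"),
                      stringsAsFactors = FALSE)
    res <- partition_and_compare(obs, grp, ord, contrast = "pairwise",
                                 gap_as_diff = config$gap_as_diff)
    res$degrees <- dh
    message(sprintf("[hubs] %d hubs of %d proteins", sum(dh$is_hub), nrow(dh)))
    emit(dh, "degrees")
    emit(res$contrasts, "hub_contrasts")
    res
  })

  gains <- stage("gains", {
    g <- gain_table(bundle, mode = config$gains_mode)
    message(sprintf("[gains] %d sites, %d resolved", nrow(g), sum(g$resolved)))
    emit(g, "gains")
    g
  })
  gain_counts <- stage("gain_counts", {
    gc <- count_gains_per_epoch(gains, ord)
    emit(gc, "gain_counts")
    gc
  })

  enrich <- stage("enrich", {
    go <- bundle$annotations[bundle$annotations$namespace == "go",
                             c("protein_id", "category")]
    background <- unique(bundle$site_table$protein_id)
    named <- ord$epochs[ord$epochs >= 1L]
    out <- list()
    for (e in names(named)) {
      gained <- unique(gains$protein_id[gains$resolved &
                                          gains$boundary == named[[e]]])
      if (length(gained) == 0L) next
      res <- enrichment(gained, background, go, alpha = config$enrichment_alpha)
      res <- cbind(epoch = e, res, stringsAsFactors = FALSE)
      out[[e]] <- res
    }
    tab <- if (length(out)) do.call(rbind, c(out, list(make.row.names = FALSE)))
           else data.frame()
    message(sprintf("[enrich] %d epoch x category tests", nrow(tab)))
    if (nrow(tab)) emit(tab, "enrichment")
    tab
  })

  summary <- stage("report", {
    po <- site_flank$per_organism
    s <- data.frame(organism = po$organism, d_site = po$d_site,
                    d_flank = po$d_flank, z = po$z, p_value = po$p_value,
                    stars = po$stars, stringsAsFactors = FALSE)
    s <- rbind(s, data.frame(organism = "combined", d_site = NA, d_flank = NA,
                             z = site_flank$combined$mean_z,
                             p_value = site_flank$combined$p_value,
                             stars = significance_stars(site_flank$combined$p_value),
                             stringsAsFactors = FALSE))
    emit(s, "summary")
    s
  })

  invisible(list(bundle = bundle, site_flank = site_flank,
                 categories = categories, tsps_split = tsps_split,
                 hub_split = hub_split, gains = gains,
                 gain_counts = gain_counts, enrichment = enrich,
                 summary = summary))
}
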