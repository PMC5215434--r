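#' Configuration of the synthetic ubiquitination-evolution dataset
#'
#' Collects and validates every knob of the generator. Defaults encode the
#' study conditions emulated throughout the package: human-sized proteins
#' carrying lysine ubiquitination sites, fourteen reference organisms at
#' increasing divergence, site/flank/background substitution-rate
#' multipliers, Dirichlet-style tissue-expression profiles spanning uniform
#' ("facilitator") to single-tissue ("specifier"), a degree-heterogeneous
#' interaction network with planted hubs, and optionally planted gain
#' epochs.
#'
#' @param n_proteins Number of human proteins.
#' @param protein_length_range Integer `c(min, max)` residues; `min >= 25`
#'   so every site has room for a full flank.
#' @param sites_per_protein Ubiquitination sites per protein.
#' @param organisms An [organism_order()]; its depths are expected
#'   background substitutions per residue.
#' @param site_rate_multiplier,flank_rate_multiplier Substitution-rate scale
#'   of site / flank positions relative to the background (`1` = neutral).
#' @param indel_rate Indel events per residue per unit depth (orthologs
#'   only; `0` disables indels).
#' @param category_labels Functional category labels (KEGG-pathway-like),
#'   one assigned per protein.
#' @param category_site_multipliers Optional named multipliers applied to
#'   the site positions of proteins in a category (category-specific site
#'   constraint or relaxation).
#' @param category_protein_multipliers Optional named multipliers applied to
#'   every position of proteins in a category (whole-protein conservation
#'   differences between categories, which the relative distance is designed
#'   to remove).
#' @param n_tissues Number of tissues in the expression matrix (`>= 2`).
#' @param expression_concentration Named numeric
#'   `c(facilitator = , specifier = )` Dirichlet concentrations; high =
#'   near-uniform profile, low = spiky.
#' @param facilitator_fraction Fraction of proteins drawn as facilitators.
#' @param hub_fraction Fraction of proteins planted as network hubs.
#' @param hub_degree_range Target degree range of planted hubs (above the
#'   hub threshold of 20).
#' @param degree_exponent Power-law exponent of non-hub target degrees.
#' @param go_labels GO-term-like labels; each protein receives one to three.
#' @param planted_gain_epochs Named integer vector, epoch label -> number of
#'   sites planted with that gain pattern.
#' @param gain_loss_rate Probability that a planted gain site suffers a
#'   secondary loss at one organism strictly interior to its conserved span.
#' @param missing_ortholog_rate Probability that a protein lacks an ortholog
#'   in a given organism.
#' @param seed Integer RNG seed; the full bundle is a pure function of the
#'   configuration.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 200L,
                              protein_length_range = c(300L, 600L),
                              sites_per_protein = 5L,
                              organisms = default_organism_order(),
                              site_rate_multiplier = 1,
                              flank_rate_multiplier = 1,
                              indel_rate = 0,
                              category_labels = c("metabolism",
                                                  "genetic_information",
                                                  "environmental_information",
                                                  "cellular_processes",
                                                  "organismal_systems",
                                                  "human_diseases"),
                              category_site_multipliers = NULL,
                              category_protein_multipliers = NULL,
                              n_tissues = 32L,
                              expression_concentration = c(facilitator = 20,
                                                           specifier = 0.15),
                              facilitator_fraction = 0.5,
                              hub_fraction = 0.1,
                              hub_degree_range = c(21L, 60L),
                              degree_exponent = 2.2,
                              go_labels = paste0("go_term_", 1:8),
                              planted_gain_epochs = NULL,
                              gain_loss_rate = 0,
                              missing_ortholog_rate = 0,
                              seed = 1L) {
  fail <- function(field, why) stop(sprintf("simulation_config: %s %s", field, why))
  if (n_proteins < 1) fail("n_proteins", "must be >= 1")
  if (length(protein_length_range) != 2L ||
      protein_length_range[1] > protein_length_range[2])
    fail("protein_length_range", "must be c(min, max) with min <= max")
  if (protein_length_range[1] < 25)
    fail("protein_length_range", "minimum length must be >= 25 (room for a flank)")
  if (sites_per_protein < 1) fail("sites_per_protein", "must be >= 1")
  if (!inherits(organisms, "organism_order"))
    fail("organisms", "must be an organism_order object")
  for (nm in c("site_rate_multiplier", "flank_rate_multiplier", "indel_rate",
               "gain_loss_rate", "missing_ortholog_rate")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) fail(nm, "must be a nonnegative scalar")
  }
  if (gain_loss_rate > 1) fail("gain_loss_rate", "must be <= 1")
  if (missing_ortholog_rate >= 1) fail("missing_ortholog_rate", "must be < 1")
  if (n_tissues < 2) fail("n_tissues", "must be >= 2")
  if (any(expression_concentration <= 0))
    fail("expression_concentration", "must be positive")
  if (!all(c("facilitator", "specifier") %in% names(expression_concentration)))
    fail("expression_concentration", "needs 'facilitator' and 'specifier' entries")
  if (facilitator_fraction < 0 || facilitator_fraction > 1)
    fail("facilitator_fraction", "must be in [0, 1]")
  if (hub_fraction < 0 || hub_fraction > 1) fail("hub_fraction", "must be in [0, 1]")
  if (hub_degree_range[1] <= 20) fail("hub_degree_range", "must start above 20")
  norm_mult <- function(m, field) {
    if (is.null(m)) return(stats::setNames(rep(1, length(category_labels)),
                                           category_labels))
    if (any(m < 0)) fail(field, "must be nonnegative")
    out <- stats::setNames(rep(1, length(category_labels)), category_labels)
    if (!all(names(m) %in% category_labels))
      fail(field, "names unknown among category_labels")
    out[names(m)] <- m
    out
  }
  category_site_multipliers <- norm_mult(category_site_multipliers,
                                         "category_site_multipliers")
  category_protein_multipliers <- norm_mult(category_protein_multipliers,
                                            "category_protein_multipliers")
  if (!is.null(planted_gain_epochs)) {
    if (is.null(names(planted_gain_epochs)))
      fail("planted_gain_epochs", "must be a named epoch -> count vector")
    epoch_boundary(names(planted_gain_epochs), organisms)  # errors on unknown
    if (sum(planted_gain_epochs) > n_proteins * sites_per_protein)
      fail("planted_gain_epochs", "requests more gains than sites exist")
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    protein_length_range = as.integer(protein_length_range),
    sites_per_protein = as.integer(sites_per_protein),
    organisms = organisms,
    site_rate_multiplier = site_rate_multiplier,
    flank_rate_multiplier = flank_rate_multiplier,
    indel_rate = indel_rate,
    category_labels = category_labels,
    category_site_multipliers = category_site_multipliers,
    category_protein_multipliers = category_protein_multipliers,
    n_tissues = as.integer(n_tissues),
    expression_concentration = expression_concentration,
    facilitator_fraction = facilitator_fraction,
    hub_fraction = hub_fraction,
    hub_degree_range = as.integer(hub_degree_range),
    degree_exponent = degree_exponent,
    go_labels = go_labels,
    planted_gain_epochs = planted_gain_epochs,
    gain_loss_rate = gain_loss_rate,
    missing_ortholog_rate = missing_ortholog_rate,
    seed = as.integer(seed)), class = "simulation_config")
}

.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Residue after N ~ Poisson(rate) uniform-replacement events, drawn from the
# exact marginal of the 20-state jump chain: P(unchanged | N = k) =
# 1/20 + (19/20) (-1/19)^k; conditional on change, uniform over the other 19.
.substitute_residues <- function(residues, rates) {
  n <- length(residues)
  k <- stats::rpois(n, rates)
  p_same <- 1 / 20 + (19 / 20) * (-1 / 19)^k
  changed <- stats::runif(n) > p_same
  out <- residues
  if (any(changed)) {
    idx <- which(changed)
    # uniform over the 19 non-identical residues: draw among the first 19
    # letters and remap a self-hit to the 20th (a bijection onto the others)
    pick <- .aa_letters[sample.int(19L, length(idx), replace = TRUE)]
    pick[pick == residues[idx]] <- .aa_letters[20L]
    out[idx] <- pick
  }
  out
}

.random_non_k <- function(n) {
  alt <- setdiff(.aa_letters, "K")
  alt[sample.int(19L, n, replace = TRUE)]
}

#' Planted per-organism residue pattern for a gained site
#'
#' A site gained at epoch boundary `b` is a lysine in human and in every
#' organism that diverged after the epoch (ladder positions `1..b`), and a
#' non-lysine in every organism that diverged before it (`b+1..n`). Non-K
#' residues are drawn uniformly from the 19 alternatives with the current
#' RNG.
#'
#' @param site A list with at least `residue` (must be `"K"`).
#' @param epoch Epoch label understood by [epoch_boundary()].
#' @param order An `organism_order`.
#' @return Named character vector over `order$names`.
#' @export
plant_gain_pattern <- function(site, epoch, order) {
  if (!identical(site$residue, "K"))
    stop("plant_gain_pattern: site residue must be 'K'")
  b <- epoch_boundary(epoch, order)
  n <- length(order$names)
  out <- c(rep("K", b), .random_non_k(n - b))
  names(out) <- order$names
  out
}

#' Generate a complete synthetic dataset with recorded ground truth
#'
#' Draws human protein sequences with planted lysine sites, evolves one
#' ortholog per organism under a per-residue Poisson substitution process
#' (rate = organism depth x region multiplier x category multiplier, with
#' uniform replacement over the 19 alternative residues), optionally
#' inserts geometric-length indels, overlays planted gain patterns, and
#' emits functional annotations, a tissue-expression matrix and a
#' degree-heterogeneous interaction edge list. The true alignments (before
#' any re-alignment) are stored in `$alignments`; everything planted is
#' recorded in `$ground_truth`.
#'
#' @param config A [simulation_config()].
#' @return A dataset bundle: list with `sequences` (named character, human),
#'   `orthologs` (per organism, named by ortholog id), `site_table`,
#'   `ortholog_map`, `alignments` (`[[organism]][[protein_id]]` ->
#'   [aligned_pair()]), `annotations`, `expression` (matrix), `edges`,
#'   `organism_order`, `ground_truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, .simulate_dataset_impl(config))
}

.simulate_dataset_impl <- function(config) {
  ord <- config$organisms
  n_org <- length(ord$names)
  n_prot <- config$n_proteins
  ids <- sprintf("UBP%04d", seq_len(n_prot))
  lengths <- sample(seq(config$protein_length_range[1],
                        config$protein_length_range[2]), n_prot, replace = TRUE)
  categories <- sample(config$category_labels, n_prot, replace = TRUE)

  # human sequences with planted K sites
  sequences <- character(n_prot)
  site_rows <- vector("list", n_prot)
  for (i in seq_len(n_prot)) {
    L <- lengths[i]
    s <- sample(.aa_letters, L, replace = TRUE)
    pos <- sort(sample.int(L, config$sites_per_protein))
    s[pos] <- "K"
    sequences[i] <- paste(s, collapse = "")
    site_rows[[i]] <- data.frame(protein_id = ids[i], position = pos,
                                 residue = "K", modification = "ubiquitination",
                                 stringsAsFactors = FALSE)
  }
  names(sequences) <- ids
  site_table <- do.call(rbind, c(site_rows, list(make.row.names = FALSE)))

  # planted gain assignments
  n_sites <- nrow(site_table)
  gain_epoch <- rep(NA_character_, n_sites)
  gain_boundary <- rep(NA_integer_, n_sites)
  loss_organism <- rep(NA_character_, n_sites)
  if (!is.null(config$planted_gain_epochs)) {
    chosen <- sample.int(n_sites, sum(config$planted_gain_epochs))
    gain_epoch[chosen] <- rep(names(config$planted_gain_epochs),
                              config$planted_gain_epochs)
    gain_boundary[chosen] <- epoch_boundary(gain_epoch[chosen], ord)
    lossy <- chosen[stats::runif(length(chosen)) < config$gain_loss_rate &
                      gain_boundary[chosen] >= 2L]
    for (j in lossy) {
      loss_organism[j] <- ord$names[sample.int(gain_boundary[j] - 1L, 1L)]
    }
  }

  # per-position rate multipliers (background 1, flanks, sites; category scale)
  mult_of <- function(i) {
    L <- lengths[i]
    m <- rep(1, L)
    pos <- site_rows[[i]]$position
    for (p in pos) m[flank_positions(L, p)] <- config$flank_rate_multiplier
    m[pos] <- config$site_rate_multiplier *
      config$category_site_multipliers[[categories[i]]]
    m * config$category_protein_multipliers[[categories[i]]]
  }

  orthologs <- stats::setNames(vector("list", n_org), ord$names)
  alignments <- stats::setNames(vector("list", n_org), ord$names)
  map_rows <- list()
  org_short <- gsub("[^A-Za-z]", "", ord$names)
  site_index <- split(seq_len(n_sites), site_table$protein_id)

  for (o in seq_len(n_org)) {
    org <- ord$names[o]
    depth <- ord$depths[o]
    seqs_o <- character(0)
    aln_o <- list()
    for (i in seq_len(n_prot)) {
      if (stats::runif(1) < config$missing_ortholog_rate) next
      res_h <- strsplit(sequences[i], "", fixed = TRUE)[[1]]
      res_o <- .substitute_residues(res_h, depth * mult_of(i))
      # overlay planted gain patterns / losses at this protein's sites
      for (j in site_index[[ids[i]]]) {
        b <- gain_boundary[j]
        if (is.na(b)) next
        p <- site_table$position[j]
        res_o[p] <- if (o <= b) "K" else .random_non_k(1L)
        if (!is.na(loss_organism[j]) && loss_organism[j] == org)
          res_o[p] <- .random_non_k(1L)
      }
      aln <- .apply_indels(res_h, res_o, config$indel_rate * depth)
      oid <- paste0(ids[i], "_", org_short[o])
      seqs_o[oid] <- gsub("-", "", aln$b, fixed = TRUE)
      aln_o[[ids[i]]] <- aligned_pair(ids[i], org, aln$a, aln$b)
      map_rows[[length(map_rows) + 1L]] <-
        data.frame(human_id = ids[i], organism = org, ortholog_id = oid,
                   stringsAsFactors = FALSE)
    }
    orthologs[[org]] <- seqs_o
    alignments[[org]] <- aln_o
  }
  ortholog_map <- do.call(rbind, c(map_rows, list(make.row.names = FALSE)))

  # annotations: one KEGG-like pathway category + 1-3 GO-like terms each
  go_n <- sample(1:3, n_prot, replace = TRUE)
  go_rows <- lapply(seq_len(n_prot), function(i)
    data.frame(protein_id = ids[i], namespace = "go",
               category = sample(config$go_labels, go_n[i]),
               stringsAsFactors = FALSE))
  annotations <- rbind(
    data.frame(protein_id = ids, namespace = "kegg", category = categories,
               stringsAsFactors = FALSE),
    do.call(rbind, c(go_rows, list(make.row.names = FALSE))))

  # tissue expression: Dirichlet profiles, spiky for specifiers
  expr_class <- ifelse(stats::runif(n_prot) < config$facilitator_fraction,
                       "facilitator", "specifier")
  expression <- t(vapply(seq_len(n_prot), function(i) {
    conc <- config$expression_concentration[[expr_class[i]]]
    w <- stats::rgamma(config$n_tissues, shape = conc)
    if (sum(w) <= 0) w[sample.int(config$n_tissues, 1L)] <- 1
    w / sum(w) * stats::rlnorm(1, log(100), 0.5)
  }, numeric(config$n_tissues)))
  dimnames(expression) <- list(ids, sprintf("tissue_%02d", seq_len(config$n_tissues)))

  # interaction network: planted hubs + power-law target degrees, stub matching
  n_hub <- round(config$hub_fraction * n_prot)
  hub_ids <- if (n_hub > 0) sample(ids, n_hub) else character(0)
  deg_target <- stats::setNames(integer(n_prot), ids)
  if (n_hub > 0)
    deg_target[hub_ids] <- sample(seq(config$hub_degree_range[1],
                                      config$hub_degree_range[2]),
                                  n_hub, replace = TRUE)
  rest <- setdiff(ids, hub_ids)
  pl <- (1:15)^(-config$degree_exponent)
  deg_target[rest] <- sample(1:15, length(rest), replace = TRUE, prob = pl / sum(pl))
  deg_target <- pmin(deg_target, n_prot - 1L)
  # each protein draws its target number of *distinct* partners; the union
  # keeps realized degree >= target, so planted hubs stay above threshold
  a <- rep(ids, deg_target)
  b <- unlist(lapply(seq_len(n_prot), function(i)
    sample(ids[-i], deg_target[i])))
  e1 <- pmin(a, b)
  e2 <- pmax(a, b)
  dup <- duplicated(paste(e1, e2))
  edges <- data.frame(protein_a = e1[!dup], protein_b = e2[!dup],
                      stringsAsFactors = FALSE)
  realized <- table(factor(c(edges$protein_a, edges$protein_b), levels = ids))

  ground_truth <- list(
    proteins = data.frame(protein_id = ids, length = lengths,
                          category = categories, expression_class = expr_class,
                          planted_hub = ids %in% hub_ids,
                          degree = as.integer(realized),
                          stringsAsFactors = FALSE),
    sites = data.frame(protein_id = site_table$protein_id,
                       position = site_table$position,
                       gain_epoch = gain_epoch,
                       gain_boundary = gain_boundary,
                       loss_organism = loss_organism,
                       stringsAsFactors = FALSE))

  list(sequences = sequences, orthologs = orthologs, site_table = site_table,
       ortholog_map = ortholog_map, alignments = alignments,
       annotations = annotations, expression = expression, edges = edges,
       organism_order = ord, ground_truth = ground_truth, config = config)
}

# Geometric-length indels applied to the ortholog only; returns the true
# aligned strings (a = human with '-', b = ortholog with '-').
.apply_indels <- function(res_h, res_o, rate_per_residue, mean_len = 3) {
  a <- res_h
  b <- res_o
  if (rate_per_residue > 0) {
    n_ev <- stats::rpois(1, rate_per_residue * length(res_h))
    for (ev in seq_len(n_ev)) {
      len <- stats::rgeom(1, 1 / mean_len) + 1L
      if (stats::runif(1) < 0.5) {  # deletion in ortholog
        live <- which(b != "-")
        if (length(live) <= len) next
        start <- sample.int(length(live) - len + 1L, 1L)
        b[live[start:(start + len - 1L)]] <- "-"
      } else {                      # insertion in ortholog
        at <- sample.int(length(a) + 1L, 1L)
        ins_a <- rep("-", len)
        ins_b <- sample(.aa_letters, len, replace = TRUE)
        a <- append(a, ins_a, after = at - 1L)
        b <- append(b, ins_b, after = at - 1L)
      }
    }
  }
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
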