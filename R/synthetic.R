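#' Configuration for the synthetic two-group expression study
#'
#' Describes a simulated 3-vs-3 case/control design profiled on both a
#' qPCR Ct array (miRNAs) and a microarray (genes), with planted
#' two-sided differential expression, a miRNA target map enriched for
#' inversely regulated genes, and a regulatory knowledge graph containing
#' intermediate regulator nodes.
#'
#' Defaults emulate a small rodent brain study: 3 animals per group,
#' miRNA baselines uniform on 18-30 Ct (the range of reliably detected
#' assays; values drift above the detection limit through noise and
#' planted downshifts), replicate noise of 0.3 cycles, a planted shift of
#' 2 cycles (fourfold), gene baselines uniform on 6-14 log2 units with
#' 0.25 log2 noise and a twofold planted effect. Half of the planted
#' features move in each direction. Lower Ct means higher abundance, so a
#' negative Ct shift is upregulation.
#'
#' @param n_mirnas,n_genes feature counts.
#' @param n_per_group samples per group (>= 2; default 3).
#' @param frac_de fraction of features with a planted effect.
#' @param effect_ct Ct shift applied to planted miRNAs in the case group;
#'   half of the planted set gets `effect_ct`, the other half
#'   `-effect_ct` (sign = direction).
#' @param effect_log2fc log2 fold change planted in genes (split the same
#'   way).
#' @param noise_sd_ct,noise_sd_log2 Gaussian noise SDs (Ct cycles / log2
#'   units).
#' @param detect_limit_ct noisy Ct values above this are recorded as
#'   Undetermined (stored as the ceiling, 40).
#' @param baseline_ct_range length-2 numeric, uniform range of per-miRNA
#'   baseline Cts.
#' @param baseline_log2_range uniform range of per-gene baseline log2
#'   intensities.
#' @param flag_absent_quantile fraction of genes (lowest mean intensity)
#'   flagged absent in all samples.
#' @param target_map_density probability that any miRNA targets any gene.
#' @param p_target_true probability that a planted DEmiRNA targets each
#'   oppositely planted DEG (on top of the background density).
#' @param n_intermediates number of regulator nodes in the knowledge
#'   graph.
#' @param seed integer seed; every simulator derives its own sub-stream
#'   from it, so one seed fixes the whole study.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_mirnas = 300L, n_genes = 2000L, n_per_group = 3L,
                       frac_de = 0.1, effect_ct = -2, effect_log2fc = 1,
                       noise_sd_ct = 0.3, noise_sd_log2 = 0.25,
                       detect_limit_ct = 35,
                       baseline_ct_range = c(18, 30),
                       baseline_log2_range = c(6, 14),
                       flag_absent_quantile = 0.1,
                       target_map_density = 0.02,
                       p_target_true = 0.9,
                       n_intermediates = 20L,
                       seed = 1L) {
  cfg <- list(n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
              n_per_group = as.integer(n_per_group), frac_de = frac_de,
              effect_ct = effect_ct, effect_log2fc = effect_log2fc,
              noise_sd_ct = noise_sd_ct, noise_sd_log2 = noise_sd_log2,
              detect_limit_ct = detect_limit_ct,
              baseline_ct_range = as.numeric(baseline_ct_range),
              baseline_log2_range = as.numeric(baseline_log2_range),
              flag_absent_quantile = flag_absent_quantile,
              target_map_density = target_map_density,
              p_target_true = p_target_true,
              n_intermediates = as.integer(n_intermediates),
              seed = as.integer(seed))
  for (f in c("frac_de", "flag_absent_quantile", "target_map_density",
              "p_target_true"))
    if (is.na(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be a fraction in [0, 1]")
  if (cfg$n_per_group < 2L) stop("'n_per_group' must be at least 2")
  if (!all(is.finite(c(cfg$effect_ct, cfg$effect_log2fc, cfg$noise_sd_ct,
                       cfg$noise_sd_log2, cfg$detect_limit_ct))))
    stop("effect and noise values must be finite")
  if (cfg$noise_sd_ct < 0 || cfg$noise_sd_log2 < 0)
    stop("noise SDs must be non-negative")
  for (f in c("baseline_ct_range", "baseline_log2_range"))
    if (length(cfg[[f]]) != 2L || cfg[[f]][1] >= cfg[[f]][2])
      stop("'", f, "' must be c(lo, hi) with lo < hi")
  structure(cfg, class = "sim_config")
}

mirna_ids <- function(cfg) sprintf("mir-%04d", seq_len(cfg$n_mirnas))
gene_ids <- function(cfg) sprintf("gene%05d", seq_len(cfg$n_genes))
regulator_ids <- function(cfg) {
  if (cfg$n_intermediates > 0L)
    sprintf("reg-%03d", seq_len(cfg$n_intermediates))
  else character(0)
}

# Planted ids and signed effects for one feature universe. The first half
# of the sampled set receives `effect`, the rest `-effect`, giving planted
# changes in both directions under a single magnitude.
plant_effects <- function(ids, frac_de, effect) {
  n_de <- round(frac_de * length(ids))
  if (n_de == 0L || effect == 0)
    return(setNames(numeric(0), character(0)))
  planted <- sample(ids, n_de)
  shifts <- rep(c(effect, -effect), length.out = n_de)
  setNames(shifts, planted)
}

new_ground_truth <- function(up, down, effects,
                             true_pairs = data.frame(mirna = character(0),
                                                     gene = character(0))) {
  stopifnot(length(intersect(up, down)) == 0L)
  structure(list(up = sort(up), down = sort(down),
                 planted_effects = effects, true_pairs = true_pairs),
            class = "ground_truth")
}

#' Simulate a qPCR Ct-array experiment with known ground truth
#'
#' Per-miRNA baseline Cts are drawn uniformly from
#' `baseline_ct_range`; case samples of planted miRNAs are shifted by the
#' planted effect; Gaussian replicate noise is added; and any value above
#' `detect_limit_ct` is recorded as Undetermined (the ceiling value 40).
#' Because lower Ct means more template, a negative shift marks an
#' upregulated miRNA.
#'
#' @param config a [sim_config()].
#'
#' @return A list with `ct` (a [ct_matrix()], groups "control"/"case")
#'   and `truth` (class `ground_truth`: sorted id vectors `up` and
#'   `down`, and `planted_effects`, a named vector of Ct shifts).
#' @export
#' @examples
#' sim <- simulate_ct_experiment(sim_config(n_mirnas = 50, seed = 42))
#' sim$ct
#' sim$truth$up
simulate_ct_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  ids <- mirna_ids(config)
  n_s <- 2L * config$n_per_group
  groups <- factor(rep(c("control", "case"), each = config$n_per_group),
                   levels = c("control", "case"))
  baseline <- runif(config$n_mirnas, config$baseline_ct_range[1],
                    config$baseline_ct_range[2])
  effects <- plant_effects(ids, config$frac_de, config$effect_ct)
  mu <- matrix(baseline, config$n_mirnas, n_s)
  case_cols <- which(groups == "case")
  mu[match(names(effects), ids), case_cols] <-
    mu[match(names(effects), ids), case_cols] + effects
  values <- mu + matrix(rnorm(config$n_mirnas * n_s, sd = config$noise_sd_ct),
                        config$n_mirnas, n_s)
  ceiling_ct <- 40
  values[values > config$detect_limit_ct] <- ceiling_ct
  values[values <= 0] <- 0.01   # guard: noise cannot push Ct below zero
  dimnames(values) <- list(ids, sprintf("%s_%d", as.character(groups),
                                        c(seq_len(config$n_per_group),
                                          seq_len(config$n_per_group))))
  truth <- new_ground_truth(up = names(effects)[effects < 0],
                            down = names(effects)[effects > 0],
                            effects = effects)
  list(ct = ct_matrix(values, groups, ceiling = ceiling_ct), truth = truth)
}

#' Simulate a two-group microarray with known ground truth
#'
#' Per-gene baseline log2 intensities are uniform on
#' `baseline_log2_range`; planted genes are shifted by the planted log2
#' fold change in the case group; Gaussian noise of SD `noise_sd_log2` is
#' added. The fraction `flag_absent_quantile` of genes with the lowest
#' mean intensity is flagged absent ("A") in every sample; all other
#' flags are present ("P").
#'
#' @param config a [sim_config()].
#'
#' @return A list with `expr` (an [expression_matrix()]) and `truth`
#'   (class `ground_truth`; `planted_effects` holds log2 fold changes,
#'   positive = upregulated).
#' @export
simulate_microarray <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 202L)
  ids <- gene_ids(config)
  n_s <- 2L * config$n_per_group
  groups <- factor(rep(c("control", "case"), each = config$n_per_group),
                   levels = c("control", "case"))
  baseline <- runif(config$n_genes, config$baseline_log2_range[1],
                    config$baseline_log2_range[2])
  effects <- plant_effects(ids, config$frac_de, config$effect_log2fc)
  mu <- matrix(baseline, config$n_genes, n_s)
  case_cols <- which(groups == "case")
  mu[match(names(effects), ids), case_cols] <-
    mu[match(names(effects), ids), case_cols] + effects
  values <- mu + matrix(rnorm(config$n_genes * n_s, sd = config$noise_sd_log2),
                        config$n_genes, n_s)
  dimnames(values) <- list(ids, sprintf("%s_%d", as.character(groups),
                                        c(seq_len(config$n_per_group),
                                          seq_len(config$n_per_group))))
  n_absent <- round(config$flag_absent_quantile * config$n_genes)
  absent <- rank(rowMeans(values), ties.method = "first") <= n_absent
  flags <- matrix("P", config$n_genes, n_s, dimnames = dimnames(values))
  flags[absent, ] <- "A"
  truth <- new_ground_truth(up = names(effects)[effects > 0],
                            down = names(effects)[effects < 0],
                            effects = effects)
  list(expr = expression_matrix(values, groups, flags), truth = truth)
}

#' Simulate a miRNA target map enriched for inverse regulation
#'
#' Every miRNA targets each gene independently with probability
#' `target_map_density`; on top of that, each planted DEmiRNA targets each
#' oppositely planted DEG (up-miRNA with down-gene and vice versa) with
#' probability `p_target_true`, emulating the repression model that makes
#' inverse miRNA-mRNA intersection informative. The map has no self
#' loops; the planted pairs are recorded as `true_pairs`.
#'
#' @param config a [sim_config()].
#' @param mirna_truth,gene_truth `ground_truth` objects from
#'   [simulate_ct_experiment()] and [simulate_microarray()].
#'
#' @return A list with `target_map` (named list miRNA -> character vector
#'   of targets) and `true_pairs` (data.frame mirna, gene).
#' @export
simulate_target_map <- function(config, mirna_truth, gene_truth) {
  stopifnot(inherits(config, "sim_config"),
            inherits(mirna_truth, "ground_truth"),
            inherits(gene_truth, "ground_truth"))
  set.seed(config$seed + 303L)
  mids <- mirna_ids(config); gids <- gene_ids(config)
  map <- lapply(setNames(mids, mids), function(m)
    gids[runif(config$n_genes) < config$target_map_density])
  pairs_m <- character(0); pairs_g <- character(0)
  add_true <- function(mirnas, genes) {
    for (m in mirnas) {
      hit <- genes[runif(length(genes)) < config$p_target_true]
      if (length(hit) > 0L) {
        map[[m]] <<- sort(unique(c(map[[m]], hit)))
        pairs_m <<- c(pairs_m, rep(m, length(hit)))
        pairs_g <<- c(pairs_g, hit)
      }
    }
  }
  add_true(mirna_truth$up, gene_truth$down)
  add_true(mirna_truth$down, gene_truth$up)
  map <- lapply(map, sort)
  list(target_map = map,
       true_pairs = data.frame(mirna = pairs_m, gene = pairs_g,
                               stringsAsFactors = FALSE))
}

#' Simulate a regulatory knowledge graph with intermediate nodes
#'
#' Builds a directed graph over miRNAs, genes and `n_intermediates`
#' regulator nodes: direct `miRNA -> gene` edges come from the target
#' map; each regulator additionally receives edges from a few miRNAs and
#' sends edges to a few genes, so some miRNA-gene pairs are connected
#' only through one intermediate (found only in "shortest path plus one
#' node" mode). Regulators preferentially bridge planted DEmiRNAs to
#' oppositely planted DEGs, mirroring the expectation that an indirect
#' regulatory layer extends, rather than reverses, the inverse trend.
#'
#' @param config a [sim_config()].
#' @param mirna_truth,gene_truth `ground_truth` objects.
#' @param target_map named list from [simulate_target_map()].
#' @param mirnas_per_regulator,genes_per_regulator fan-in/fan-out of each
#'   regulator node (defaults 2 and 3).
#'
#' @return A [knowledge_graph()] with direction labels attached for the
#'   planted features.
#' @export
simulate_knowledge_graph <- function(config, mirna_truth, gene_truth,
                                     target_map,
                                     mirnas_per_regulator = 2L,
                                     genes_per_regulator = 3L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 404L)
  mids <- mirna_ids(config); gids <- gene_ids(config)
  regs <- regulator_ids(config)
  src <- rep(names(target_map), lengths(target_map))
  tgt <- unlist(target_map, use.names = FALSE)
  lab <- rep("targets", length(src))
  planted_m <- c(mirna_truth$up, mirna_truth$down)
  for (r in regs) {
    pick_m <- if (length(planted_m) > 0L && runif(1) < 0.5)
      sample(planted_m, min(mirnas_per_regulator, length(planted_m)))
    else sample(mids, min(mirnas_per_regulator, length(mids)))
    opp <- unique(c(
      if (any(pick_m %in% mirna_truth$up)) gene_truth$down else character(0),
      if (any(pick_m %in% mirna_truth$down)) gene_truth$up else character(0)))
    pick_g <- if (length(opp) > 0L && runif(1) < 0.7)
      sample(opp, min(genes_per_regulator, length(opp)))
    else sample(gids, min(genes_per_regulator, length(gids)))
    src <- c(src, pick_m, rep(r, length(pick_g)))
    tgt <- c(tgt, rep(r, length(pick_m)), pick_g)
    lab <- c(lab, rep("regulates", length(pick_m) + length(pick_g)))
  }
  edges <- data.frame(source = src, interaction = lab, target = tgt,
                      stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[c("source", "target", "interaction")]), ]
  node_types <- c(setNames(rep("mirna", length(mids)), mids),
                  setNames(rep("gene", length(gids)), gids),
                  setNames(rep("regulator", length(regs)), regs))
  directions <- c(setNames(rep("up", length(mirna_truth$up)), mirna_truth$up),
                  setNames(rep("down", length(mirna_truth$down)), mirna_truth$down),
                  setNames(rep("up", length(gene_truth$up)), gene_truth$up),
                  setNames(rep("down", length(gene_truth$down)), gene_truth$down))
  knowledge_graph(edges, node_types = node_types, directions = directions)
}

#' Simulate the complete two-platform study
#'
#' Convenience wrapper running all four simulators under one seed.
#'
#' @param config a [sim_config()].
#'
#' @return A list with `ct`, `mirna_truth`, `expr`, `gene_truth`,
#'   `target_map`, `true_pairs` and `graph`.
#' @export
simulate_study <- function(config = sim_config()) {
  ctx <- simulate_ct_experiment(config)
  arr <- simulate_microarray(config)
  tm <- simulate_target_map(config, ctx$truth, arr$truth)
  graph <- simulate_knowledge_graph(config, ctx$truth, arr$truth,
                                    tm$target_map)
  list(ct = ctx$ct, mirna_truth = ctx$truth,
       expr = arr$expr, gene_truth = arr$truth,
       target_map = tm$target_map, true_pairs = tm$true_pairs,
       graph = graph)
}
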