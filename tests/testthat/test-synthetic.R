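test_that("identical config and seed reproduce the whole study exactly", {
  cfg <- sim_config(n_mirnas = 60, n_genes = 300, seed = 88)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$ct$values, s2$ct$values)
  expect_identical(s1$expr$values, s2$expr$values)
  expect_identical(s1$target_map, s2$target_map)
  expect_identical(s1$graph$edges, s2$graph$edges)
  s3 <- simulate_study(sim_config(n_mirnas = 60, n_genes = 300, seed = 89))
  expect_false(identical(s1$ct$values, s3$ct$values))
})

test_that("config validation rejects out-of-range values", {
  expect_error(sim_config(frac_de = 1.2), "fraction")
  expect_error(sim_config(n_per_group = 1), "n_per_group")
  expect_error(sim_config(effect_ct = Inf), "finite")
  expect_error(sim_config(baseline_ct_range = c(30, 18)), "lo < hi")
  expect_error(sim_config(noise_sd_ct = -1), "non-negative")
})

test_that("no planted effect and no noise gives identical group means", {
  cfg <- sim_config(n_mirnas = 30, frac_de = 0, noise_sd_ct = 0, seed = 4)
  sim <- simulate_ct_experiment(cfg)
  v <- sim$ct$values
  expect_equal(rowMeans(v[, 1:3]), rowMeans(v[, 4:6]))
  expect_length(sim$truth$up, 0)
  expect_length(sim$truth$down, 0)
})

test_that("a noise-free planted shift propagates exactly into ddCt", {
  cfg <- sim_config(n_mirnas = 30, frac_de = 0.2, effect_ct = -1,
                    noise_sd_ct = 0, seed = 4)
  sim <- simulate_ct_experiment(cfg)
  v <- sim$ct$values
  dd <- rowMeans(v[, 4:6]) - rowMeans(v[, 1:3])
  expect_equal(unname(dd[sim$truth$up]), rep(-1, length(sim$truth$up)))
  expect_equal(unname(dd[sim$truth$down]), rep(1, length(sim$truth$down)))
  # lower Ct = higher expression: negative shift means upregulated, RQ = 2
  expect_equal(unname(2^-dd[sim$truth$up]), rep(2, length(sim$truth$up)))
})

test_that("realized Ct baselines center on the midpoint of the range", {
  cfg <- sim_config(n_mirnas = 300, frac_de = 0, noise_sd_ct = 0,
                    baseline_ct_range = c(18, 30), seed = 12)
  sim <- simulate_ct_experiment(cfg)
  base <- rowMeans(sim$ct$values)
  se <- (30 - 18) / sqrt(12) / sqrt(300)
  expect_lt(abs(mean(base) - 24), 3 * se)
})

test_that("values beyond the detection limit are recorded as the ceiling", {
  cfg <- sim_config(n_mirnas = 200, baseline_ct_range = c(30, 38),
                    detect_limit_ct = 35, noise_sd_ct = 1, frac_de = 0,
                    seed = 6)
  sim <- simulate_ct_experiment(cfg)
  v <- sim$ct$values
  expect_true(any(v == 40))
  expect_false(any(v > 35 & v < 40))
})

test_that("microarray flags mark exactly the configured fraction absent", {
  cfg <- sim_config(n_genes = 1000, flag_absent_quantile = 0.1, seed = 14)
  sim <- simulate_microarray(cfg)
  absent_rows <- rowSums(sim$expr$flags == "A") == 6
  expect_equal(sum(absent_rows), 100)
  mixed <- rowSums(sim$expr$flags == "A") %in% 1:5
  expect_false(any(mixed))  # absence is all-or-nothing by construction
})

test_that("noise-free planted genes show the exact fold change", {
  cfg <- sim_config(n_genes = 100, frac_de = 0.1, effect_log2fc = 1,
                    noise_sd_log2 = 0, seed = 15)
  sim <- simulate_microarray(cfg)
  v <- sim$expr$values
  fc <- rowMeans(v[, 4:6]) - rowMeans(v[, 1:3])
  expect_equal(unname(fc[sim$truth$up]), rep(1, length(sim$truth$up)))
  expect_equal(unname(fc[sim$truth$down]), rep(-1, length(sim$truth$down)))
})

test_that("null microarray data yields calibrated raw p-values downstream", {
  cfg <- sim_config(n_genes = 600, frac_de = 0, seed = 16)
  sim <- simulate_microarray(cfg)
  fit <- fit_moderated_t(sim$expr, normalize = FALSE)
  frac <- mean(fit$table$raw_p < 0.05)
  se <- sqrt(0.05 * 0.95 / 600)
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("target map density follows the binomial expectation", {
  cfg <- sim_config(n_mirnas = 50, n_genes = 1000, frac_de = 0,
                    target_map_density = 0.05, seed = 17)
  sim <- simulate_ct_experiment(cfg)
  arr <- simulate_microarray(cfg)
  tm <- simulate_target_map(cfg, sim$truth, arr$truth)
  edges <- sum(lengths(tm$target_map))
  mu <- 50 * 1000 * 0.05
  sd3 <- 3 * sqrt(50 * 1000 * 0.05 * 0.95)
  expect_lt(abs(edges - mu), sd3)
  # density 0 and no planted pairs: empty map
  cfg0 <- sim_config(n_mirnas = 10, n_genes = 50, frac_de = 0,
                     target_map_density = 0, p_target_true = 0, seed = 18)
  s0 <- simulate_ct_experiment(cfg0)
  a0 <- simulate_microarray(cfg0)
  tm0 <- simulate_target_map(cfg0, s0$truth, a0$truth)
  expect_equal(sum(lengths(tm0$target_map)), 0)
})

test_that("without intermediates every reachable path has length one", {
  cfg <- sim_config(n_mirnas = 20, n_genes = 100, n_intermediates = 0,
                    target_map_density = 0.05, seed = 19)
  sim <- simulate_study(cfg)
  expect_false(any(sim$graph$node_types == "regulator"))
  dm <- setNames(rep("up", 20), sprintf("mir-%04d", 1:20))
  dg <- setNames(rep("down", 100), sprintf("gene%05d", 1:100))
  plus <- suppressWarnings(
    find_relations(sim$graph, dm, dg, "shortest_plus_one"))
  expect_true(all(plus$path_length == 1L))
})

test_that("intermediate-only pairs appear solely in plus-one mode", {
  cfg <- sim_config(n_mirnas = 30, n_genes = 150, n_intermediates = 10,
                    target_map_density = 0.02, seed = 20)
  sim <- simulate_study(cfg)
  dm_ids <- intersect(sprintf("mir-%04d", 1:30), sim$graph$nodes)
  dg_ids <- intersect(sprintf("gene%05d", 1:150), sim$graph$nodes)
  dm <- setNames(rep("up", length(dm_ids)), dm_ids)
  dg <- setNames(rep("down", length(dg_ids)), dg_ids)
  short <- find_relations(sim$graph, dm, dg, "shortest")
  plus <- find_relations(sim$graph, dm, dg, "shortest_plus_one")
  expect_true(all(short$path_length == 1L))
  expect_gt(nrow(plus), nrow(short))
  key <- function(d) paste(d$mirna, d$gene)
  expect_true(all(key(short) %in% key(plus)))
})

test_that("ground truth direction sets are disjoint and reference real ids", {
  cfg <- sim_config(n_mirnas = 40, frac_de = 0.25, seed = 21)
  sim <- simulate_ct_experiment(cfg)
  expect_length(intersect(sim$truth$up, sim$truth$down), 0)
  expect_true(all(c(sim$truth$up, sim$truth$down) %in%
                    rownames(sim$ct$values)))
  expect_equal(sort(names(sim$truth$planted_effects)),
               sort(c(sim$truth$up, sim$truth$down)))
})
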