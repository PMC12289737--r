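edge_df <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(source = m[, 1], interaction = "regulates", target = m[, 2],
             stringsAsFactors = FALSE)
}

test_that("direct edges are found in both modes; intermediates only in plus-one", {
  g <- knowledge_graph(edge_df("m1", "g1",
                               "m2", "R", "R", "g2"))
  dm <- c(m1 = "up", m2 = "down")
  dg <- c(g1 = "down", g2 = "up")
  short <- find_relations(g, dm, dg, mode = "shortest")
  expect_equal(nrow(short), 1)
  expect_equal(short$mirna, "m1")
  expect_equal(short$path_length, 1L)
  plus <- find_relations(g, dm, dg, mode = "shortest_plus_one")
  expect_equal(nrow(plus), 2)
  r2 <- plus[plus$mirna == "m2", ]
  expect_equal(r2$path_length, 2L)
  expect_equal(r2$intermediate, "R")
  expect_equal(r2$gene_direction, "up")
})

test_that("the lexicographically smallest intermediate is reported", {
  g <- knowledge_graph(edge_df("m1", "Rb", "Rb", "g1",
                               "m1", "Ra", "Ra", "g1",
                               "m1", "Rc", "Rc", "g1"))
  rel <- find_relations(g, c(m1 = "up"), c(g1 = "down"),
                        mode = "shortest_plus_one")
  expect_equal(nrow(rel), 1)   # unique per (miRNA, gene) pair
  expect_equal(rel$intermediate, "Ra")
})

test_that("relations equal the exhaustive path-enumeration oracle on random graphs", {
  set.seed(31)
  for (rep in 1:5) {
    nm <- 8; ng <- 15; nr <- 6
    mids <- paste0("m", 1:nm); gids <- paste0("g", 1:ng)
    rids <- paste0("R", 1:nr)
    nodes <- c(mids, gids, rids)
    src <- sample(c(mids, rids), 80, replace = TRUE)
    tgt <- sample(c(gids, rids), 80, replace = TRUE)
    keep <- src != tgt
    edges <- unique(data.frame(source = src[keep], interaction = "x",
                               target = tgt[keep], stringsAsFactors = FALSE))
    g <- suppressWarnings(knowledge_graph(edges))
    dm <- setNames(rep(c("up", "down"), length.out = nm), mids)
    dg <- setNames(rep(c("down", "up"), length.out = ng), gids)
    for (mode in c("shortest", "shortest_plus_one")) {
      got <- suppressWarnings(find_relations(g, dm, dg, mode = mode))
      want <- path_enum_oracle(edges,
                               sort(intersect(mids, g$nodes)),
                               sort(intersect(gids, g$nodes)),
                               if (mode == "shortest") 1L else 2L)
      expect_equal(got[c("mirna", "gene", "path_length")],
                   want, ignore_attr = TRUE)
    }
  }
})

test_that("relation output does not depend on node or query order", {
  set.seed(32)
  edges <- edge_df("m2", "g2", "m1", "g1", "m2", "R", "R", "g1")
  g1 <- knowledge_graph(edges)
  g2 <- knowledge_graph(edges[sample(nrow(edges)), ])
  dm <- c(m1 = "up", m2 = "down"); dg <- c(g1 = "down", g2 = "up")
  r1 <- find_relations(g1, dm, dg, "shortest_plus_one")
  r2 <- find_relations(g2, rev(dm), rev(dg), "shortest_plus_one")
  expect_identical(r1, r2)
})

test_that("query ids absent from the graph are skipped with a warning", {
  g <- knowledge_graph(edge_df("m1", "g1"))
  expect_warning(rel <- find_relations(g, c(m1 = "up", mZ = "down"),
                                       c(g1 = "down"), "shortest"),
                 "absent")
  expect_equal(nrow(rel), 1)
})

test_that("direction table reports counts and percentages over unique relations", {
  rel <- data.frame(
    mirna = paste0("m", 1:92),
    mirna_direction = rep(c("up", "down", "up", "down"), c(53, 37, 1, 1)),
    gene = paste0("g", 1:92),
    gene_direction = rep(c("down", "up", "up", "down"), c(53, 37, 1, 1)),
    path_length = 1L, intermediate = NA_character_,
    stringsAsFactors = FALSE)
  tab <- direction_table(rel)
  expect_equal(tab$total, 92)
  expect_equal(tab$observed["up", "down"], 53)
  expect_equal(tab$percent["up", "down"], 100 * 53 / 92, tolerance = 1e-12)
  expect_equal(round(tab$percent["up", "down"], 2), 57.61)
  expect_equal(sum(tab$observed), nrow(rel))
  expect_equal(sum(tab$percent), 100)
  # swapping the miRNA direction labels swaps the rows
  rel2 <- rel
  rel2$mirna_direction <- ifelse(rel$mirna_direction == "up", "down", "up")
  tab2 <- direction_table(rel2)
  expect_equal(unname(tab2$observed), unname(tab$observed[2:1, ]))
  expect_error(direction_table(rel[0, ]), "empty")
})

test_that("chi-square matches closed form, stats::chisq.test and Yates ordering", {
  # perfect independence
  flat <- chi_square_2x2(matrix(10, 2, 2), correct = FALSE)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  # strongly inverse table, continuity correction on
  O <- matrix(c(1, 37, 53, 1), 2, 2)
  yates <- suppressWarnings(chi_square_2x2(O, correct = TRUE))
  expect_equal(yates$statistic, 80.0416, tolerance = 1e-4)
  ref <- suppressWarnings(chisq.test(O, correct = TRUE))
  expect_equal(yates$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(yates$p, ref$p.value, tolerance = 1e-10)
  expect_equal(unname(yates$expected), unname(ref$expected))

  set.seed(33)
  for (rep in 1:200) {
    O <- matrix(rpois(4, 20) + 1, 2, 2)
    res <- suppressWarnings(chi_square_2x2(O, correct = FALSE))
    expect_equal(res$statistic, chisq_closed_form(O), tolerance = 1e-10)
    resy <- suppressWarnings(chi_square_2x2(O, correct = TRUE))
    expect_lte(resy$statistic, res$statistic + 1e-12)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2, 2)), "margin")
  # margins (2, 18) x (10, 10) over 20 give E11 = 1 < 5
  expect_warning(chi_square_2x2(matrix(c(1, 9, 1, 9), 2, 2)), "below 5")
})

test_that("inverse overlap tests match the enumeration oracle and truth", {
  # engineered counts: N = 100, K = 10 (targets in bg), n = 20, k = 5
  bg <- paste0("g", 1:100)
  targets <- bg[1:10]
  degs_down <- c(bg[6:10], bg[21:35])           # n = 20, overlap k = 5
  map <- list(mU = targets)
  ov <- inverse_overlap(degs_up = character(0), degs_down = degs_down,
                        demirnas_up = "mU", demirnas_down = character(0),
                        target_map = map, background = bg)
  res <- ov$up_mirna_down_deg$result
  # query = target union (n = 10), set = down-DEGs (K = 20); the
  # hypergeometric tail is symmetric in the two roles
  expect_equal(c(res$k, res$K, res$n, res$N), c(5, 20, 10, 100))
  expect_equal(res$p, hyper_enum_oracle(5, 10, 20, 100), tolerance = 1e-12)
  expect_equal(ov$up_mirna_down_deg$genes, sort(bg[6:10]))
  # disjoint targets and DEGs: k = 0, p = 1
  ov2 <- inverse_overlap(character(0), bg[50:60], "mU", character(0),
                         list(mU = bg[1:5]), bg)
  expect_equal(ov2$up_mirna_down_deg$result$k, 0)
  expect_equal(ov2$up_mirna_down_deg$result$p, 1)
  expect_error(inverse_overlap(bg[1:3], bg[3:5], "a", "b", map, bg),
               "disjoint")
})

test_that("planted inverse targeting is fully recovered when p_target_true = 1", {
  cfg <- sim_config(n_mirnas = 40, n_genes = 200, p_target_true = 1,
                    target_map_density = 0.01, seed = 61)
  sim <- simulate_study(cfg)
  tm <- sim$target_map
  for (m in sim$mirna_truth$up)
    expect_true(all(sim$gene_truth$down %in% tm[[m]]))
  ov <- inverse_overlap(sim$gene_truth$up, sim$gene_truth$down,
                        sim$mirna_truth$up, sim$mirna_truth$down,
                        tm, paste0("gene", sprintf("%05d", 1:200)))
  expect_true(all(sim$gene_truth$down %in% ov$up_mirna_down_deg$genes))
})
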