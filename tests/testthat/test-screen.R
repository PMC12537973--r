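test_that("gene stats reproduce medians and the Welch t closed form", {
  st <- compute_gene_stats(tiny_dep(), tiny_grouping())
  sel <- st[st$gene == "SEL", ]
  expect_equal(sel$median_target, -0.9)
  expect_equal(sel$median_background, 0.0)
  expect_equal(sel$median_diff, -0.9)
  # frozen Welch oracle for target (-0.9,-0.8,-1.0) vs background (0,0.1,-0.1)
  expect_equal(sel$t_stat, -11.0227038425, tolerance = 1e-9)
  expect_equal(sel$p_value, 3.85067711367e-04, tolerance = 1e-9)
  expect_equal(sel$neg_log10_p, -log10(sel$p_value))
  expect_equal(sel$n_target_used, 3L)
  expect_equal(sel$n_background_used, 3L)
  # cross-check against stats::t.test on the same data
  tt <- t.test(c(-0.9, -0.8, -1.0), c(0, 0.1, -0.1))
  expect_equal(sel$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(sel$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("constant identical groups follow the degenerate contract", {
  st <- compute_gene_stats(tiny_dep(), tiny_grouping())
  flat <- st[st$gene == "FLAT", ]
  expect_equal(flat$median_diff, 0)
  expect_equal(flat$t_stat, 0)
  expect_equal(flat$p_value, 1)
})

test_that("pooled t form is available and matches t.test(var.equal=TRUE)", {
  st <- compute_gene_stats(tiny_dep(), tiny_grouping(), var_equal = TRUE)
  tt <- t.test(c(-0.9, -0.8, -1.0), c(0, 0.1, -0.1), var.equal = TRUE)
  expect_equal(st$t_stat[st$gene == "SEL"], unname(tt$statistic),
               tolerance = 1e-12)
  expect_equal(st$p_value[st$gene == "SEL"], tt$p.value, tolerance = 1e-12)
})

test_that("missing scores are dropped per gene; small groups get NA stats", {
  scores <- rbind(GA = c(-1, NA, -0.8, 0, 0.1, NA),
                  GB = c(-1, NA, NA, 0, 0.1, 0.2))
  colnames(scores) <- c("T1", "T2", "T3", "B1", "B2", "B3")
  st <- compute_gene_stats(dependency_matrix(scores), tiny_grouping(),
                           min_group_size = 2)
  expect_equal(st$n_target_used, c(2L, 1L))
  expect_equal(st$median_target[1], -0.9)
  expect_true(is.na(st$p_value[2]))
  # NA-stat genes are never selected
  expect_false("GB" %in%
    select_top_candidates(st, selection_config(top_k = 10,
                                               min_group_size = 2)))
})

test_that("empty groups error", {
  dep <- tiny_dep()
  g <- cell_grouping(c("X1", "X2"), c("AML", "OTHER"), "AML")
  expect_error(compute_gene_stats(dep, g), "target cell line")
})

test_that("top-K selection applies the sign filter, ranking and tie-breaks", {
  stats <- data.frame(
    gene = c("g1", "g2", "g3", "g4"),
    median_diff = c(-0.5, 0.2, -0.1, -0.3),
    p_value = c(0.001, 0.0001, 0.01, 0.01))
  expect_equal(select_top_candidates(stats, selection_config(top_k = 2)),
               c("g1", "g4"))
  expect_equal(select_top_candidates(stats, selection_config(top_k = 10)),
               c("g1", "g4", "g3"))
  all_pos <- transform(stats, median_diff = abs(median_diff))
  expect_length(select_top_candidates(all_pos, selection_config(top_k = 2)), 0)
  # equal p and equal diff falls back to the gene symbol
  tie <- data.frame(gene = c("zz", "aa"), median_diff = c(-0.2, -0.2),
                    p_value = c(0.01, 0.01))
  expect_equal(select_top_candidates(tie, selection_config(top_k = 2)),
               c("aa", "zz"))
})

test_that("top-K output for smaller K is a prefix of larger K", {
  sim <- gen_dependency_matrix(screen_sim_config(seed = 9, n_genes = 100))
  st <- compute_gene_stats(sim$dep, sim$grouping)
  for (k in c(1, 5, 20)) {
    small <- select_top_candidates(st, selection_config(top_k = k))
    big <- select_top_candidates(st, selection_config(top_k = 50))
    expect_equal(small, big[seq_along(small)])
  }
})

test_that("essentiality filter applies both strict thresholds and ranks by p", {
  stats <- data.frame(
    gene = c("keep", "at_thr", "bg_essential", "best"),
    median_target = c(-0.85, -0.5, -0.9, -0.95),
    median_background = c(-0.2, -0.2, -0.6, -0.1),
    median_diff = c(-0.65, -0.3, -0.3, -0.85),
    p_value = c(0.01, 0.001, 0.001, 0.002))
  ct <- essentiality_filter(stats$gene, stats, selection_config())
  expect_equal(ct$gene, c("best", "keep"))
  expect_equal(ct$rank, 1:2)
  expect_error(essentiality_filter("ghost", stats, selection_config()),
               "ghost")
})

test_that("orientation flip reverses median_diff; location shift leaves it unchanged", {
  sim <- gen_dependency_matrix(screen_sim_config(seed = 4, n_genes = 50))
  st <- compute_gene_stats(sim$dep, sim$grouping)

  flipped <- dependency_matrix(-sim$dep$scores)
  st_f <- compute_gene_stats(flipped, sim$grouping)
  expect_equal(st_f$median_diff, -st$median_diff)

  shifted <- dependency_matrix(sim$dep$scores + 0.37)
  st_s <- compute_gene_stats(shifted, sim$grouping)
  expect_equal(st_s$median_diff, st$median_diff, tolerance = 1e-12)
  expect_equal(st_s$t_stat, st$t_stat, tolerance = 1e-9)
})

test_that("run_screen records per-stage counts and survives empty gene sets", {
  sim <- gen_dependency_matrix(screen_sim_config(seed = 2, n_genes = 200,
                                                 n_planted_selective = 5))
  sets <- gen_gene_sets(sim$truth, n_sets = 10, seed = 2)
  rep <- run_screen(sim$dep, sim$grouping, sets,
                    cfg = selection_config(top_k = 50))
  expect_s3_class(rep, "screen_report")
  sc <- setNames(rep$stage_counts$n, rep$stage_counts$stage)
  expect_equal(sc[["tested"]], 200)
  expect_equal(sc[["top_candidates"]], 50)
  expect_lte(sc[["in_enriched_sets"]], sc[["top_candidates"]])
  expect_equal(sc[["final"]], nrow(rep$candidates))
  expect_equal(rep$candidates$rank, seq_len(nrow(rep$candidates)))

  # degenerate input contract: no sets -> filter applies to the top-K list
  rep0 <- run_screen(sim$dep, sim$grouping, NULL,
                     cfg = selection_config(top_k = 50))
  expect_null(rep0$enrichment)
  expect_equal(rep0$pathway_genes, rep0$top_candidates)
  expect_true(nrow(rep0$candidates) >= 5)
})

test_that("screen recovers planted selective genes at study conditions", {
  sim <- gen_dependency_matrix(screen_sim_config(seed = 1))
  sets <- gen_gene_sets(sim$truth, seed = 1)
  rep <- run_screen(sim$dep, sim$grouping, sets,
                    cfg = selection_config(top_k = 50))
  planted <- sim$truth$gene[sim$truth$class == "planted_selective"]
  expect_gte(sum(planted %in% rep$candidates$gene), 9)
  # planted genes dominate the top of the ranking
  expect_true(all(rep$candidates$gene[1:5] %in% planted))
})

test_that("screen report writes its five tables", {
  sim <- gen_dependency_matrix(screen_sim_config(seed = 6, n_genes = 60))
  rep <- run_screen(sim$dep, sim$grouping,
                    gen_gene_sets(sim$truth, n_sets = 5, seed = 6),
                    cfg = selection_config(top_k = 20))
  dir <- tempfile()
  write_screen_report(rep, dir)
  expect_setequal(list.files(dir),
                  c("gene_stats.tsv", "top_candidates.tsv", "enrichment.tsv",
                    "final_candidates.tsv", "stage_counts.tsv"))
  expect_equal(nrow(read_table(file.path(dir, "gene_stats.tsv"))), 60)
})
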