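test_that("generators are pure functions of parameters and seed", {
  tr <- synthetic_truth(n_genes = 80, n_modules = 2, module_size = 6, seed = 13)
  tr2 <- synthetic_truth(n_genes = 80, n_modules = 2, module_size = 6, seed = 13)
  expect_identical(tr$true_effects, tr2$true_effects)
  e1 <- igraph::as_edgelist(simulate_network(tr))
  e2 <- igraph::as_edgelist(simulate_network(tr2))
  expect_identical(e1, e2)
  s1 <- simulate_screen(tr)
  s2 <- simulate_screen(tr2)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$baselines, s2$baselines)
  mt1 <- simulate_mouse_tables(tr, data.frame(gene_id = tr$genes[1:20],
    hit_class = "suppressor"), 10, 2, 2, 2, 2)
  mt2 <- simulate_mouse_tables(tr, data.frame(gene_id = tr$genes[1:20],
    hit_class = "suppressor"), 10, 2, 2, 2, 2)
  expect_identical(mt1, mt2)
  expect_error(synthetic_truth(n_genes = 10, n_modules = 3, module_size = 5),
    "planted")
})

test_that("planted-partition network matches its edge model", {
  # p_in = 1, p_out = 0: modules are cliques, the rest is edgeless
  tr <- synthetic_truth(n_genes = 40, n_modules = 2, module_size = 5,
    p_in = 1, p_out = 0, seed = 3)
  net <- simulate_network(tr)
  expect_equal(igraph::ecount(net), 2 * choose(5, 2))
  deg <- igraph::degree(net)
  planted <- unlist(lapply(tr$planted_modules, `[[`, "genes"))
  expect_true(all(deg[planted] == 4))
  expect_true(all(deg[setdiff(tr$genes, planted)] == 0))
  # module edges carry the strong weights
  expect_true(all(igraph::E(net)$weight > 0.5))

  # background degree close to its binomial expectation
  tr2 <- synthetic_truth(seed = 5) # 500 genes, defaults
  net2 <- simulate_network(tr2)
  bg <- setdiff(tr2$genes, unlist(lapply(tr2$planted_modules, `[[`, "genes")))
  mean_deg <- mean(igraph::degree(net2)[bg])
  expected <- tr2$p_out * (tr2$n_genes - 1)
  se <- sqrt(tr2$p_out * (1 - tr2$p_out) * (tr2$n_genes - 1) / length(bg))
  expect_lt(abs(mean_deg - expected), 3 * se + 0.05)
  # every planted module is internally connected
  for (pm in tr2$planted_modules) {
    sub <- igraph::induced_subgraph(net2, pm$genes)
    expect_equal(igraph::components(sub)$no, 1)
  }
})

test_that("screen generator reproduces the configured effects", {
  tr <- synthetic_truth(n_genes = 60, n_modules = 2, module_size = 6, seed = 17)
  scr <- simulate_screen(tr)
  expect_equal(nrow(scr$records), 60)
  n_anim <- lengths(strsplit(scr$records$responses, ";"))
  expect_true(all(n_anim >= 70 & n_anim <= 90))
  # baseline close to the configured 20.6 +/- 3
  cum <- scr$baselines[scr$baselines$batch == "cumulated", ]
  expect_lt(abs(cum$mean_percent - tr$baseline_mean), 1.5)
  expect_lt(abs(cum$sd_percent - tr$baseline_sd), 2)
  # parameter recovery: per-gene mean percent tracks the true effect
  ss <- score_screen(scr$records, cumulated_baseline())
  err <- ss$percent_response - tr$true_effects[ss$gene_id]
  binom_se <- 100 * sqrt(0.25 / tr$touches / 70)
  expect_lt(max(abs(err)), 4 * binom_se)

  # p_gene = 0 gives all-zero responses and S = -1 downstream
  tr0 <- synthetic_truth(n_genes = 5, n_modules = 0, seed = 2)
  tr0$true_effects[] <- 0.0 # responsiveness 0% (clamped domain edge)
  tr0$true_effects <- pmax(tr0$true_effects, 0)
  scr0 <- simulate_screen(tr0)
  ss0 <- score_screen(scr0$records, cumulated_baseline())
  expect_true(all(ss0$s == -1))

  # strong planted suppressors (p = 0.8) are called at 70-90 animals
  tr8 <- synthetic_truth(n_genes = 30, n_modules = 0, seed = 19)
  tr8$true_effects[] <- 80
  scr8 <- simulate_screen(tr8)
  ss8 <- score_screen(scr8$records, cumulated_baseline())
  expect_true(all(ss8$hit_class == "suppressor"))
})

test_that("toxicity flags and overdispersion are exercised on request", {
  tr <- synthetic_truth(n_genes = 200, n_modules = 0, seed = 23)
  scr <- simulate_screen(tr, toxic_fraction = 0.3)
  ss <- score_screen(scr$records, scr$baselines)
  expect_gt(sum(ss$excluded), 20)
  expect_true(all(ss$exclude_reason[ss$excluded] %in% TOXICITY_FLAGS))
  # beta-binomial animals inflate the per-clone SD
  scr_od <- simulate_screen(tr, overdispersion = 0.3)
  ss_od <- score_screen(scr_od$records, scr$baselines)
  expect_gt(mean(ss_od$sd_percent), mean(ss$sd_percent[!ss$excluded]))
})

test_that("annotation generator plants recoverable positive controls", {
  tr <- synthetic_truth(n_genes = 100, n_modules = 2, module_size = 8, seed = 29)
  coll <- simulate_annotations(tr, n_random_terms = 0)
  expect_s3_class(coll, "gene_set_collection")
  expect_equal(length(coll$sets), 2)
  res <- enrich(tr$planted_modules[[1]]$genes, coll)
  expect_equal(res$term[1], "planted_module_1")
  coll2 <- simulate_annotations(tr, n_random_terms = 5, genes_per_term = 10)
  expect_equal(length(coll2$sets), 7)
})

test_that("mouse-table generator reproduces a requested overlap structure", {
  # structure mirroring the screen-to-mouse comparison: 662 modifiers,
  # 239 conserved, 49 dysregulated of which 6 oppositely
  tr <- synthetic_truth(n_genes = 700, n_modules = 0, seed = 31)
  mods <- data.frame(
    gene_id = tr$genes[1:662],
    hit_class = rep(c("suppressor", "enhancer"), c(399, 263)),
    stringsAsFactors = FALSE
  )
  mt <- simulate_mouse_tables(tr, mods,
    n_conserved = 239,
    in_a_only = 20, in_b_only = 10, both_concordant = 43, both_opposite = 6
  )
  expect_equal(nrow(mt$orthologs), 239)
  cons <- suppressMessages(conserved_modifiers(mods, mt$orthologs))
  expect_equal(length(unique(cons$mouse_gene)), 239)
  ov <- intersect_dysregulation(cons, mt$table_a, mt$table_b)
  expect_equal(unname(ov$counts["in_both_opposite"]), 6)
  expect_equal(
    unname(ov$counts["in_both_concordant"] + ov$counts["in_both_opposite"]),
    49
  )
  expect_equal(unname(ov$counts["total"]), 79)
  expect_error(
    simulate_mouse_tables(tr, mods, 10, 5, 5, 5, 5),
    "exceeds"
  )
})
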