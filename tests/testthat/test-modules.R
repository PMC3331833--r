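make_series <- function(values_by_level, genes) {
  # hand-built attenuation series: values_by_level is a list of numeric
  # vectors (one per level, level 0 first)
  m <- do.call(cbind, values_by_level)
  dimnames(m) <- list(genes, paste0("level_", seq_along(values_by_level) - 1))
  structure(m,
    step = 0.025, n_steps = length(values_by_level) - 1,
    class = c("attenuation_series", "matrix", "array")
  )
}

test_that("thresholding is strict and sign-specific", {
  genes <- c("g1", "g2", "g3")
  ser <- make_series(list(c(2, -2, 0)), genes)
  expect_equal(threshold_genes(ser, 0, 0, 1, "positive"), "g1")
  expect_equal(threshold_genes(ser, 0, 0, 1, "negative"), "g2")
  # all values equal to mu with sigma = 0 -> empty (strict inequality)
  ser0 <- make_series(list(rep(0.5, 3)), genes)
  expect_equal(length(threshold_genes(ser0, 0, 0.5, 0, "positive")), 0)
  expect_error(threshold_genes(ser, 5, 0, 1, "positive"), "level")
})

test_that("connected modules are induced components of size >= 2", {
  expect_equal(connected_modules(character(0), k3_network()), list())
  # path a-b-c with only {a, c} above threshold: no module
  g <- path_network(c("a", "b", "c"))
  expect_equal(connected_modules(c("a", "c"), g), list())
  # two cliques above threshold -> exactly two modules
  g2 <- gene_network(rbind(
    clique_edges(c("a1", "a2", "a3")),
    clique_edges(c("b1", "b2", "b3"))
  ))
  mods <- connected_modules(c("a1", "a2", "a3", "b1", "b2", "b3"), g2)
  expect_equal(length(mods), 2)
  expect_equal(mods[[1]], c("a1", "a2", "a3"))
  expect_equal(mods[[2]], c("b1", "b2", "b3"))
})

test_that("stability tracking enforces birth level, retention fraction and run", {
  genes <- sprintf("g%02d", 1:10)
  full <- list(genes)
  thr_all <- stats::setNames(rep(list(genes), 8), as.character(0:7))
  mods_all <- stats::setNames(rep(list(full), 8), as.character(0:7))
  # identical module at every level -> retained with a long run
  kept <- track_stability(mods_all, thr_all, "positive")
  expect_gt(length(kept), 0)
  expect_true(all(vapply(kept, `[[`, integer(1), "stability_run") >= 2))
  expect_equal(kept[[1]]$birth_level, 4L)

  # module present only before the start level -> rejected
  thr_early <- stats::setNames(
    c(list(genes, genes, genes, genes), rep(list(character(0)), 4)),
    as.character(0:7)
  )
  mods_early <- stats::setNames(
    c(list(full, full, full, full), rep(list(list()), 4)),
    as.character(0:7)
  )
  expect_equal(length(track_stability(mods_early, thr_early, "positive")), 0)

  # exactly 40% of genes retained at the next two levels -> kept (inclusive)
  thr_40 <- stats::setNames(c(
    rep(list(genes), 5), # levels 0..4
    list(genes[1:4], genes[1:4], character(0)) # levels 5..7
  ), as.character(0:7))
  mods_40 <- lapply(thr_40, function(g) if (length(g) >= 2) list(g) else list())
  kept_40 <- track_stability(mods_40, thr_40, "positive")
  runs <- vapply(kept_40, `[[`, integer(1), "stability_run")
  births <- vapply(kept_40, `[[`, integer(1), "birth_level")
  expect_true(any(births == 4 & runs >= 2))
  # and 3 of 10 (30%) fails the 40% criterion
  thr_30 <- stats::setNames(c(
    rep(list(genes), 5),
    list(genes[1:3], genes[1:3], character(0))
  ), as.character(0:7))
  mods_30 <- lapply(thr_30, function(g) if (length(g) >= 2) list(g) else list())
  kept_30 <- track_stability(mods_30, thr_30, "positive")
  expect_false(any(
    vapply(kept_30, `[[`, integer(1), "birth_level") == 4 &
      vapply(kept_30, function(m) length(m$genes), integer(1)) == 10
  ))
})

test_that("redundancy filtering keeps the preferred module of a similar pair", {
  m_a <- new_module(sprintf("g%02d", 1:10), "positive", 5L, 3L)
  m_b <- new_module(sprintf("g%02d", 1:10), "positive", 5L, 3L)
  expect_equal(length(deduplicate_modules(list(m_a, m_b))), 1)
  m_c <- new_module(sprintf("h%02d", 1:5), "positive", 4L, 2L)
  expect_equal(length(deduplicate_modules(list(m_a, m_c))), 2)
  # nested pair with Jaccard 10/12 ~ 0.83: superset wins on the size tie-break
  sup <- new_module(sprintf("g%02d", 1:12), "positive", 5L, 3L)
  sub <- new_module(sprintf("g%02d", 1:10), "positive", 5L, 3L)
  kept <- deduplicate_modules(list(sub, sup))
  expect_equal(length(kept), 1)
  expect_equal(length(kept[[1]]$genes), 12)
  # longer stability run beats size
  sub_stable <- new_module(sprintf("g%02d", 1:10), "positive", 5L, 6L)
  kept2 <- deduplicate_modules(list(sub_stable, sup))
  expect_equal(length(kept2[[1]]$genes), 10)
})

test_that("module annotation delegates to hypergeometric enrichment", {
  universe <- sprintf("u%03d", 1:200)
  coll <- gene_set_collection(
    list(target = universe[1:10], decoy = universe[51:60]),
    universe,
    name = "paths"
  )
  mod <- new_module(universe[c(1:4, 101, 102)], "positive", 4L, 2L)
  ann <- annotate_modules(list(mod), coll)[[1]]$annotations
  expect_equal(ann$term[1], "target")
  expect_equal(ann$p[1], hyper_exact(4, 6, 10, 200), tolerance = 1e-9)
  # module equal to a whole set -> that term has the smallest p
  mod2 <- new_module(universe[1:10], "positive", 4L, 2L)
  ann2 <- annotate_modules(list(mod2), coll)[[1]]$annotations
  expect_equal(ann2$term[which.min(ann2$p)], "target")
  # disjoint module -> empty annotation table
  mod3 <- new_module(universe[100:105], "negative", 4L, 2L)
  expect_equal(nrow(annotate_modules(list(mod3), coll)[[1]]$annotations), 0)
})

test_that("module graph export min-max normalises confidence weights", {
  g <- gene_network(data.frame(
    gene_a = c("a", "b", "c"), gene_b = c("b", "c", "d"),
    weight = c(2, 4, 6)
  ))
  out <- export_module_graph(c("a", "b", "c", "d"), g)
  expect_equal(out$normalized_weight, c(0, 0.5, 1))
  # uniform weights -> all 1.0 by convention
  gu <- gene_network(clique_edges(c("x", "y", "z"), weight = 3))
  expect_true(all(export_module_graph(c("x", "y", "z"), gu)$normalized_weight == 1))
  g1 <- k2_network(w = 7)
  expect_equal(export_module_graph(c("a", "b"), g1)$normalized_weight, 1)
})

test_that("module detection is deterministic and sign-pure", {
  withr::with_seed(21, {
    tr <- synthetic_truth(n_genes = 120, n_modules = 2, module_size = 8, seed = 21)
    net <- simulate_network(tr)
    scr <- simulate_screen(tr)
    ss <- score_screen(scr$records, scr$baselines)
    sig <- stats::setNames(ss$s[!ss$excluded], ss$gene_id[!ss$excluded])
    rn <- suppressMessages(restrict_to_scored(net, sig))
    b <- spectral_basis(rn, normalized = TRUE)
    ser <- attenuation_series(sig, b)
    mods1 <- detect_modules(ser, rn)
    mods2 <- detect_modules(ser, rn)
    expect_identical(modules_table(mods1), modules_table(mods2))
    # every retained module satisfies the configured filters
    for (m in mods1) {
      expect_gte(m$birth_level, 4)
      expect_gte(m$stability_run, 2)
      expect_gte(length(m$genes), 2)
    }
    # no module mixes signs: positive modules sit above mu+sd on the raw
    # signal more often than below
    mu0 <- mean(ser[, 1])
    sd0 <- stats::sd(ser[, 1])
    for (m in mods1) {
      col <- ser[m$genes, m$birth_level + 1]
      if (m$sign == "positive") expect_true(all(col > mu0 + sd0))
      if (m$sign == "negative") expect_true(all(col < mu0 - sd0))
    }
  })
})
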