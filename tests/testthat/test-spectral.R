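test_that("gene network construction validates edges", {
  expect_error(gene_network(data.frame(gene_a = "a", gene_b = "a", weight = 1)),
    "self-loop")
  expect_error(gene_network(data.frame(gene_a = "a", gene_b = "b", weight = -1)),
    "non-negative")
  expect_error(
    gene_network(data.frame(
      gene_a = c("a", "b"), gene_b = c("b", "a"), weight = 1
    )),
    "duplicate"
  )
  g <- gene_network(data.frame(gene_a = "a", gene_b = "b", weight = 2),
    nodes = "lonely")
  expect_setequal(igraph::V(g)$name, c("a", "b", "lonely"))
  expect_equal(igraph::ecount(g), 1)
})

test_that("restriction to scored genes keeps singletons and splits paths", {
  g <- path_network(c("a", "b", "c", "d", "e"))
  # all nodes scored -> identity
  all_s <- stats::setNames(1:5, c("a", "b", "c", "d", "e"))
  expect_equal(igraph::ecount(restrict_to_scored(g, all_s)), 4)
  # middle node unscored -> two 2-node components
  part <- stats::setNames(c(1, 2, 4, 5), c("a", "b", "d", "e"))
  r <- restrict_to_scored(g, part)
  comp <- igraph::components(r)
  expect_equal(comp$no, 2)
  expect_equal(sort(comp$csize), c(2, 2))
  # a scored gene absent from the network becomes a singleton, with a message
  expect_message(
    r2 <- restrict_to_scored(g, c(all_s, ghost = 9)),
    "singleton"
  )
  expect_true("ghost" %in% igraph::V(r2)$name)
  expect_equal(igraph::degree(r2)[["ghost"]], 0)
  expect_error(restrict_to_scored(g, c(zz = 1)), "no scored gene")
})

test_that("Laplacian spectra match closed forms on tiny graphs", {
  b2 <- spectral_basis(k2_network())
  expect_equal(b2$components[[1]]$values, c(0, 2), tolerance = 1e-10)
  b3 <- spectral_basis(k3_network())
  expect_equal(b3$components[[1]]$values, c(0, 3, 3), tolerance = 1e-10)
  b1 <- spectral_basis(gene_network(
    data.frame(gene_a = character(0), gene_b = character(0)),
    nodes = "solo"
  ))
  expect_equal(b1$components[[1]]$values, 0)
  # orthonormal eigenvectors, one zero eigenvalue per connected component
  withr::with_seed(11, {
    g <- random_network(40, 0.08)
    b <- spectral_basis(g)
    n_comp <- igraph::components(g)$no
    n_zero <- sum(vapply(b$components, function(cmp) sum(cmp$values < 1e-8), numeric(1)))
    expect_equal(n_zero, n_comp)
    for (cmp in b$components) {
      V <- cmp$vectors
      expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
      expect_true(all(diff(cmp$values) >= -1e-10))
      expect_true(all(cmp$values >= 0))
    }
  })
})

test_that("graph Fourier transform concentrates constants and inverts exactly", {
  b3 <- spectral_basis(k3_network())
  # constant c on a component of size m -> all energy on the zero frequency, c*sqrt(m)
  const <- stats::setNames(rep(2.5, 3), c("a", "b", "c"))
  cf <- graph_fourier(const, b3)[[1]]
  expect_equal(abs(cf[1]), 2.5 * sqrt(3), tolerance = 1e-10)
  expect_lt(max(abs(cf[-1])), 1e-10)
  # a signal equal to an eigenvector has a single unit coefficient
  ev <- stats::setNames(b3$components[[1]]$vectors[, 2], b3$components[[1]]$nodes)
  cf2 <- graph_fourier(ev, b3)[[1]]
  expect_equal(unname(cf2[2]), 1, tolerance = 1e-10)
  expect_lt(max(abs(cf2[-2])), 1e-10)
  # round-trip and Parseval on a random signal
  withr::with_seed(3, {
    x <- stats::setNames(stats::rnorm(3), c("a", "b", "c"))
    cf3 <- graph_fourier(x, b3)
    back <- inverse_graph_fourier(cf3, b3)
    expect_lt(max(abs(back[names(x)] - x)), 1e-10)
    expect_equal(sum(unlist(cf3)^2), sum(x^2), tolerance = 1e-9)
  })
  expect_error(graph_fourier(c(a = 1, b = 2), b3), "missing")
})

test_that("attenuation removes frequencies gradually and preserves means", {
  withr::with_seed(5, {
    g <- random_network(30, 0.12)
    x <- random_signal(g)
    b <- spectral_basis(g)
    ser <- attenuation_series(x, b)
    expect_equal(ncol(ser), 41)
    expect_equal(colnames(ser)[c(1, 41)], c("level_0", "level_40"))
    # level 0 reconstructs the input
    expect_lt(max(abs(ser[names(x), 1] - x)), 1e-8)
    # last level flattens every component to its mean (combinatorial basis)
    memb <- igraph::components(g)$membership
    for (ci in unique(memb)) {
      nodes <- names(memb)[memb == ci]
      expect_equal(unname(ser[nodes, 41]),
        rep(mean(x[nodes]), length(nodes)),
        tolerance = 1e-8
      )
    }
    # per-component mean preserved at every level
    for (ci in unique(memb)) {
      nodes <- names(memb)[memb == ci]
      mus <- colMeans(ser[nodes, , drop = FALSE])
      expect_lt(max(abs(mus - mean(x[nodes]))), 1e-8)
    }
    # Dirichlet energy non-increasing in level
    en <- apply(ser, 2, dirichlet_energy, network = g)
    expect_true(all(diff(en) <= 1e-10))
  })
  # constant input is untouched at every level
  b3 <- spectral_basis(k3_network())
  const <- stats::setNames(rep(1.3, 3), c("a", "b", "c"))
  ser_c <- attenuation_series(const, b3)
  expect_lt(max(abs(ser_c - 1.3)), 1e-10)
  expect_error(attenuation_series(const, b3, step = 0.1, n_steps = 11),
    "exceed")
})

test_that("degree-normalised filtering is monotone in its own energy", {
  withr::with_seed(6, {
    g <- random_network(30, 0.12)
    x <- random_signal(g)
    b <- spectral_basis(g, normalized = TRUE)
    for (cmp in b$components) {
      expect_true(all(cmp$values >= -1e-10 & cmp$values <= 2 + 1e-10))
    }
    ser <- attenuation_series(x, b)
    expect_lt(max(abs(ser[names(x), 1] - x)), 1e-8)
    en <- apply(ser, 2, dirichlet_energy, network = g, normalized = TRUE)
    expect_true(all(diff(en) <= 1e-10))
  })
})

test_that("smoothing raises correlation with a noiseless planted signal", {
  withr::with_seed(9, {
    edges <- rbind(
      clique_edges(sprintf("m%02d", 1:8), weight = 1),
      clique_edges(sprintf("k%02d", 1:8), weight = 1)
    )
    genes <- c(sprintf("m%02d", 1:8), sprintf("k%02d", 1:8), sprintf("b%02d", 1:24))
    pairs <- utils::combn(genes, 2)
    bg <- stats::runif(ncol(pairs)) < 0.04
    edges <- rbind(edges, data.frame(
      gene_a = pairs[1, bg], gene_b = pairs[2, bg], weight = 0.3
    ))
    key <- paste(pmin(edges$gene_a, edges$gene_b), pmax(edges$gene_a, edges$gene_b))
    edges <- edges[!duplicated(key), ]
    g <- gene_network(edges, nodes = genes)
    clean <- stats::setNames(rep(0, length(genes)), genes)
    clean[sprintf("m%02d", 1:8)] <- 1
    clean[sprintf("k%02d", 1:8)] <- -1
    noisy <- clean + stats::rnorm(length(genes), 0, 0.5)
    ser <- attenuation_series(noisy, spectral_basis(g))
    cors <- vapply(0:8, function(l) stats::cor(ser[genes, l + 1], clean[genes]),
      numeric(1))
    expect_true(all(diff(cors) >= -1e-6))
    expect_gt(cors[9], cors[1])
  })
})
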