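# Graph-Laplacian spectral smoothing of S-score signals ("Fourier-like"
# low-pass filtering over a functional gene network).

#' Construct a weighted undirected gene network
#'
#' @param edges Data frame with columns `gene_a`, `gene_b`, `weight`
#'   (`weight` defaults to 1 when missing). Self-loops and duplicate
#'   unordered pairs are rejected; weights must be finite and non-negative.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   nodes.
#' @return An undirected [igraph::igraph] graph with a `weight` edge
#'   attribute.
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (nrow(edges) > 0) {
    if (!all(c("gene_a", "gene_b") %in% names(edges))) {
      stop("edges need columns gene_a, gene_b", call. = FALSE)
    }
    a <- as.character(edges$gene_a)
    b <- as.character(edges$gene_b)
    w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, nrow(edges))
    if (any(a == b)) stop("self-loops are not allowed", call. = FALSE)
    if (any(!is.finite(w)) || any(w < 0)) {
      stop("edge weights must be finite and non-negative", call. = FALSE)
    }
    key <- paste(pmin(a, b), pmax(a, b))
    if (anyDuplicated(key)) {
      stop("duplicate edge(s): ", paste(unique(key[duplicated(key)]), collapse = ", "),
        call. = FALSE
      )
    }
    el <- data.frame(from = a, to = b, weight = w, stringsAsFactors = FALSE)
  } else {
    el <- data.frame(
      from = character(0), to = character(0), weight = numeric(0),
      stringsAsFactors = FALSE
    )
  }
  verts <- unique(c(el$from, el$to, as.character(nodes)))
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}

#' Restrict a network to the genes carrying an S-score
#'
#' Induced subgraph on scored genes. Scored genes absent from the network are
#' retained as singleton components (their smoothed value is their own mean,
#' unchanged by filtering) so downstream gene lists stay complete; singletons
#' can never seed multi-gene modules.
#'
#' @param network A [gene_network()] graph.
#' @param scores Named numeric vector, gene -> S.
#' @return An igraph graph whose vertex set is exactly `names(scores)`.
#' @export
restrict_to_scored <- function(network, scores) {
  genes <- names(scores)
  if (is.null(genes) || length(genes) == 0) stop("`scores` must be named", call. = FALSE)
  common <- intersect(igraph::V(network)$name, genes)
  if (length(common) == 0) {
    stop("no scored gene is present in the network", call. = FALSE)
  }
  g <- igraph::induced_subgraph(network, common)
  missing <- setdiff(genes, igraph::V(network)$name)
  if (length(missing) > 0) {
    message(length(missing), " scored gene(s) absent from the network kept as singletons")
    g <- igraph::add_vertices(g, length(missing), name = missing)
  }
  g
}

#' Laplacian eigenbasis of a gene network, per connected component
#'
#' Builds the combinatorial Laplacian `L = D - W` of each connected component
#' and diagonalises it. With `weighted = TRUE` edge weights are scaled by the
#' network-wide maximum (so weights lie in (0, 1\] and connectivity is
#' preserved); with `weighted = FALSE` the 0/1 adjacency is used.
#'
#' The default combinatorial operator `L = D - W` has the constant vector in
#' its null space, so filtering preserves per-component means and the final
#' attenuation level flattens each component to its mean. The symmetric
#' normalised Laplacian `D^-1/2 L D^-1/2` (`normalized = TRUE`) instead
#' normalises by degree, which stops hub genes and weakly-weighted
#' background edges from dominating the frequency ordering; it is the
#' default for the module-detection pipeline (see [pipeline_config()]),
#' where that property is what lets low-pass filtering separate coherent
#' modules from scattered noise.
#'
#' Eigenvalues are sorted ascending within each component (the first is the
#' zero "constant" frequency) and eigenvectors are orthonormal.
#'
#' @param network A [gene_network()] graph (possibly already restricted to
#'   scored genes).
#' @param weighted Use confidence weights (default `TRUE`).
#' @param normalized Use the symmetric normalised Laplacian (default
#'   `FALSE`).
#' @param max_component Emit a warning when a component exceeds this many
#'   nodes (dense eigendecomposition; default 5000).
#' @return An object of class `spectral_basis`: a list with `components`
#'   (each holding `nodes`, `values`, `vectors`), `nodes` (all nodes in basis
#'   order) and the flags used.
#' @export
spectral_basis <- function(network, weighted = TRUE, normalized = FALSE,
                           max_component = 5000L) {
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  w <- igraph::E(network)$weight
  if (weighted && igraph::ecount(network) > 0) {
    wmax <- max(w)
    if (wmax <= 0) stop("all edge weights are zero; use weighted = FALSE", call. = FALSE)
    igraph::E(network)$weight <- w / wmax
  }
  comp <- igraph::components(network)
  comps <- vector("list", comp$no)
  for (ci in seq_len(comp$no)) {
    nodes <- igraph::V(network)$name[comp$membership == ci]
    if (length(nodes) > max_component) {
      warning("component ", ci, " has ", length(nodes),
        " nodes; dense eigendecomposition may be slow",
        call. = FALSE
      )
    }
    sub <- igraph::induced_subgraph(network, nodes)
    A <- igraph::as_adjacency_matrix(sub,
      attr = if (weighted && igraph::ecount(sub) > 0) "weight" else NULL,
      sparse = FALSE
    )
    A <- A[nodes, nodes, drop = FALSE]
    deg <- rowSums(A)
    L <- diag(deg, nrow = length(nodes)) - A
    if (normalized) {
      d <- ifelse(deg > 0, 1 / sqrt(deg), 0)
      L <- diag(d, nrow = length(nodes)) %*% L %*% diag(d, nrow = length(nodes))
      L <- (L + t(L)) / 2
    }
    e <- eigen(L, symmetric = TRUE)
    ord <- order(e$values)
    comps[[ci]] <- list(
      nodes = nodes,
      values = pmax(e$values[ord], 0),
      vectors = e$vectors[, ord, drop = FALSE]
    )
  }
  structure(
    list(
      components = comps,
      nodes = unlist(lapply(comps, `[[`, "nodes"), use.names = FALSE),
      weighted = weighted, normalized = normalized
    ),
    class = "spectral_basis"
  )
}

check_signal <- function(signal, basis) {
  if (is.null(names(signal))) stop("`signal` must be a named vector", call. = FALSE)
  missing <- setdiff(basis$nodes, names(signal))
  if (length(missing) > 0) {
    stop("signal missing value(s) for: ", paste(utils::head(missing, 5), collapse = ", "),
      if (length(missing) > 5) " ..." else "",
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Graph Fourier transform of a gene signal
#'
#' Projects the signal onto the Laplacian eigenbasis of each connected
#' component; the coefficient at the zero eigenvalue carries the component
#' mean (times sqrt of component size), higher eigenvalues correspond to
#' higher "frequencies" over the network.
#'
#' @param signal Named numeric vector, gene -> S, covering all basis nodes.
#' @param basis A [spectral_basis()].
#' @return List of per-component coefficient vectors.
#' @export
graph_fourier <- function(signal, basis) {
  check_signal(signal, basis)
  lapply(basis$components, function(cmp) {
    drop(crossprod(cmp$vectors, signal[cmp$nodes]))
  })
}

#' Inverse graph Fourier transform
#'
#' @param coefficients Per-component coefficient list from [graph_fourier()].
#' @param basis The matching [spectral_basis()].
#' @return Named numeric vector over all basis nodes.
#' @export
inverse_graph_fourier <- function(coefficients, basis) {
  parts <- mapply(function(cmp, coef) {
    x <- drop(cmp$vectors %*% coef)
    names(x) <- cmp$nodes
    x
  }, basis$components, coefficients, SIMPLIFY = FALSE)
  out <- unlist(parts, use.names = TRUE)
  names(out) <- unlist(lapply(basis$components, `[[`, "nodes"), use.names = FALSE)
  out[basis$nodes]
}

#' Iteratively attenuate the high-frequency content of a gene signal
#'
#' Starting from the raw S-score signal, the highest-frequency Laplacian
#' components are removed a fixed fraction at a time (default 2.5% per step,
#' 40 steps), producing increasingly smoothed versions of the data. At level
#' `k` the coefficients of the globally highest `floor(k * step * (m - c))`
#' nonzero-frequency components are zeroed (`m` = number of genes, `c` =
#' number of connected components); frequency ranking pools all components,
#' with eigenvalue ties broken by component id then within-component index.
#' Zero-frequency (constant) components are never removed, so per-component
#' means are preserved at every level and the final level flattens each
#' component to its mean.
#'
#' @param signal Named numeric vector, gene -> S.
#' @param basis A [spectral_basis()].
#' @param step Fraction of nonzero-frequency components removed per level
#'   (default 0.025).
#' @param n_steps Number of attenuation levels (default 40;
#'   `step * n_steps <= 1`).
#' @return An object of class `attenuation_series`: a numeric matrix (genes
#'   by levels `level_0..level_<n_steps>`) with attributes `step`, `n_steps`
#'   and `kept_fraction`.
#' @export
attenuation_series <- function(signal, basis, step = 0.025, n_steps = 40L) {
  if (step <= 0 || step > 1) stop("`step` must be in (0, 1]", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  if (step * n_steps > 1 + 1e-12) {
    stop("`step * n_steps` must not exceed 1", call. = FALSE)
  }
  check_signal(signal, basis)
  coefs <- graph_fourier(signal, basis)
  m <- length(basis$nodes)
  c_comp <- length(basis$components)
  # pooled table of removable (nonzero-frequency) coefficients
  rem <- do.call(rbind, lapply(seq_along(basis$components), function(ci) {
    vals <- basis$components[[ci]]$values
    if (length(vals) < 2) return(NULL)
    data.frame(comp = ci, idx = 2:length(vals), value = vals[-1])
  }))
  if (!is.null(rem)) {
    rem <- rem[order(-rem$value, rem$comp, rem$idx), , drop = FALSE]
  }
  n_removable <- m - c_comp
  out <- matrix(NA_real_, nrow = m, ncol = n_steps + 1,
    dimnames = list(basis$nodes, paste0("level_", 0:n_steps))
  )
  kept <- numeric(n_steps + 1)
  for (k in 0:n_steps) {
    n_remove <- min(floor(k * step * n_removable + 1e-9), n_removable)
    ck <- coefs
    if (n_remove > 0) {
      kill <- rem[seq_len(n_remove), , drop = FALSE]
      for (ci in unique(kill$comp)) {
        ck[[ci]][kill$idx[kill$comp == ci]] <- 0
      }
    }
    out[, k + 1] <- inverse_graph_fourier(ck, basis)
    kept[k + 1] <- if (n_removable > 0) 1 - n_remove / n_removable else 1
  }
  structure(out,
    step = step, n_steps = n_steps, kept_fraction = kept,
    class = c("attenuation_series", "matrix", "array")
  )
}

#' Dirichlet energy of a gene signal on a network
#'
#' The graph-smoothness functional `x' L x`: for the combinatorial Laplacian
#' the sum over edges of `w_uv (x_u - x_v)^2`, for the normalised operator
#' the same with degree-scaled values. Low-pass filtering in the matching
#' eigenbasis cannot increase it. Weights are scaled by the network maximum
#' when `weighted = TRUE`, matching [spectral_basis()].
#'
#' @param signal Named numeric vector over the network's nodes.
#' @param network A [gene_network()] graph.
#' @param weighted Use (max-scaled) confidence weights (default `TRUE`).
#' @param normalized Energy of the symmetric normalised Laplacian instead of
#'   the combinatorial one (default `FALSE`).
#' @return A single non-negative number.
#' @export
dirichlet_energy <- function(signal, network, weighted = TRUE, normalized = FALSE) {
  if (igraph::ecount(network) == 0) return(0)
  el <- igraph::as_edgelist(network, names = TRUE)
  w <- igraph::E(network)$weight
  if (weighted) w <- w / max(w) else w <- rep(1, length(w))
  x <- signal
  if (normalized) {
    deg <- stats::setNames(rep(0, igraph::vcount(network)), igraph::V(network)$name)
    for (i in seq_along(w)) {
      deg[el[i, 1]] <- deg[el[i, 1]] + w[i]
      deg[el[i, 2]] <- deg[el[i, 2]] + w[i]
    }
    x <- ifelse(deg[names(signal)] > 0, signal / sqrt(deg[names(signal)]), signal)
    names(x) <- names(signal)
  }
  sum(w * (x[el[, 1]] - x[el[, 2]])^2)
}
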