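# Module detection on the attenuation series: thresholding, connected
# components, birth-level / stability / redundancy filters, annotation.

#' Construct a gene module
#'
#' A signed, connected gene set with its birth attenuation level and
#' stability run. Mostly produced by [track_stability()] /
#' [detect_modules()]; exported for constructing reference modules.
#'
#' @param genes Character vector of gene identifiers (stored sorted).
#' @param sign `"positive"` (suppressor-like) or `"negative"`
#'   (enhancer-like).
#' @param birth_level First attenuation level the module was observed at.
#' @param stability_run Number of successive stable levels.
#' @return An object of class `gene_module`.
#' @export
new_module <- function(genes, sign, birth_level, stability_run) {
  structure(
    list(
      genes = sort(as.character(genes)), sign = sign,
      birth_level = as.integer(birth_level),
      stability_run = as.integer(stability_run),
      annotations = NULL
    ),
    class = "gene_module"
  )
}

#' @export
print.gene_module <- function(x, ...) {
  cat(sprintf(
    "<gene_module> %s, %d genes, birth level %d, stability run %d\n  %s\n",
    x$sign, length(x$genes), x$birth_level, x$stability_run,
    paste(x$genes, collapse = ";")
  ))
  invisible(x)
}

#' Genes above (or below) the module threshold at one attenuation level
#'
#' A gene belongs to the positive (suppressor-like) candidate set when its
#' smoothed signal is strictly greater than `mu + sigma`, and to the negative
#' (enhancer-like) set when strictly less than `mu - sigma`. By default `mu`
#' and `sigma` are computed once from the raw (level-0) signal and held fixed
#' across levels.
#'
#' @param series An [attenuation_series()].
#' @param level Attenuation level (0-based).
#' @param mu,sigma Mean and SD of the S-score distribution defining the
#'   threshold.
#' @param sign `"positive"` or `"negative"`.
#' @return Character vector of gene names (sorted).
#' @export
threshold_genes <- function(series, level, mu, sigma, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  col <- paste0("level_", level)
  if (!col %in% colnames(series)) stop("level ", level, " not in series", call. = FALSE)
  x <- series[, col]
  sel <- if (sign == "positive") x > mu + sigma else x < mu - sigma
  sort(rownames(series)[sel])
}

#' Connected modules among a thresholded gene set
#'
#' Connected components of the network induced on the gene set; singletons
#' are discarded (a module is a group of connected genes, size >= 2).
#'
#' @param genes Character vector of genes (subset of the network's nodes).
#' @param network The (scored-gene) network.
#' @return List of sorted character vectors, ordered by their smallest gene.
#' @export
connected_modules <- function(genes, network) {
  genes <- intersect(genes, igraph::V(network)$name)
  if (length(genes) == 0) return(list())
  sub <- igraph::induced_subgraph(network, genes)
  comp <- igraph::components(sub)
  out <- lapply(seq_len(comp$no), function(ci) {
    sort(igraph::V(sub)$name[comp$membership == ci])
  })
  out <- out[vapply(out, length, integer(1)) >= 2]
  out[order(vapply(out, `[`, character(1), 1))]
}

#' Birth-level and stability filtering of candidate modules
#'
#' A candidate module observed at level `k >= start_level` is retained when,
#' for at least `min_run` successive levels after `k`, at least
#' `stability_fraction` of its genes are still above the threshold
#' (inclusive: exactly 40% passes at the default). The retained module
#' records its birth level and the length of its stability run.
#'
#' @param modules_by_level Named list (names = levels as characters), each a
#'   list of gene sets (from [connected_modules()]).
#' @param threshold_by_level Named list (same level names), each the
#'   thresholded gene set at that level (from [threshold_genes()]).
#' @param sign Module sign, stored on the results.
#' @param start_level Earliest birth level considered (default 4).
#' @param stability_fraction Minimum fraction of genes retained above the
#'   threshold at each successive level (default 0.40).
#' @param min_run Minimum number of successive stable levels (default 2).
#' @return List of `gene_module` objects (possibly redundant across levels;
#'   see [deduplicate_modules()]).
#' @export
track_stability <- function(modules_by_level, threshold_by_level, sign,
                            start_level = 4L, stability_fraction = 0.40,
                            min_run = 2L) {
  levels <- sort(as.integer(names(modules_by_level)))
  if (length(levels) > 1 && any(diff(levels) != 1)) {
    stop("levels must be contiguous", call. = FALSE)
  }
  max_level <- max(levels)
  out <- list()
  for (k in levels) {
    if (k < start_level) next
    for (genes in modules_by_level[[as.character(k)]]) {
      run <- 0L
      j <- k + 1L
      while (j <= max_level) {
        frac <- length(intersect(genes, threshold_by_level[[as.character(j)]])) /
          length(genes)
        if (frac >= stability_fraction - 1e-12) {
          run <- run + 1L
          j <- j + 1L
        } else {
          break
        }
      }
      if (run >= min_run) {
        out[[length(out) + 1]] <- new_module(genes, sign, k, run)
      }
    }
  }
  out
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

#' Remove redundant modules
#'
#' Among any pair of modules with Jaccard similarity at or above the
#' threshold, the one with the longer stability run is kept; ties go to the
#' lower birth level, then the larger module, then the lexicographically
#' smallest gene set. Selection is greedy in that priority order, so the
#' result is deterministic.
#'
#' @param modules List of `gene_module` objects.
#' @param jaccard_threshold Redundancy threshold (default 0.8).
#' @return Filtered list of modules, in priority order.
#' @export
deduplicate_modules <- function(modules, jaccard_threshold = 0.8) {
  if (length(modules) <= 1) return(modules)
  key <- vapply(modules, function(m) paste(m$genes, collapse = ";"), character(1))
  ord <- order(
    -vapply(modules, `[[`, integer(1), "stability_run"),
    vapply(modules, `[[`, integer(1), "birth_level"),
    -vapply(modules, function(m) length(m$genes), integer(1)),
    key
  )
  kept <- list()
  for (i in ord) {
    m <- modules[[i]]
    redundant <- any(vapply(kept, function(km) {
      jaccard(m$genes, km$genes) >= jaccard_threshold - 1e-12
    }, logical(1)))
    if (!redundant) kept[[length(kept) + 1]] <- m
  }
  kept
}

#' Detect signed gene modules from an attenuation series
#'
#' Full module-detection chain: threshold the smoothed signal at every level
#' (`mu +/- sigma`, statistics taken from the raw level-0 signal unless
#' `threshold_per_level`), take connected components of size >= 2, apply the
#' birth-level and stability filters, and remove redundant modules. Positive
#' modules are suppressor-like (signal above `mu + sigma`), negative modules
#' enhancer-like.
#'
#' @param series An [attenuation_series()].
#' @param network The scored-gene network the series was computed on.
#' @param start_level Earliest birth level (default 4).
#' @param stability_fraction Stability criterion (default 0.40).
#' @param min_run Minimum stable run (default 2).
#' @param jaccard_threshold Redundancy threshold (default 0.8).
#' @param threshold_per_level Recompute `mu`/`sigma` from each level's signal
#'   instead of holding the raw-signal statistics fixed (default `FALSE`).
#' @return List of `gene_module` objects (both signs, positive first).
#' @export
detect_modules <- function(series, network, start_level = 4L,
                           stability_fraction = 0.40, min_run = 2L,
                           jaccard_threshold = 0.8,
                           threshold_per_level = FALSE) {
  n_steps <- attr(series, "n_steps")
  levels <- 0:n_steps
  mu0 <- mean(series[, "level_0"])
  sd0 <- stats::sd(series[, "level_0"])
  out <- list()
  for (sg in c("positive", "negative")) {
    thr <- lapply(levels, function(l) {
      if (threshold_per_level) {
        threshold_genes(series, l, mean(series[, l + 1]), stats::sd(series[, l + 1]), sg)
      } else {
        threshold_genes(series, l, mu0, sd0, sg)
      }
    })
    names(thr) <- as.character(levels)
    mods <- lapply(thr, connected_modules, network = network)
    names(mods) <- as.character(levels)
    cand <- track_stability(mods, thr, sg,
      start_level = start_level,
      stability_fraction = stability_fraction, min_run = min_run
    )
    out <- c(out, deduplicate_modules(cand, jaccard_threshold))
  }
  out
}

#' Annotate modules by gene-set enrichment
#'
#' Attaches, to each module, hypergeometric enrichment results against each
#' collection (delegating to [enrich()]); used for labelling modules with
#' pathways, druggable genes, htt partners, autophagy/mitochondrial/synaptic
#' gene lists and the like.
#'
#' @param modules List of `gene_module` objects.
#' @param collections List of [gene_set_collection()] objects.
#' @param min_overlap Minimum overlap passed to [enrich()] (default 1).
#' @return The modules, each with an `annotations` data frame (columns
#'   `collection`, `term`, `k`, `n`, `K`, `N`, `p`, `genes`).
#' @export
annotate_modules <- function(modules, collections, min_overlap = 1L) {
  if (inherits(collections, "gene_set_collection")) collections <- list(collections)
  lapply(modules, function(m) {
    ann <- lapply(collections, function(coll) {
      res <- enrich(m$genes, coll, min_overlap = min_overlap)
      if (nrow(res) == 0) return(NULL)
      cbind(collection = coll$name, res[, c("term", "k", "n", "K", "N", "p", "genes")])
    })
    ann <- do.call(rbind, ann[!vapply(ann, is.null, logical(1))])
    m$annotations <- if (is.null(ann)) {
      data.frame(
        collection = character(0), term = character(0), k = integer(0),
        n = integer(0), K = integer(0), N = integer(0), p = numeric(0),
        genes = character(0), stringsAsFactors = FALSE
      )
    } else {
      rownames(ann) <- NULL
      ann
    }
    m
  })
}

#' Export a module's induced subnetwork as a confidence graph
#'
#' Induced edges of the module with min-max normalised weights in \[0, 1\]
#' (all 1.0 when the weights are uniform), for display as a confidence
#' graph. Edges are ordered by (gene_a, gene_b) with each pair stored
#' alphabetically.
#'
#' @param module A `gene_module` (or plain character vector of genes).
#' @param network The gene network.
#' @return Data frame `gene_a`, `gene_b`, `weight`, `normalized_weight`.
#' @export
export_module_graph <- function(module, network) {
  genes <- if (inherits(module, "gene_module")) module$genes else as.character(module)
  sub <- igraph::induced_subgraph(network, intersect(genes, igraph::V(network)$name))
  el <- igraph::as_edgelist(sub, names = TRUE)
  w <- igraph::E(sub)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  nw <- if (length(w) == 0) {
    numeric(0)
  } else if (max(w) == min(w)) {
    rep(1.0, length(w))
  } else {
    (w - min(w)) / (max(w) - min(w))
  }
  out <- data.frame(
    gene_a = a, gene_b = b, weight = w, normalized_weight = nw,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-match recovery of planted modules
#'
#' For each reference (planted) module, the maximum Jaccard similarity
#' achieved by any detected module of the same sign.
#'
#' @param modules Detected `gene_module` list.
#' @param truth_modules List of lists with elements `genes` and `sign`.
#' @return Numeric vector of best Jaccard values, one per reference module.
#' @export
module_recovery <- function(modules, truth_modules) {
  vapply(truth_modules, function(tm) {
    js <- vapply(modules, function(m) {
      if (m$sign != tm$sign) return(0)
      jaccard(m$genes, tm$genes)
    }, numeric(1))
    if (length(js) == 0) 0 else max(js)
  }, numeric(1))
}

#' Flatten a module list to a data frame
#'
#' @param modules List of `gene_module` objects.
#' @return Data frame `module_id`, `sign`, `birth_level`, `stability_run`,
#'   `n_genes`, `genes` (semicolon-joined).
#' @export
modules_table <- function(modules) {
  data.frame(
    module_id = if (length(modules)) sprintf("M%03d", seq_along(modules)) else character(0),
    sign = vapply(modules, `[[`, character(1), "sign"),
    birth_level = vapply(modules, `[[`, integer(1), "birth_level"),
    stability_run = vapply(modules, `[[`, integer(1), "stability_run"),
    n_genes = vapply(modules, function(m) length(m$genes), integer(1)),
    genes = vapply(modules, function(m) paste(m$genes, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
}
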