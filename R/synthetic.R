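# Seeded generators for every pipeline input: planted-partition gene network,
# touch-test screen records, annotation collections and mouse tables.

#' Parameters and ground truth for a synthetic screen + network
#'
#' Fixes the study conditions emulated by all generators: a touch-test screen
#' with 5 touches per animal and 70-90 animals per clone against a baseline
#' of 20.6% +/- 3%, and a planted-partition gene network carrying modules
#' whose true S-score is shifted by a multiple of the background noise SD.
#' The background noise SD on the S scale is `baseline_sd / baseline_mean`
#' (background genes' true responsiveness is drawn from
#' Normal(baseline_mean, baseline_sd), truncated to \[1, 99\]); a planted
#' module of sign `+`/`-` has true responsiveness
#' `baseline_mean * (1 +/- effect_sigma * baseline_sd / baseline_mean)`,
#' truncated to the same range.
#' Module signs alternate positive, negative, positive, ...
#'
#' @param n_genes Total genes (default 500).
#' @param n_modules Planted modules (default 3).
#' @param module_size Genes per planted module (default 10).
#' @param effect_sigma Planted mean shift in units of the background S-score
#'   SD (default 2).
#' @param p_in Within-module edge probability (default 0.6).
#' @param p_out Background edge probability (default 0.01).
#' @param baseline_mean,baseline_sd Baseline responsiveness %, mean and SD
#'   (defaults 20.6 and 3).
#' @param animals Integer range (min, max) of animals per clone (default
#'   70-90).
#' @param touches Touches per animal (default 5).
#' @param n_batches Number of monthly batches (default 4).
#' @param seed Integer seed; all generators are pure functions of the truth
#'   object (parameters + seed).
#' @return An object of class `synthetic_truth` holding all parameters,
#'   `genes`, `planted_modules` (gene set, sign, effect) and `true_effects`
#'   (gene -> true responsiveness %).
#' @export
synthetic_truth <- function(n_genes = 500L, n_modules = 3L, module_size = 10L,
                            effect_sigma = 2, p_in = 0.6, p_out = 0.01,
                            baseline_mean = 20.6, baseline_sd = 3,
                            animals = c(70L, 90L), touches = 5L,
                            n_batches = 4L, seed = 1L) {
  if (n_modules * module_size > n_genes) {
    stop("planted modules need more genes than `n_genes` provides", call. = FALSE)
  }
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1) {
    stop("edge probabilities must lie in [0, 1]", call. = FALSE)
  }
  genes <- sprintf("g%04d", seq_len(n_genes))
  sigma_s <- baseline_sd / baseline_mean
  planted <- lapply(seq_len(n_modules), function(i) {
    idx <- ((i - 1) * module_size + 1):(i * module_size)
    sign <- if (i %% 2 == 1) "positive" else "negative"
    list(
      genes = genes[idx], sign = sign,
      effect_sigma = if (sign == "positive") effect_sigma else -effect_sigma
    )
  })
  true_effects <- withr::with_seed(seed, {
    p <- stats::rnorm(n_genes, baseline_mean, baseline_sd)
    p <- pmin(pmax(p, 1), 99)
    names(p) <- genes
    for (pm in planted) {
      p[pm$genes] <- min(max(baseline_mean * (1 + pm$effect_sigma * sigma_s), 1), 99)
    }
    p
  })
  structure(
    list(
      n_genes = n_genes, n_modules = n_modules, module_size = module_size,
      effect_sigma = effect_sigma, p_in = p_in, p_out = p_out,
      baseline_mean = baseline_mean, baseline_sd = baseline_sd,
      animals = as.integer(animals), touches = as.integer(touches),
      n_batches = as.integer(n_batches), seed = as.integer(seed),
      genes = genes, planted_modules = planted, true_effects = true_effects
    ),
    class = "synthetic_truth"
  )
}

#' Simulate a planted-partition gene network
#'
#' Within-module gene pairs are connected with probability `p_in` and weight
#' Uniform(0.5, 1\]; all other pairs with probability `p_out` and weight
#' Uniform(0, 0.5\]. Each planted module is guaranteed connected: if its
#' sampled edges leave it split, a spanning path over the module's genes is
#' added. Deterministic given the truth's seed.
#'
#' @param truth A [synthetic_truth()].
#' @return A [gene_network()] over all of the truth's genes.
#' @export
simulate_network <- function(truth) {
  withr::with_seed(truth$seed + 1L, {
    genes <- truth$genes
    module_of <- rep(0L, length(genes))
    names(module_of) <- genes
    for (i in seq_along(truth$planted_modules)) {
      module_of[truth$planted_modules[[i]]$genes] <- i
    }
    pairs <- utils::combn(genes, 2)
    same <- module_of[pairs[1, ]] == module_of[pairs[2, ]] &
      module_of[pairs[1, ]] > 0L
    p_edge <- ifelse(same, truth$p_in, truth$p_out)
    keep <- stats::runif(ncol(pairs)) < p_edge
    a <- pairs[1, keep]
    b <- pairs[2, keep]
    in_mod <- same[keep]
    w <- ifelse(in_mod, stats::runif(sum(keep), 0.5, 1), stats::runif(sum(keep), 0, 0.5))
    edges <- data.frame(gene_a = a, gene_b = b, weight = w, stringsAsFactors = FALSE)
    # guarantee each planted module is internally connected
    for (pm in truth$planted_modules) {
      sub <- edges[edges$gene_a %in% pm$genes & edges$gene_b %in% pm$genes, ]
      g <- igraph::graph_from_data_frame(sub[, 1:2],
        directed = FALSE, vertices = pm$genes
      )
      memb <- igraph::components(g)$membership
      if (max(memb) > 1) {
        for (j in seq_along(pm$genes)[-1]) {
          a2 <- pm$genes[j - 1]
          b2 <- pm$genes[j]
          present <- any(
            (edges$gene_a == a2 & edges$gene_b == b2) |
              (edges$gene_a == b2 & edges$gene_b == a2)
          )
          if (!present && memb[a2] != memb[b2]) {
            edges <- rbind(edges, data.frame(
              gene_a = a2, gene_b = b2,
              weight = stats::runif(1, 0.5, 1), stringsAsFactors = FALSE
            ))
            memb[memb == memb[b2]] <- memb[a2]
          }
        }
      }
    }
    gene_network(edges, nodes = genes)
  })
}

#' Simulate touch-test screen records and baselines
#'
#' One RNAi clone per gene: the number of animals is Uniform{min..max}, and
#' each animal's response count is Binomial(touches, p) at the gene's true
#' responsiveness. Empty-vector control clones are simulated per monthly
#' batch (with well-to-well variability in true responsiveness so the
#' baseline SD matches the configured value) and summarised into per-batch
#' and cumulated baseline rows. Optionally a fraction of clones is flagged
#' with a toxicity phenotype (flags are assigned, not modelled).
#'
#' @param truth A [synthetic_truth()].
#' @param n_controls_per_batch Control clones per batch (default 30).
#' @param toxic_fraction Fraction of gene clones assigned a random toxicity
#'   flag (default 0).
#' @param overdispersion Beta-binomial overdispersion rho in \[0, 1); 0
#'   (default) gives pure binomial animals.
#' @return List with `records` (screen records data frame, responses and
#'   flags as delimited strings) and `baselines` (batch, mean_percent,
#'   sd_percent; includes a `"cumulated"` row).
#' @export
simulate_screen <- function(truth, n_controls_per_batch = 30L,
                            toxic_fraction = 0, overdispersion = 0) {
  withr::with_seed(truth$seed + 2L, {
    genes <- truth$genes
    n <- length(genes)
    batches <- sprintf("m%02d", ((seq_len(n) - 1) %% truth$n_batches) + 1)
    n_animals <- sample(seq(truth$animals[1], truth$animals[2]), n, replace = TRUE)
    draw_animals <- function(k, p) {
      if (overdispersion > 0) {
        ab <- (1 - overdispersion) / overdispersion
        pa <- stats::rbeta(k, p * ab, (1 - p) * ab)
        stats::rbinom(k, truth$touches, pa)
      } else {
        stats::rbinom(k, truth$touches, p)
      }
    }
    responses <- vapply(seq_len(n), function(i) {
      p <- truth$true_effects[genes[i]] / 100
      paste(draw_animals(n_animals[i], p), collapse = ";")
    }, character(1))
    flags <- rep("", n)
    if (toxic_fraction > 0) {
      tox <- stats::runif(n) < toxic_fraction
      flags[tox] <- sample(TOXICITY_FLAGS, sum(tox), replace = TRUE)
    }
    records <- data.frame(
      clone_id = sprintf("c%04d", seq_len(n)),
      gene_id = genes, batch = batches, touches = truth$touches,
      responses = responses, flags = flags, stringsAsFactors = FALSE
    )
    # control wells: extra true-responsiveness spread so the SD across
    # control clones matches the configured baseline SD on top of the
    # binomial sampling error of ~80 animals
    mean_animals <- mean(truth$animals)
    binom_se <- 100 * sqrt(0.206 * (1 - 0.206) / truth$touches / mean_animals)
    well_sd <- sqrt(max(truth$baseline_sd^2 - binom_se^2, 0)) / 100
    ctrl_pct <- list()
    for (b in unique(batches)) {
      k <- sample(seq(truth$animals[1], truth$animals[2]), n_controls_per_batch,
        replace = TRUE
      )
      p_well <- pmin(pmax(stats::rnorm(
        n_controls_per_batch,
        truth$baseline_mean / 100, well_sd
      ), 0.01), 0.99)
      ctrl_pct[[b]] <- vapply(seq_len(n_controls_per_batch), function(i) {
        mean(100 * stats::rbinom(k[i], truth$touches, p_well[i]) / truth$touches)
      }, numeric(1))
    }
    baselines <- data.frame(
      batch = c(names(ctrl_pct), "cumulated"),
      mean_percent = c(
        vapply(ctrl_pct, mean, numeric(1)),
        mean(unlist(ctrl_pct))
      ),
      sd_percent = c(
        vapply(ctrl_pct, stats::sd, numeric(1)),
        stats::sd(unlist(ctrl_pct))
      ),
      stringsAsFactors = FALSE
    )
    rownames(baselines) <- NULL
    list(records = records, baselines = baselines)
  })
}

#' Simulate an annotation collection with planted positive controls
#'
#' One term per planted module (covering exactly its genes) plus random
#' terms drawn from the whole gene universe.
#'
#' @param truth A [synthetic_truth()].
#' @param n_random_terms Number of random terms (default 20).
#' @param genes_per_term Genes per random term (default 15).
#' @return A [gene_set_collection()] over all of the truth's genes.
#' @export
simulate_annotations <- function(truth, n_random_terms = 20L, genes_per_term = 15L) {
  withr::with_seed(truth$seed + 3L, {
    sets <- lapply(truth$planted_modules, `[[`, "genes")
    names(sets) <- sprintf("planted_module_%d", seq_along(sets))
    if (n_random_terms > 0) {
      rnd <- lapply(seq_len(n_random_terms), function(i) {
        sample(truth$genes, genes_per_term)
      })
      names(rnd) <- sprintf("random_term_%02d", seq_len(n_random_terms))
      sets <- c(sets, rnd)
    }
    gene_set_collection(sets, truth$genes, name = "synthetic_annotations")
  })
}

#' Simulate an ortholog map and two mouse dysregulation tables
#'
#' Constructs tables containing exactly the requested overlap structure: of
#' `n_conserved` worm modifiers given mouse orthologs, `in_a_only` genes are
#' dysregulated only in model A, `in_b_only` only in model B,
#' `both_concordant` in both with the same direction, and `both_opposite` in
#' both with opposite directions; remaining conserved genes are dysregulated
#' in neither. Directions are drawn at random under the seed.
#'
#' @param truth A [synthetic_truth()].
#' @param modifiers Data frame `gene_id`, `hit_class` of worm modifiers.
#' @param n_conserved Number of modifiers given a mouse ortholog.
#' @param in_a_only,in_b_only,both_concordant,both_opposite Overlap counts.
#' @return List with `orthologs` (worm_gene, mouse_gene, cluster_id),
#'   `table_a` and `table_b` (mouse_gene, direction, model_label).
#' @export
simulate_mouse_tables <- function(truth, modifiers, n_conserved,
                                  in_a_only = 0L, in_b_only = 0L,
                                  both_concordant = 0L, both_opposite = 0L) {
  if (n_conserved > nrow(modifiers)) {
    stop("n_conserved exceeds the number of modifiers", call. = FALSE)
  }
  if (in_a_only + in_b_only + both_concordant + both_opposite > n_conserved) {
    stop("overlap spec exceeds n_conserved", call. = FALSE)
  }
  withr::with_seed(truth$seed + 4L, {
    worm <- as.character(modifiers$gene_id)[seq_len(n_conserved)]
    mouse <- paste0("Mm_", worm)
    orthologs <- data.frame(
      worm_gene = worm, mouse_gene = mouse,
      cluster_id = sprintf("C%04d", seq_len(n_conserved)),
      stringsAsFactors = FALSE
    )
    idx <- sample(seq_len(n_conserved))
    take <- function(k) {
      out <- idx[seq_len(k)]
      idx <<- idx[-seq_len(k)]
      out
    }
    i_a <- take(in_a_only)
    i_b <- take(in_b_only)
    i_cc <- take(both_concordant)
    i_op <- take(both_opposite)
    rdir <- function(k) sample(c("up", "down"), k, replace = TRUE)
    dir_cc <- rdir(both_concordant)
    dir_op <- rdir(both_opposite)
    table_a <- data.frame(
      mouse_gene = mouse[c(i_a, i_cc, i_op)],
      direction = c(rdir(in_a_only), dir_cc, dir_op),
      model_label = "A", stringsAsFactors = FALSE
    )
    table_b <- data.frame(
      mouse_gene = mouse[c(i_b, i_cc, i_op)],
      direction = c(
        rdir(in_b_only), dir_cc,
        ifelse(dir_op == "up", "down", "up")
      ),
      model_label = "B", stringsAsFactors = FALSE
    )
    list(orthologs = orthologs, table_a = table_a, table_b = table_b)
  })
}
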