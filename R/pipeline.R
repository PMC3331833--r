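# Pipeline orchestration: configuration, input validation, end-to-end run
# (score -> smooth -> modules -> enrich -> crossmap) with a reproducible
# manifest.

#' Pipeline configuration
#'
#' All stage parameters default to the screen's published analysis
#' constants: hit-calling multiplier 2.6, attenuation step 2.5% over 40
#' levels, module birth level 4, stability fraction 40% over at least 2
#' successive levels, redundancy Jaccard 0.8. Configurations round-trip
#' losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param output_dir Directory for all pipeline outputs.
#' @param seed Integer seed used by the synthetic generators.
#' @param inputs Optional named list of input paths (`records`, `baselines`,
#'   `network`, `annotations`, `orthologs`, `mouse_a`, `mouse_b`); when
#'   `NULL` the synthetic generators produce them under `output_dir/inputs`.
#' @param multiplier,step,n_steps,start_level,stability_fraction,min_run,jaccard
#'   Stage parameters (see the stage functions for semantics).
#' @param weighted Use network confidence weights (default `TRUE`).
#' @param normalized Smooth with the symmetric normalised Laplacian (default
#'   `TRUE`; see [spectral_basis()] for why the pipeline normalises by
#'   degree).
#' @param synthetic Named list of overrides for [synthetic_truth()]
#'   parameters (used only when `inputs` is `NULL`).
#' @param crossmap Named list of overlap counts for
#'   [simulate_mouse_tables()] (`n_conserved`, `in_a_only`, `in_b_only`,
#'   `both_concordant`, `both_opposite`); `NULL` picks counts proportional
#'   to the number of modifiers found.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1L, inputs = NULL,
                            multiplier = 2.6, step = 0.025, n_steps = 40L,
                            start_level = 4L, stability_fraction = 0.40,
                            min_run = 2L, jaccard = 0.8, weighted = TRUE,
                            normalized = TRUE, synthetic = list(),
                            crossmap = NULL) {
  structure(
    list(
      output_dir = output_dir, seed = as.integer(seed), inputs = inputs,
      multiplier = multiplier, step = step, n_steps = as.integer(n_steps),
      start_level = as.integer(start_level),
      stability_fraction = stability_fraction, min_run = as.integer(min_run),
      jaccard = jaccard, weighted = weighted, normalized = normalized,
      synthetic = synthetic, crossmap = crossmap
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[names(x) %in% names(formals(pipeline_config))])
}

stage_fail <- function(stage, ...) {
  stop("[stage: ", stage, "] ", ..., call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input generation (synthetic, unless paths are
#' supplied), screen scoring, spectral smoothing of the S signal over the
#' scored-gene network, module detection and annotation, gene-set enrichment
#' of the suppressor and enhancer gene lists, and cross-species
#' intersection. Every intermediate artifact is written under the
#' configuration's output directory and a manifest (file MD5 hashes,
#' parameters, seed, stage timings) is written as `manifest.json`; identical
#' configuration and inputs give identical content hashes.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stage_fail(stage, conditionMessage(e))
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  outputs <- character(0)
  emit <- function(name) {
    outputs <<- c(outputs, name)
    file.path(config$output_dir, name)
  }

  # stage 1: inputs ----------------------------------------------------
  truth <- NULL
  if (is.null(config$inputs)) {
    inp_dir <- file.path(config$output_dir, "inputs")
    dir.create(inp_dir, showWarnings = FALSE)
    inputs <- clock("simulate", {
      truth <- do.call(
        synthetic_truth,
        utils::modifyList(list(seed = config$seed), config$synthetic)
      )
      net <- simulate_network(truth)
      scr <- simulate_screen(truth)
      coll <- simulate_annotations(truth)
      write_gene_network(net, file.path(inp_dir, "network.tsv"))
      write_tsv_plain(scr$records, file.path(inp_dir, "records.tsv"))
      write_tsv_plain(scr$baselines, file.path(inp_dir, "baselines.tsv"))
      outputs <<- c(outputs, file.path("inputs", c(
        "network.tsv", "records.tsv", "baselines.tsv"
      )))
      list(
        records = scr$records, baselines = scr$baselines,
        network = net, collection = coll
      )
    })
  } else {
    inputs <- clock("load", {
      for (p in unlist(config$inputs)) {
        if (!file.exists(p)) stop("missing input file: ", p)
      }
      sets <- if (!is.null(config$inputs$annotations)) {
        read_gene_term(config$inputs$annotations)
      } else {
        NULL
      }
      list(
        records = read_screen_records(config$inputs$records),
        baselines = read_baselines(config$inputs$baselines),
        network = read_gene_network(config$inputs$network),
        annotation_sets = sets
      )
    })
  }

  # stage 2: score ------------------------------------------------------
  sscores <- clock("score", {
    s <- score_screen(inputs$records, inputs$baselines, config$multiplier)
    write_sscore_table(s, emit("sscores.tsv"))
    s
  })

  # stage 3: smooth -----------------------------------------------------
  smooth <- clock("smooth", {
    scored <- sscores[!sscores$excluded, ]
    signal <- stats::setNames(scored$s, scored$gene_id)
    signal <- tapply(signal, names(signal), mean) # clones -> gene level
    signal <- stats::setNames(as.numeric(signal), names(signal))
    net <- suppressMessages(restrict_to_scored(inputs$network, signal))
    basis <- spectral_basis(net,
      weighted = config$weighted, normalized = config$normalized
    )
    series <- attenuation_series(signal, basis,
      step = config$step, n_steps = config$n_steps
    )
    write_attenuation_series(series, emit("smoothed.tsv"))
    list(network = net, series = series)
  })

  # universe for enrichment: genes assayed and scored
  universe <- unique(sscores$gene_id[!sscores$excluded])
  collection <- if (!is.null(inputs$collection)) {
    inputs$collection
  } else if (!is.null(inputs$annotation_sets)) {
    gene_set_collection(inputs$annotation_sets, universe, name = "annotations")
  } else {
    NULL
  }

  # stage 4: modules ----------------------------------------------------
  modules <- clock("modules", {
    mods <- detect_modules(smooth$series, smooth$network,
      start_level = config$start_level,
      stability_fraction = config$stability_fraction,
      min_run = config$min_run, jaccard_threshold = config$jaccard
    )
    if (!is.null(collection)) {
      mods <- suppressMessages(annotate_modules(mods, collection))
      ann <- do.call(rbind, lapply(seq_along(mods), function(i) {
        a <- mods[[i]]$annotations
        if (nrow(a) == 0) return(NULL)
        cbind(module_id = sprintf("M%03d", i), a)
      }))
      if (!is.null(ann)) write_tsv_plain(ann, emit("module_annotations.tsv"))
    }
    write_tsv_plain(modules_table(mods), emit("modules.tsv"))
    mods
  })

  # stage 5: enrich -----------------------------------------------------
  mods_df <- modifier_genes(sscores)
  clock("enrich", {
    if (!is.null(collection)) {
      for (cls in c("suppressor", "enhancer")) {
        q <- mods_df$gene_id[mods_df$hit_class == cls]
        res <- suppressMessages(enrich(q, collection))
        write_tsv_plain(res, emit(paste0("enrichment_", cls, ".tsv")))
      }
    }
    NULL
  })

  # stage 6: crossmap ---------------------------------------------------
  clock("crossmap", {
    have_tables <- FALSE
    orth <- ta <- tb <- NULL
    if (!is.null(config$inputs)) {
      if (!is.null(config$inputs$orthologs)) {
        orth <- read_ortholog_map(config$inputs$orthologs)
        ta <- read_dysregulation(config$inputs$mouse_a)
        tb <- read_dysregulation(config$inputs$mouse_b)
        have_tables <- TRUE
      }
    } else if (nrow(mods_df) > 0) {
      spec <- config$crossmap
      if (is.null(spec)) {
        n_cons <- max(1L, floor(0.4 * nrow(mods_df)))
        n_dys <- floor(n_cons / 2)
        spec <- list(
          n_conserved = n_cons,
          in_a_only = floor(n_dys / 3), in_b_only = floor(n_dys / 3),
          both_concordant = max(n_dys - 2 * floor(n_dys / 3) - 1, 0),
          both_opposite = min(1L, n_dys)
        )
      }
      mt <- do.call(
        simulate_mouse_tables,
        c(list(truth = truth, modifiers = mods_df), spec)
      )
      orth <- mt$orthologs
      ta <- mt$table_a
      tb <- mt$table_b
      write_tsv_plain(orth, emit(file.path("inputs", "orthologs.tsv")))
      write_tsv_plain(ta, emit(file.path("inputs", "mouse_a.tsv")))
      write_tsv_plain(tb, emit(file.path("inputs", "mouse_b.tsv")))
      have_tables <- TRUE
    }
    if (have_tables) {
      cons <- suppressMessages(conserved_modifiers(mods_df, orth))
      ov <- intersect_dysregulation(cons, ta, tb)
      write_tsv_plain(ov$report, emit("crossmap.tsv"))
      pri <- prioritize(ov)
      write_tsv_plain(pri, emit("prioritized.tsv"))
      jsonlite::write_json(
        list(counts = as.list(ov$counts), n_prioritized = nrow(pri)),
        file.path(config$output_dir, "crossmap_summary.json"),
        auto_unbox = TRUE
      )
      outputs <<- c(outputs, "crossmap_summary.json")
    }
    NULL
  })

  # manifest -------------------------------------------------------------
  files <- file.path(config$output_dir, outputs)
  manifest <- list(
    seed = config$seed,
    parameters = unclass(config)[c(
      "multiplier", "step", "n_steps", "start_level", "stability_fraction",
      "min_run", "jaccard", "weighted", "normalized"
    )],
    files = stats::setNames(
      as.list(unname(tools::md5sum(files))), outputs
    ),
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}

add_failure <- function(failures, file, line, message) {
  rbind(failures, data.frame(
    file = file, line = line, message = message, stringsAsFactors = FALSE
  ))
}

#' Validate pipeline input files
#'
#' Per-file format checks (column presence, value domains, duplicate
#' detection) with line numbers; failures are reported, not raised.
#'
#' @param paths Named list of paths; recognised names are `records`,
#'   `baselines`, `network`, `orthologs`, `mouse_a`, `mouse_b`.
#' @return Data frame `file`, `line`, `message` (zero rows when everything
#'   is well-formed). Line numbers refer to data rows (header = line 1).
#' @export
validate_inputs <- function(paths) {
  failures <- data.frame(
    file = character(0), line = integer(0), message = character(0),
    stringsAsFactors = FALSE
  )
  try_read <- function(path, required) {
    tryCatch(read_tsv_plain(path, required), error = function(e) {
      failures <<- add_failure(failures, path, NA_integer_, conditionMessage(e))
      NULL
    })
  }
  if (!is.null(paths$records)) {
    x <- try_read(paths$records, c("clone_id", "gene_id", "batch", "touches", "responses", "flags"))
    if (!is.null(x)) {
      dup <- which(duplicated(x$clone_id))
      for (i in dup) {
        failures <- add_failure(failures, paths$records, i + 1L,
          paste0("duplicate clone_id '", x$clone_id[i], "'"))
      }
      resp <- parse_int_field(x$responses)
      for (i in seq_len(nrow(x))) {
        r <- resp[[i]]
        if (length(r) == 0 || anyNA(r) || any(r < 0) || any(r > x$touches[i])) {
          failures <- add_failure(failures, paths$records, i + 1L,
            "responses outside [0, touches] or unparseable")
        }
        fl <- parse_flag_field(x$flags[i])[[1]]
        bad <- setdiff(fl, TOXICITY_FLAGS)
        if (length(bad) > 0) {
          failures <- add_failure(failures, paths$records, i + 1L,
            paste0("unknown flag(s): ", paste(bad, collapse = ",")))
        }
      }
    }
  }
  if (!is.null(paths$baselines)) {
    x <- try_read(paths$baselines, c("batch", "mean_percent", "sd_percent"))
    if (!is.null(x)) {
      for (i in seq_len(nrow(x))) {
        if (is.na(x$mean_percent[i]) || x$mean_percent[i] <= 0 || x$mean_percent[i] > 100) {
          failures <- add_failure(failures, paths$baselines, i + 1L,
            "mean_percent outside (0, 100]")
        }
        if (is.na(x$sd_percent[i]) || x$sd_percent[i] < 0) {
          failures <- add_failure(failures, paths$baselines, i + 1L, "sd_percent < 0")
        }
      }
    }
  }
  if (!is.null(paths$network)) {
    x <- try_read(paths$network, c("gene_a", "gene_b", "weight"))
    if (!is.null(x)) {
      key <- paste(pmin(x$gene_a, x$gene_b), pmax(x$gene_a, x$gene_b))
      for (i in seq_len(nrow(x))) {
        if (is.na(x$weight[i]) || x$weight[i] < 0) {
          failures <- add_failure(failures, paths$network, i + 1L, "negative or missing weight")
        }
        if (x$gene_a[i] == x$gene_b[i]) {
          failures <- add_failure(failures, paths$network, i + 1L, "self-loop")
        }
        if (i > 1 && key[i] %in% key[seq_len(i - 1)]) {
          failures <- add_failure(failures, paths$network, i + 1L, "duplicate edge")
        }
      }
    }
  }
  for (nm in c("mouse_a", "mouse_b")) {
    if (!is.null(paths[[nm]])) {
      x <- try_read(paths[[nm]], c("mouse_gene", "direction"))
      if (!is.null(x)) {
        for (i in seq_len(nrow(x))) {
          if (!x$direction[i] %in% c("up", "down")) {
            failures <- add_failure(failures, paths[[nm]], i + 1L,
              paste0("invalid direction '", x$direction[i], "'"))
          }
        }
        dirs <- tapply(x$direction, x$mouse_gene, function(d) length(unique(d)))
        for (g in names(dirs)[dirs > 1]) {
          failures <- add_failure(failures, paths[[nm]], NA_integer_,
            paste0("conflicting directions for gene '", g, "'"))
        }
      }
    }
  }
  if (!is.null(paths$orthologs)) {
    x <- try_read(paths$orthologs, c("worm_gene", "mouse_gene"))
    if (!is.null(x)) {
      for (i in seq_len(nrow(x))) {
        if (!nzchar(x$worm_gene[i]) || !nzchar(x$mouse_gene[i])) {
          failures <- add_failure(failures, paths$orthologs, i + 1L, "empty identifier")
        }
      }
    }
  }
  failures
}
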