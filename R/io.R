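# TSV readers and writers for the pipeline's file formats (UTF-8,
# tab-separated, '#' comment lines, no quoting).

read_tsv_plain <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.table(path,
    header = TRUE, sep = "\t", quote = "", comment.char = "#",
    stringsAsFactors = FALSE, check.names = FALSE, colClasses = NA
  )
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing) > 0) {
      stop(path, ": missing column(s) ", paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
  }
  x
}

format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(signif(x, 6), format = "g", digits = 6))
}

write_tsv_plain <- function(x, path) {
  num <- vapply(x, is.double, logical(1))
  x[num] <- lapply(x[num], format_num)
  utils::write.table(x, path,
    sep = "\t", quote = FALSE, row.names = FALSE, na = "NA"
  )
  invisible(path)
}

#' Read screen records from TSV
#'
#' Expected columns: `clone_id`, `gene_id`, `batch`, `touches`, `responses`
#' (semicolon-separated per-animal response counts), `flags`
#' (comma-separated toxicity flags, empty for none).
#'
#' @param path File path.
#' @return Data frame suitable for [score_screen()].
#' @export
read_screen_records <- function(path) {
  x <- read_tsv_plain(path,
    required = c("clone_id", "gene_id", "batch", "touches", "responses", "flags")
  )
  x$flags <- as.character(x$flags)
  x$flags[is.na(x$flags)] <- ""
  x
}

#' Read a baseline table from TSV
#'
#' Columns: `batch`, `mean_percent`, `sd_percent`; a `"cumulated"` batch row
#' acts as the fallback baseline.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_baselines <- function(path) {
  read_tsv_plain(path, required = c("batch", "mean_percent", "sd_percent"))
}

#' Write an S-score table to TSV
#'
#' One row per clone, stable column order, floats at 6 significant digits.
#'
#' @param table S-score table from [score_screen()].
#' @param path File path.
#' @export
write_sscore_table <- function(table, path) {
  cols <- c(
    "clone_id", "gene_id", "batch", "n_animals", "percent_response",
    "sd_percent", "s", "s_sd", "hit_class", "excluded", "exclude_reason"
  )
  write_tsv_plain(as.data.frame(table)[, cols], path)
}

#' Read an S-score table written by [write_sscore_table()]
#' @param path File path.
#' @return S-score table data frame.
#' @export
read_sscore_table <- function(path) {
  x <- read_tsv_plain(path, required = c("clone_id", "gene_id", "s", "hit_class", "excluded"))
  class(x) <- c("sscore_table", "data.frame")
  x
}

#' Read a gene network edge list from TSV
#'
#' Three columns `gene_a`, `gene_b`, `weight` (header required); `#` lines
#' are comments.
#'
#' @param path File path.
#' @param nodes Optional extra isolated nodes.
#' @return A [gene_network()] graph.
#' @export
read_gene_network <- function(path, nodes = NULL) {
  x <- read_tsv_plain(path, required = c("gene_a", "gene_b", "weight"))
  gene_network(x, nodes = nodes)
}

#' Write a gene network edge list to TSV
#' @param network A [gene_network()] graph.
#' @param path File path.
#' @export
write_gene_network <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  out <- data.frame(
    gene_a = pmin(el[, 1], el[, 2]), gene_b = pmax(el[, 1], el[, 2]),
    weight = w, stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  write_tsv_plain(out, path)
}

#' Read a gene -> S signal from two-column TSV (`gene`, `s`)
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_signal <- function(path) {
  x <- read_tsv_plain(path, required = c("gene", "s"))
  stats::setNames(as.numeric(x$s), as.character(x$gene))
}

#' Write an attenuation series to wide TSV (`gene`, `level_0..level_n`)
#' @param series An [attenuation_series()].
#' @param path File path.
#' @export
write_attenuation_series <- function(series, path) {
  out <- data.frame(gene = rownames(series), as.data.frame(unclass(series)),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  write_tsv_plain(out, path)
}

#' Read gene sets from a GMT-style TSV (term, description, genes...)
#' @param path File path.
#' @return Named list term -> gene character vector.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop(path, ": GMT lines need term, description, >=1 gene", call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(names(sets))) stop(path, ": duplicate terms", call. = FALSE)
  sets
}

#' Read gene sets from a two-column gene-term TSV (`gene`, `term`)
#' @param path File path.
#' @return Named list term -> gene character vector.
#' @export
read_gene_term <- function(path) {
  x <- read_tsv_plain(path, required = c("gene", "term"))
  split(as.character(x$gene), as.character(x$term))
}

#' Read an ontology subset from an OBO file (`id` and `is_a` tags only)
#' @param path File path.
#' @return Named list term -> character vector of parents (for
#'   [propagate_ontology()]).
#' @export
read_obo_subset <- function(path) {
  lines <- readLines(path, warn = FALSE)
  parents <- list()
  current <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      current <- NULL
    } else if (startsWith(ln, "id:")) {
      current <- trimws(sub("^id:", "", ln))
      if (is.null(parents[[current]])) parents[[current]] <- character(0)
    } else if (startsWith(ln, "is_a:") && !is.null(current)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      parents[[current]] <- union(parents[[current]], p)
    }
  }
  parents
}

#' Read an ortholog map from TSV (`worm_gene`, `mouse_gene`, `cluster_id`)
#' @param path File path.
#' @return Data frame.
#' @export
read_ortholog_map <- function(path) {
  x <- read_tsv_plain(path, required = c("worm_gene", "mouse_gene"))
  if (any(!nzchar(x$worm_gene)) || any(!nzchar(x$mouse_gene))) {
    stop(path, ": empty gene identifiers", call. = FALSE)
  }
  x
}

#' Read a dysregulation table from TSV (`mouse_gene`, `direction`,
#' `model_label`)
#' @param path File path.
#' @return Data frame.
#' @export
read_dysregulation <- function(path) {
  read_tsv_plain(path, required = c("mouse_gene", "direction"))
}

#' Canonicalise dual "SEQID/name" gene identifiers
#'
#' Splits identifiers like `"B0478.1/jnk-1"` on `/`, keeping the first
#' (sequence-name) token as canonical.
#'
#' @param ids Character vector of gene identifiers.
#' @return Character vector of canonical identifiers.
#' @export
canonical_gene_id <- function(ids) {
  vapply(strsplit(as.character(ids), "/", fixed = TRUE), `[`, character(1), 1)
}
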