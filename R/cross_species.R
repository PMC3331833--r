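# Cross-species stage: map worm modifier genes to mouse orthologs and
# intersect with striatal dysregulation tables from two HD mouse models.

#' Map worm modifier genes to mouse orthologs
#'
#' Every worm modifier with at least one ortholog contributes all of its
#' mouse genes (many-to-many expansion), each record carrying the worm hit
#' class; worm modifiers without orthologs are counted and reported via a
#' message.
#'
#' @param modifiers Data frame `gene_id`, `hit_class` (e.g. from
#'   [modifier_genes()]).
#' @param orthologs Data frame `worm_gene`, `mouse_gene` (an optional
#'   `cluster_id` column is carried through).
#' @return Data frame `mouse_gene`, `worm_gene`, `hit_class`.
#' @export
conserved_modifiers <- function(modifiers, orthologs) {
  m <- merge(
    data.frame(
      worm_gene = as.character(modifiers$gene_id),
      hit_class = as.character(modifiers$hit_class),
      stringsAsFactors = FALSE
    ),
    orthologs,
    by = "worm_gene"
  )
  unmapped <- setdiff(modifiers$gene_id, orthologs$worm_gene)
  if (length(unmapped) > 0) {
    message(length(unmapped), " modifier gene(s) without mouse orthologs")
  }
  out <- m[order(m$mouse_gene, m$worm_gene), c("mouse_gene", "worm_gene", "hit_class")]
  rownames(out) <- NULL
  out
}

check_dysregulation <- function(table, label) {
  if (!all(c("mouse_gene", "direction") %in% names(table))) {
    stop(label, ": needs columns mouse_gene, direction", call. = FALSE)
  }
  bad <- setdiff(unique(table$direction), c("up", "down"))
  if (length(bad) > 0) {
    stop(label, ": direction must be 'up' or 'down', got: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  dirs <- tapply(table$direction, table$mouse_gene, function(d) length(unique(d)))
  if (any(dirs > 1)) {
    stop(label, ": conflicting directions for gene(s): ",
      paste(names(dirs)[dirs > 1], collapse = ", "),
      call. = FALSE
    )
  }
  invisible(TRUE)
}

#' Intersect conserved modifiers with two dysregulation tables
#'
#' Per mouse gene: membership in each model's dysregulated set, the
#' directions, and an `opposite` flag set when the gene appears in both
#' models with different directions. Orthology is resolved at the mouse-gene
#' level: a mouse gene is counted once however many worm genes map to it
#' (worm hit classes are collapsed; disagreeing classes become `"mixed"`).
#'
#' @param conserved Output of [conserved_modifiers()].
#' @param table_a,table_b Data frames `mouse_gene`, `direction`
#'   (`"up"`/`"down"`); duplicate genes with conflicting directions within
#'   one table raise an error.
#' @param label_a,label_b Model labels for the report (defaults `"A"`,
#'   `"B"`).
#' @return A list of class `dysregulation_overlap` with `report` (one row per
#'   conserved mouse gene dysregulated in at least one model) and `counts`
#'   (`in_A_only`, `in_B_only`, `in_both_concordant`, `in_both_opposite`,
#'   `total`).
#' @export
intersect_dysregulation <- function(conserved, table_a, table_b,
                                    label_a = "A", label_b = "B") {
  check_dysregulation(table_a, label_a)
  check_dysregulation(table_b, label_b)
  genes <- sort(unique(conserved$mouse_gene))
  hit <- vapply(genes, function(g) {
    h <- unique(conserved$hit_class[conserved$mouse_gene == g])
    if (length(h) == 1) h else "mixed"
  }, character(1))
  dir_a <- table_a$direction[match(genes, table_a$mouse_gene)]
  dir_b <- table_b$direction[match(genes, table_b$mouse_gene)]
  in_a <- !is.na(dir_a)
  in_b <- !is.na(dir_b)
  report <- data.frame(
    mouse_gene = genes, hit_class = hit,
    in_a = in_a, in_b = in_b,
    direction_a = dir_a, direction_b = dir_b,
    opposite = in_a & in_b & dir_a != dir_b,
    stringsAsFactors = FALSE
  )
  report <- report[report$in_a | report$in_b, , drop = FALSE]
  rownames(report) <- NULL
  counts <- c(
    in_A_only = sum(report$in_a & !report$in_b),
    in_B_only = sum(report$in_b & !report$in_a),
    in_both_concordant = sum(report$in_a & report$in_b & !report$opposite),
    in_both_opposite = sum(report$opposite),
    total = nrow(report)
  )
  structure(
    list(report = report, counts = counts, labels = c(label_a, label_b)),
    class = "dysregulation_overlap"
  )
}

#' @export
print.dysregulation_overlap <- function(x, ...) {
  cat(sprintf(
    "<dysregulation_overlap> %s vs %s: %d genes (%d %s only, %d %s only, %d concordant, %d opposite)\n",
    x$labels[1], x$labels[2], x$counts["total"],
    x$counts["in_A_only"], x$labels[1], x$counts["in_B_only"], x$labels[2],
    x$counts["in_both_concordant"], x$counts["in_both_opposite"]
  ))
  invisible(x)
}

#' Prioritise candidate intervention targets from the overlap report
#'
#' The default rule (`"suppressor_up"`) flags genes whose RNAi knockdown
#' suppresses neuron dysfunction in the worm AND that are up-regulated in at
#' least one mouse model: inhibiting such genes is a candidate
#' neuroprotective strategy. Genes up in both models rank before genes up in
#' one, alphabetical within rank. The rule is purely data-driven.
#'
#' @param overlap A `dysregulation_overlap` from [intersect_dysregulation()].
#' @param rule Rule label; only `"suppressor_up"` is defined.
#' @return Data frame `mouse_gene`, `hit_class`, `direction_a`,
#'   `direction_b`, `n_models_up`, ranked.
#' @export
prioritize <- function(overlap, rule = "suppressor_up") {
  if (!identical(rule, "suppressor_up")) {
    stop("unknown prioritisation rule: ", rule, call. = FALSE)
  }
  r <- overlap$report
  up_a <- r$in_a & r$direction_a == "up"
  up_b <- r$in_b & r$direction_b == "up"
  sel <- r$hit_class == "suppressor" & (up_a | up_b)
  out <- r[sel, c("mouse_gene", "hit_class", "direction_a", "direction_b"), drop = FALSE]
  out$n_models_up <- (up_a + up_b)[sel]
  out <- out[order(-out$n_models_up, out$mouse_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
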