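# Touch-response scoring: per-clone responsiveness, S-scores and hit calls.

#' Toxicity phenotype flags, in canonical (exclusion-reason) order
#'
#' RNAi clones producing any of these developmental/morphological phenotypes
#' are excluded from touch-response scoring; the first matching flag in this
#' order is reported as the exclusion reason.
#'
#' @format Character vector of the six recognised flags.
#' @export
TOXICITY_FLAGS <- c(
  "lethality", "larval_arrest", "egg_laying_defect", "developmental_delay",
  "morphological_abnormality", "other_abnormality"
)

#' Percent touch responsiveness
#'
#' Converts a response count (touches the animal backed away from) into a
#' responsiveness percentage: 4 responses out of 5 touches is 80%.
#'
#' @param responses Integer vector of response counts, each in `0..touches`.
#' @param touches Number of touches applied per animal (default 5).
#' @return Numeric vector, `100 * responses / touches`.
#' @export
#' @examples
#' percent_responsiveness(4, 5) # 80
percent_responsiveness <- function(responses, touches = 5L) {
  if (any(touches < 1)) stop("`touches` must be >= 1", call. = FALSE)
  if (any(responses < 0 | responses > touches)) {
    stop("`responses` must lie in [0, touches]", call. = FALSE)
  }
  100 * responses / touches
}

#' S-score for change in touch response
#'
#' The screen's score for change in touch response relative to the
#' empty-vector baseline: `S = (percent_response - baseline_mean) /
#' baseline_mean`. S = -1 corresponds to complete loss of touch response and
#' S = 0 to responsiveness equal to the baseline mean; positive S means the
#' RNAi clone improved the touch response (suppressor sense), negative S that
#' it worsened it (enhancer sense).
#'
#' @param percent_response Responsiveness percentage(s), in \[0, 100\].
#' @param baseline_mean Baseline responsiveness percentage (> 0).
#' @return Numeric vector of S-scores, bounded below by -1.
#' @export
#' @examples
#' s_score(0, 20.6)    # -1: complete loss of touch response
#' s_score(20.6, 20.6) #  0: at baseline
s_score <- function(percent_response, baseline_mean) {
  if (any(baseline_mean <= 0)) {
    stop("`baseline_mean` must be > 0", call. = FALSE)
  }
  if (any(percent_response < 0 | percent_response > 100)) {
    stop("`percent_response` must lie in [0, 100]", call. = FALSE)
  }
  (percent_response - baseline_mean) / baseline_mean
}

#' Call a clone as suppressor, enhancer or no-effect
#'
#' A clone is a positive hit when the interval `s_mean +/- s_sd` lies entirely
#' outside the baseline band `+/- multiplier * baseline_sd_s` (the baseline is
#' 0 on the S scale by construction). Suppressors clear the band upward,
#' enhancers downward; a clone exactly at the band edge is `no_effect`
#' (strict inequality).
#'
#' @param s_mean Mean S-score of the clone.
#' @param s_sd SD of per-animal S values for the clone (>= 0).
#' @param baseline_sd_s Baseline SD expressed on the S scale, i.e.
#'   `sd_percent / mean_percent` (>= 0).
#' @param multiplier Width of the baseline band in baseline SDs (default 2.6).
#' @return Character vector in `{"suppressor", "enhancer", "no_effect"}`.
#' @export
call_hit <- function(s_mean, s_sd, baseline_sd_s, multiplier = 2.6) {
  if (any(s_sd < 0)) stop("`s_sd` must be >= 0", call. = FALSE)
  if (any(baseline_sd_s < 0)) stop("`baseline_sd_s` must be >= 0", call. = FALSE)
  band <- multiplier * baseline_sd_s
  ifelse(s_mean - s_sd > band, "suppressor",
    ifelse(s_mean + s_sd < -band, "enhancer", "no_effect")
  )
}

#' Classify a clone's toxicity phenotype flags
#'
#' @param flags Character vector of phenotype flags for one clone (possibly
#'   empty); every flag must be one of [TOXICITY_FLAGS].
#' @return A list with `excluded` (logical) and `reason` (the first flag in
#'   canonical order, or `NA` if included).
#' @export
classify_toxicity <- function(flags) {
  flags <- flags[!is.na(flags) & nzchar(flags)]
  unknown <- setdiff(flags, TOXICITY_FLAGS)
  if (length(unknown) > 0) {
    stop(
      "unknown phenotype flag(s): ", paste(unknown, collapse = ", "),
      "; allowed: ", paste(TOXICITY_FLAGS, collapse = ", "),
      call. = FALSE
    )
  }
  if (length(flags) == 0) {
    list(excluded = FALSE, reason = NA_character_)
  } else {
    list(excluded = TRUE, reason = TOXICITY_FLAGS[min(match(flags, TOXICITY_FLAGS))])
  }
}

parse_int_field <- function(x, sep = ";") {
  if (is.list(x)) {
    lapply(x, as.integer)
  } else {
    lapply(strsplit(as.character(x), sep, fixed = TRUE), as.integer)
  }
}

parse_flag_field <- function(x, sep = ",") {
  if (is.list(x)) {
    lapply(x, function(f) as.character(f[!is.na(f) & nzchar(f)]))
  } else {
    x <- as.character(x)
    x[is.na(x)] <- ""
    lapply(strsplit(x, sep, fixed = TRUE), function(f) f[nzchar(f)])
  }
}

lookup_baseline <- function(baselines, batch) {
  i <- match(batch, baselines$batch)
  if (is.na(i)) i <- match("cumulated", baselines$batch)
  if (is.na(i)) {
    stop(
      "no baseline for batch '", batch, "' and no 'cumulated' fallback",
      call. = FALSE
    )
  }
  baselines[i, , drop = FALSE]
}

#' Score a set of screen records
#'
#' Converts raw per-clone touch-test records into an S-score table. Clones
#' with any toxicity phenotype flag are excluded (no hit class, no S); the
#' remainder are scored against their batch baseline (falling back to the
#' `"cumulated"` baseline when the batch has none). The per-clone S SD is the
#' SD of per-animal S values, equivalently the SD of per-animal percents
#' divided by the baseline mean.
#'
#' @param records Data frame with columns `clone_id`, `gene_id`, `batch`,
#'   `touches`, `responses` (semicolon-separated integers or a list column),
#'   `flags` (comma-separated flags or a list column; empty = none).
#' @param baselines Data frame with columns `batch`, `mean_percent`,
#'   `sd_percent`; a row with batch `"cumulated"` acts as fallback.
#' @param multiplier Hit-calling band width in baseline SDs (default 2.6).
#' @return A data frame (one row per clone) with columns `clone_id`,
#'   `gene_id`, `batch`, `n_animals`, `percent_response`, `sd_percent`, `s`,
#'   `s_sd`, `hit_class`, `excluded`, `exclude_reason`.
#' @export
score_screen <- function(records, baselines, multiplier = 2.6) {
  required <- c("clone_id", "gene_id", "batch", "touches", "responses", "flags")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  responses <- parse_int_field(records$responses)
  flags <- parse_flag_field(records$flags)
  n <- nrow(records)
  out <- data.frame(
    clone_id = as.character(records$clone_id),
    gene_id = as.character(records$gene_id),
    batch = as.character(records$batch),
    n_animals = vapply(responses, length, integer(1)),
    percent_response = NA_real_, sd_percent = NA_real_,
    s = NA_real_, s_sd = NA_real_,
    hit_class = NA_character_,
    excluded = FALSE, exclude_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    tox <- classify_toxicity(flags[[i]])
    if (tox$excluded) {
      out$excluded[i] <- TRUE
      out$exclude_reason[i] <- tox$reason
      next
    }
    resp <- responses[[i]]
    if (length(resp) < 1) stop("clone ", out$clone_id[i], ": no animals", call. = FALSE)
    pct <- percent_responsiveness(resp, records$touches[i])
    b <- lookup_baseline(baselines, out$batch[i])
    out$percent_response[i] <- mean(pct)
    out$sd_percent[i] <- if (length(pct) > 1) stats::sd(pct) else 0
    out$s[i] <- s_score(mean(pct), b$mean_percent)
    out$s_sd[i] <- out$sd_percent[i] / b$mean_percent
    out$hit_class[i] <- call_hit(
      out$s[i], out$s_sd[i], b$sd_percent / b$mean_percent, multiplier
    )
  }
  class(out) <- c("sscore_table", "data.frame")
  out
}

#' Summarise an S-score table at clone and gene level
#'
#' Clone-level counts partition the table into toxic (excluded), no-effect,
#' suppressor and enhancer clones. Gene-level counts deduplicate clones
#' targeting the same gene: a gene is a modifier if any of its clones is; a
#' gene whose clones disagree in sign is counted as `mixed` (still a
#' modifier); a gene is toxic only if all its clones were excluded.
#'
#' @param table An S-score table from [score_screen()].
#' @return A list with elements `clone` and `gene`, each a named integer
#'   vector with entries `toxic`, `no_effect`, `suppressor`, `enhancer`,
#'   (`mixed` at gene level), `total_modifiers`, `total`.
#' @export
screen_summary <- function(table) {
  cl <- table$hit_class
  clone <- c(
    toxic = sum(table$excluded),
    no_effect = sum(!table$excluded & cl == "no_effect", na.rm = TRUE),
    suppressor = sum(!table$excluded & cl == "suppressor", na.rm = TRUE),
    enhancer = sum(!table$excluded & cl == "enhancer", na.rm = TRUE)
  )
  clone <- c(clone,
    total_modifiers = unname(clone["suppressor"] + clone["enhancer"]),
    total = nrow(table)
  )
  genes <- unique(table$gene_id)
  gene_class <- vapply(genes, function(g) {
    rows <- table[table$gene_id == g, ]
    if (all(rows$excluded)) return("toxic")
    cls <- rows$hit_class[!rows$excluded]
    has_s <- any(cls == "suppressor")
    has_e <- any(cls == "enhancer")
    if (has_s && has_e) "mixed" else if (has_s) "suppressor" else if (has_e) "enhancer" else "no_effect"
  }, character(1))
  gene <- c(
    toxic = sum(gene_class == "toxic"),
    no_effect = sum(gene_class == "no_effect"),
    suppressor = sum(gene_class == "suppressor"),
    enhancer = sum(gene_class == "enhancer"),
    mixed = sum(gene_class == "mixed")
  )
  gene <- c(gene,
    total_modifiers = unname(gene["suppressor"] + gene["enhancer"] + gene["mixed"]),
    total = length(genes)
  )
  list(clone = clone, gene = gene)
}

#' Confirm primary hits against a secondary screen
#'
#' A clone is confirmed when it is called a modifier with the same sign
#' (suppressor/enhancer) in both the primary and the secondary S-score table.
#'
#' @param primary,secondary S-score tables from [score_screen()] sharing
#'   clone identifiers.
#' @return The primary table restricted to its modifier clones, with a
#'   logical `confirmed` column.
#' @export
confirm_hits <- function(primary, secondary) {
  hits <- primary[!primary$excluded &
    primary$hit_class %in% c("suppressor", "enhancer"), , drop = FALSE]
  j <- match(hits$clone_id, secondary$clone_id)
  sec_class <- secondary$hit_class[j]
  hits$confirmed <- !is.na(sec_class) & sec_class == hits$hit_class
  hits
}

#' Extract modifier genes (with hit class) from an S-score table
#'
#' @param table An S-score table.
#' @return Data frame `gene_id`, `hit_class` with one row per modifier gene
#'   (gene-level deduplication as in [screen_summary()]; mixed-sign genes are
#'   reported with class `"mixed"`).
#' @export
modifier_genes <- function(table) {
  scored <- table[!table$excluded, , drop = FALSE]
  genes <- unique(scored$gene_id)
  cls <- vapply(genes, function(g) {
    h <- scored$hit_class[scored$gene_id == g]
    has_s <- any(h == "suppressor")
    has_e <- any(h == "enhancer")
    if (has_s && has_e) "mixed" else if (has_s) "suppressor" else if (has_e) "enhancer" else "no_effect"
  }, character(1))
  keep <- cls != "no_effect"
  data.frame(
    gene_id = genes[keep], hit_class = unname(cls[keep]),
    stringsAsFactors = FALSE
  )
}
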