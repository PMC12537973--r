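# Core differential-dependency screen: per-gene statistics, top-K selection,
# dual essentiality-threshold filter, and the orchestrating run_screen().

#' Selection configuration for the vulnerability screen
#'
#' @param top_k number of most significant negative-shift genes carried into
#'   enrichment (default 200).
#' @param essential_threshold score threshold separating "essential" from
#'   "non-essential" medians (default -0.5, the conventional Chronos
#'   complete-essentiality cutoff). The filter keeps genes with target-group
#'   median strictly below it and background median strictly above it.
#' @param require_negative_diff restrict top-K selection to genes whose
#'   median difference (target - background) is strictly negative.
#' @param min_group_size minimum non-missing scores per group for a gene to
#'   receive statistics (default 3); genes under it are reported with `NA`
#'   statistics and excluded downstream.
#' @return a `selection_config` list.
#' @export
selection_config <- function(top_k = 200, essential_threshold = -0.5,
                             require_negative_diff = TRUE,
                             min_group_size = 3) {
  stopifnot(top_k >= 1, is.finite(essential_threshold), min_group_size >= 2)
  structure(list(top_k = as.integer(top_k),
                 essential_threshold = essential_threshold,
                 require_negative_diff = isTRUE(require_negative_diff),
                 min_group_size = as.integer(min_group_size)),
            class = "selection_config")
}

#' Per-gene differential dependency statistics
#'
#' For every gene, compares the dependency scores of the target cell lines
#' against the background lines: group medians (even-sized median = mean of
#' the two central order statistics), their difference
#' (target - background), and a two-sided two-sample t test (Welch by
#' default) with `-log10(p)` for volcano plotting. Missing scores are
#' dropped per gene; genes with fewer than `min_group_size` usable values in
#' either group are reported with `NA` statistics.
#'
#' Degenerate contract: when both groups have zero variance and equal means
#' the gene gets `t = 0, p = 1`; p-values underflowing to zero are floored
#' at the smallest positive double before taking `-log10`.
#'
#' @param dep a [dependency_matrix()].
#' @param grouping a [cell_grouping()]; cell lines absent from the matrix
#'   are ignored (both groups must stay non-empty).
#' @param min_group_size see [selection_config()].
#' @param var_equal use the pooled-variance Student form instead of Welch.
#' @return data.frame with one row per gene: `gene`, `median_target`,
#'   `median_background`, `median_diff`, `t_stat`, `p_value`,
#'   `neg_log10_p`, `n_target_used`, `n_background_used`.
#' @export
compute_gene_stats <- function(dep, grouping, min_group_size = 3,
                               var_equal = FALSE) {
  stopifnot(inherits(dep, "dep_matrix"), inherits(grouping, "cell_grouping"))
  tcols <- intersect(grouping$target, dep$cell_lines)
  bcols <- intersect(grouping$background, dep$cell_lines)
  if (!length(tcols)) stop("no target cell line present in the matrix")
  if (!length(bcols)) stop("no background cell line present in the matrix")
  tm <- dep$scores[, tcols, drop = FALSE]
  bm <- dep$scores[, bcols, drop = FALSE]
  ng <- length(dep$genes)
  out <- data.frame(gene = dep$genes,
                    median_target = NA_real_, median_background = NA_real_,
                    median_diff = NA_real_, t_stat = NA_real_,
                    p_value = NA_real_, neg_log10_p = NA_real_,
                    n_target_used = NA_integer_,
                    n_background_used = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ng)) {
    x <- tm[i, ]; x <- x[!is.na(x)]
    y <- bm[i, ]; y <- y[!is.na(y)]
    out$n_target_used[i] <- length(x)
    out$n_background_used[i] <- length(y)
    if (length(x) < min_group_size || length(y) < min_group_size) next
    out$median_target[i] <- stats::median(x)
    out$median_background[i] <- stats::median(y)
    out$median_diff[i] <- out$median_target[i] - out$median_background[i]
    tt <- welch_t(x, y, var_equal = var_equal)
    out$t_stat[i] <- tt$t_stat
    out$p_value[i] <- tt$p_value
    out$neg_log10_p[i] <- neg_log10(tt$p_value)
  }
  out
}

# Deterministic ordering used everywhere a "most significant first" list is
# produced: p ascending, ties broken by more-negative median difference,
# then lexicographic gene symbol.
order_by_significance <- function(stats) {
  order(stats$p_value, stats$median_diff, stats$gene)
}

#' Select the top-K most significant candidate genes
#'
#' Restricts to genes with a strictly negative median difference (stronger
#' dependency in the target entity) when `require_negative_diff` is set,
#' sorts by p-value ascending with deterministic tie-breaking
#' (more-negative median difference first, then gene symbol), and returns
#' the first `top_k` gene symbols (all eligible genes if fewer). Genes with
#' `NA` statistics are never eligible.
#'
#' @param stats output of [compute_gene_stats()].
#' @param cfg a [selection_config()].
#' @return character vector of gene symbols (possibly empty).
#' @export
select_top_candidates <- function(stats, cfg = selection_config()) {
  if (!nrow(stats)) stop("empty statistics table")
  eligible <- !is.na(stats$p_value)
  if (cfg$require_negative_diff)
    eligible <- eligible & !is.na(stats$median_diff) & stats$median_diff < 0
  s <- stats[eligible, , drop = FALSE]
  s <- s[order_by_significance(s), , drop = FALSE]
  utils::head(s$gene, cfg$top_k)
}

#' Dual essentiality-threshold filter with final ranking
#'
#' Keeps genes that look completely essential in the target entity but not
#' in the background: target-group median strictly below
#' `essential_threshold` AND background median strictly above it (a gene
#' sitting exactly at the threshold in either group is excluded). Survivors
#' are ranked by p-value ascending with the same deterministic tie-break as
#' [select_top_candidates()].
#'
#' @param genes character vector of candidate gene symbols; every one must
#'   be present in `stats`.
#' @param stats output of [compute_gene_stats()].
#' @param cfg a [selection_config()].
#' @return `candidate_table` data.frame: `rank`, `gene`, `median_target`,
#'   `median_background`, `median_diff`, `p_value`.
#' @export
essentiality_filter <- function(genes, stats, cfg = selection_config()) {
  unknown <- setdiff(genes, stats$gene)
  if (length(unknown))
    stop("gene(s) absent from statistics table: ",
         paste(unknown, collapse = ", "))
  s <- stats[match(genes, stats$gene), , drop = FALSE]
  thr <- cfg$essential_threshold
  keep <- !is.na(s$median_target) & !is.na(s$median_background) &
    s$median_target < thr & s$median_background > thr
  s <- s[keep, , drop = FALSE]
  s <- s[order_by_significance(s), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(s)), gene = s$gene,
                    median_target = s$median_target,
                    median_background = s$median_background,
                    median_diff = s$median_diff, p_value = s$p_value,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("candidate_table", "data.frame")
  out
}

#' Run the full vulnerability screen
#'
#' Executes the target-selection workflow end to end:
#' per-gene differential dependency statistics, top-K selection of the most
#' significant target-leaning genes, hypergeometric over-representation of
#' the top list against a gene-set collection, restriction to genes carried
#' by the enriched sets, and the dual essentiality-threshold filter with
#' final significance ranking. Per-stage surviving gene counts are recorded
#' (the Venn numbers of the workflow).
#'
#' When `gene_sets` is `NULL` or empty the enrichment stage is skipped and
#' the filter is applied to the top-K list directly.
#'
#' @param dep a [dependency_matrix()].
#' @param grouping a [cell_grouping()].
#' @param gene_sets a `gene_set_collection` (from [read_gmt()] or
#'   [gen_gene_sets()]), or `NULL`.
#' @param cfg a [selection_config()].
#' @param alpha BH-adjusted significance cutoff calling a set enriched
#'   (default 0.05).
#' @param universe `"tested"` (default) uses the genes that actually
#'   received statistics as the ORA universe, matching the screen's sampling
#'   frame; `"gmt"` uses the union of all set members.
#' @param var_equal passed to [compute_gene_stats()].
#' @return a `screen_report`: list with `gene_stats`, `top_candidates`,
#'   `enrichment`, `pathway_genes`, `candidates` (the final ranked
#'   `candidate_table`), `stage_counts`, and `config`.
#' @export
run_screen <- function(dep, grouping, gene_sets = NULL,
                       cfg = selection_config(), alpha = 0.05,
                       universe = c("tested", "gmt"), var_equal = FALSE) {
  universe <- match.arg(universe)
  stats <- compute_gene_stats(dep, grouping,
                              min_group_size = cfg$min_group_size,
                              var_equal = var_equal)
  tested <- stats$gene[!is.na(stats$p_value)]
  top <- select_top_candidates(stats, cfg)

  enr <- NULL
  pathway_genes <- top
  have_sets <- !is.null(gene_sets) && length(gene_sets) > 0
  if (have_sets && length(top)) {
    uni <- if (universe == "tested") tested else
      unique(unlist(lapply(gene_sets, `[[`, "genes"), use.names = FALSE))
    enr <- ora(top, gene_sets, universe = uni, alpha = alpha)
    pathway_genes <- member_overlap(enr, top, alpha = alpha)
  }
  candidates <- essentiality_filter(pathway_genes, stats, cfg)

  stage_counts <- data.frame(
    stage = c("tested", "top_candidates", "in_enriched_sets", "final"),
    n = c(length(tested), length(top), length(pathway_genes),
          nrow(candidates)),
    stringsAsFactors = FALSE)

  structure(list(gene_stats = stats, top_candidates = top, enrichment = enr,
                 pathway_genes = pathway_genes, candidates = candidates,
                 stage_counts = stage_counts, config = cfg, alpha = alpha),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Entity-specific vulnerability screen\n")
  sc <- x$stage_counts
  for (i in seq_len(nrow(sc)))
    cat(sprintf("  %-18s %d\n", sc$stage[i], sc$n[i]))
  if (nrow(x$candidates)) {
    cat("Top candidates:\n")
    print(utils::head(x$candidates, 5))
  } else cat("No gene survived the essentiality filter.\n")
  invisible(x)
}

#' @export
summary.screen_report <- function(object, ...) {
  n_enr <- if (is.null(object$enrichment)) 0L else
    sum(object$enrichment$adjusted_p < object$alpha)
  out <- list(stage_counts = object$stage_counts,
              n_enriched_sets = n_enr,
              candidates = object$candidates)
  class(out) <- "summary.screen_report"
  out
}

#' @export
print.summary.screen_report <- function(x, ...) {
  print(x$stage_counts)
  cat(sprintf("Enriched gene sets: %d\n", x$n_enriched_sets))
  print(x$candidates)
  invisible(x)
}

#' Write a screen report as a directory of TSV tables
#'
#' Emits `gene_stats.tsv`, `top_candidates.tsv`, `enrichment.tsv`,
#' `final_candidates.tsv` and `stage_counts.tsv` under `dir`.
#'
#' @param report a `screen_report` from [run_screen()].
#' @param dir output directory (created if absent).
#' @export
write_screen_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(report$gene_stats, file.path(dir, "gene_stats.tsv"))
  write_table(data.frame(gene = report$top_candidates),
              file.path(dir, "top_candidates.tsv"))
  enr <- report$enrichment
  if (is.null(enr))
    enr <- data.frame(set = character(), description = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p_value = numeric(),
                      adjusted_p = numeric(), overlap = character())
  write_table(enr, file.path(dir, "enrichment.tsv"))
  write_table(report$candidates, file.path(dir, "final_candidates.tsv"))
  write_table(report$stage_counts, file.path(dir, "stage_counts.tsv"))
  invisible(dir)
}
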