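# Median-based differential expression on count matrices, plus 2^(-ddCt)
# relative quantification for qPCR.

#' Median-based differential expression
#'
#' The statistic is deliberately simple: per gene, counts are transformed as
#' `log2(x + pseudocount)`, the log2 fold change is the difference of group
#' medians (knockdown - control, so a silenced gene comes out negative), and
#' significance comes from a two-sided unpaired t test (Welch) on the
#' transformed values at raw `p < alpha` — no multiple-testing cutoff is
#' applied to the significance flag, though a BH-adjusted column is emitted
#' for users who want one. No library-size normalization is applied by
#' default; `cpm = TRUE` pre-scales each sample to counts per million.
#'
#' Degenerate contract: a gene with identical transformed values in both
#' groups (e.g. all-zero counts) gets `log2fc = 0, p = 1`.
#'
#' @param expr an [expression_matrix()] of counts.
#' @param labels character/factor mapping each sample to `"control"` or
#'   `"knockdown"`; either named by sample or parallel to the columns.
#' @param pseudocount added before log2 (default 1).
#' @param alpha raw-p significance cutoff (default 0.05).
#' @param cpm scale samples to counts per million before the transform.
#' @return `deg_table` data.frame: `gene`, `log2fc`, `p_value`, `bh_p`,
#'   `neg_log10_p`, `significant`, `direction` (`up`/`down`/`ns`), with a
#'   `summary` attribute counting up/down/total significant genes.
#' @export
compute_deg <- function(expr, labels, pseudocount = 1, alpha = 0.05,
                        cpm = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$type != "counts") stop("compute_deg expects a counts matrix")
  labels <- as.character(labels)
  if (!is.null(names(labels))) {
    miss <- setdiff(expr$samples, names(labels))
    if (length(miss)) stop("no label for sample(s): ", paste(miss, collapse = ", "))
    labels <- labels[expr$samples]
  } else if (length(labels) != length(expr$samples)) {
    stop("`labels` must be named by sample or parallel to the columns")
  }
  if (!all(labels %in% c("control", "knockdown")))
    stop("labels must be 'control' or 'knockdown'")
  ctrl <- labels == "control"
  kd <- labels == "knockdown"
  if (sum(ctrl) < 2 || sum(kd) < 2)
    stop("each group needs at least 2 samples")

  vals <- expr$values
  if (cpm) vals <- sweep(vals, 2, colSums(vals) / 1e6, "/")
  lv <- log2(vals + pseudocount)

  ng <- nrow(lv)
  log2fc <- p <- numeric(ng)
  for (i in seq_len(ng)) {
    x <- lv[i, kd]; y <- lv[i, ctrl]
    log2fc[i] <- stats::median(x) - stats::median(y)
    p[i] <- welch_t(x, y)$p_value
  }
  sig <- p < alpha
  direction <- ifelse(!sig, "ns", ifelse(log2fc > 0, "up",
                                         ifelse(log2fc < 0, "down", "ns")))
  out <- data.frame(gene = expr$genes, log2fc = log2fc, p_value = p,
                    bh_p = stats::p.adjust(p, method = "BH"),
                    neg_log10_p = neg_log10(p),
                    significant = sig, direction = direction,
                    stringsAsFactors = FALSE)
  attr(out, "summary") <- c(up = sum(direction == "up"),
                            down = sum(direction == "down"),
                            total = sum(direction != "ns"))
  attr(out, "alpha") <- alpha
  class(out) <- c("deg_table", "data.frame")
  out
}

#' @export
print.deg_table <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("DEG table: %d genes; %d significant at p < %s (%d up, %d down)\n",
              nrow(x), s[["total"]], format(attr(x, "alpha")),
              s[["up"]], s[["down"]]))
  invisible(x)
}

#' Relative expression by the 2^(-ddCt) method
#'
#' Standard qPCR relative quantification: the target gene's Ct is normalized
#' to a reference gene (e.g. GAPDH) within both the sample of interest and
#' the control sample, and the fold change is `2^-((dCt_sample -
#' dCt_control))`. Vectorized over its arguments.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest.
#' @param ct_target_control,ct_ref_control same in the control sample.
#' @return fold change(s) relative to the control sample.
#' @export
relative_expression_ddct <- function(ct_target_sample, ct_ref_sample,
                                     ct_target_control, ct_ref_control) {
  args <- list(ct_target_sample, ct_ref_sample,
               ct_target_control, ct_ref_control)
  if (!all(vapply(args, function(a) all(is.finite(a)), logical(1))))
    stop("all Ct values must be finite")
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
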