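# Hypergeometric over-representation analysis (ORA) of a query gene list
# against a gene-set collection, with Benjamini-Hochberg correction.

#' Over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps it more than
#' expected under uniform sampling from the universe, via the exact
#' upper-tail hypergeometric probability P(X >= k) with N = universe size,
#' K = set size within the universe, n = query size within the universe and
#' k = overlap. Query and set members are intersected with the universe
#' before counting. P-values are BH-adjusted across all sets tested and the
#' result is sorted by p ascending.
#'
#' Sets smaller than `min_set_size` or larger than `max_set_frac * N`
#' (after universe intersection) are excluded, the usual ORA hygiene for
#' uninformative tiny or near-universal sets.
#'
#' @param query character vector of gene symbols.
#' @param sets a `gene_set_collection`.
#' @param universe character vector of gene symbols defining the sampling
#'   frame (typically the genes actually tested upstream); duplicates are
#'   dropped with a warning.
#' @param alpha significance level on the adjusted p, recorded for
#'   downstream calls (default 0.05).
#' @param min_set_size,max_set_frac set-size bounds (defaults 3 and 0.5).
#' @return `ora_result` data.frame: `set`, `description`, `N`, `K`, `n`,
#'   `k`, `p_value`, `adjusted_p`, `overlap` (semicolon-joined symbols).
#' @export
ora <- function(query, sets, universe, alpha = 0.05,
                min_set_size = 3, max_set_frac = 0.5) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (!length(universe)) stop("universe is empty")
  if (anyDuplicated(universe)) {
    warning("universe contains duplicates; deduplicating")
    universe <- unique(universe)
  }
  q <- unique(query[query %in% universe])
  if (!length(q)) stop("query is empty after intersection with the universe")
  N <- length(universe)
  n <- length(q)

  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]]$genes, universe)
    K <- length(members)
    if (K < min_set_size || K > max_set_frac * N) return(NULL)
    ov <- q[q %in% members]
    k <- length(ov)
    # upper tail P(X >= k); phyper is log-space stable internally
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, description = sets[[nm]]$description,
               N = N, K = K, n = n, k = k, p_value = p,
               overlap = paste(ov, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    out <- data.frame(set = character(), description = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p_value = numeric(),
                      adjusted_p = numeric(), overlap = character(),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
    out <- out[order(out$p_value, out$set), ,
               drop = FALSE]
    out <- out[, c("set", "description", "N", "K", "n", "k",
                   "p_value", "adjusted_p", "overlap")]
    rownames(out) <- NULL
  }
  attr(out, "alpha") <- alpha
  class(out) <- c("ora_result", "data.frame")
  out
}

#' @export
print.ora_result <- function(x, ...) {
  alpha <- attr(x, "alpha")
  if (is.null(alpha)) alpha <- 0.05  # subsetting can drop the attribute
  cat(sprintf("ORA: %d sets tested, %d enriched at BH %s\n", nrow(x),
              sum(x$adjusted_p < alpha), format(alpha)))
  if (nrow(x)) print(as.data.frame(utils::head(x[, setdiff(colnames(x), "overlap")], 10)))
  invisible(x)
}

#' Genes of the query carried by enriched sets
#'
#' Union of the overlapping genes across every set whose BH-adjusted p is
#' below `alpha`, in the order they appear in `query`.
#'
#' @param enriched an `ora_result`.
#' @param query the query gene list the ORA was run on.
#' @param alpha cutoff on `adjusted_p`; defaults to the alpha stored in the
#'   result.
#' @return character vector (possibly empty), in query order.
#' @export
member_overlap <- function(enriched, query, alpha = attr(enriched, "alpha")) {
  stopifnot(inherits(enriched, "ora_result"))
  if (is.null(alpha)) alpha <- 0.05
  sig <- enriched[enriched$adjusted_p < alpha, , drop = FALSE]
  hits <- unique(unlist(strsplit(sig$overlap[nzchar(sig$overlap)], ";",
                                 fixed = TRUE), use.names = FALSE))
  query[query %in% hits]
}
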