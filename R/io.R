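# Readers and writers for every external table the pipeline touches.
# All outputs are TSV with header; the DepMap wide dialect is the only CSV
# input. Encoding is UTF-8, decimal point ".", no thousands separators.

#' Construct a dependency matrix
#'
#' A dependency matrix holds gene-effect scores (Chronos-style: lower means
#' the cell line is more dependent on the gene; below -0.5 is conventionally
#' "essential") as a numeric gene x cell-line matrix. Missing scores are kept
#' as `NA` and never imputed; downstream statistics drop them per gene.
#'
#' @param scores numeric matrix, rows = genes (rownames = unique symbols),
#'   columns = cell lines (colnames = unique identifiers). `NA` allowed;
#'   `NaN`/`Inf` are not.
#' @param gene_ids optional character vector of dataset gene identifiers
#'   (e.g. Entrez) parallel to the rows, kept as metadata.
#' @return an object of class `dep_matrix`.
#' @export
dependency_matrix <- function(scores, gene_ids = NULL) {
  if (!is.matrix(scores) || !is.numeric(scores))
    stop("`scores` must be a numeric matrix")
  if (is.null(rownames(scores)) || is.null(colnames(scores)))
    stop("`scores` must have gene rownames and cell-line colnames")
  dup <- unique(rownames(scores)[duplicated(rownames(scores))])
  if (length(dup))
    stop("duplicate gene symbol(s): ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(scores)))
    stop("duplicate cell-line identifier(s)")
  bad <- !is.na(scores) & !is.finite(scores)
  if (any(bad)) stop("non-finite score(s) present (NaN/Inf); use NA for missing")
  if (!is.null(gene_ids)) {
    stopifnot(length(gene_ids) == nrow(scores))
    gene_ids <- as.character(gene_ids)
  }
  structure(list(genes = rownames(scores), cell_lines = colnames(scores),
                 scores = scores, gene_ids = gene_ids),
            class = "dep_matrix")
}

#' @export
print.dep_matrix <- function(x, ...) {
  cat(sprintf("Dependency matrix: %d genes x %d cell lines (%d missing scores)\n",
              length(x$genes), length(x$cell_lines), sum(is.na(x$scores))))
  invisible(x)
}

#' @export
dim.dep_matrix <- function(x) dim(x$scores)

# "SYMBOL (12345)" -> SYMBOL; idempotent on already-bare symbols.
strip_gene_id <- function(x) sub("\\s*\\([^)]*\\)\\s*$", "", x)
extract_gene_id <- function(x) {
  id <- sub("^.*\\(([^)]*)\\)\\s*$", "\\1", x)
  id[id == x] <- NA_character_
  id
}

#' Read a gene x cell-line dependency score table
#'
#' In the `depmap_wide` dialect (the DepMap portal "CRISPRGeneEffect" export)
#' rows are cell-line model IDs and columns are `"SYMBOL (NumericID)"`; the
#' table is transposed into gene x cell-line orientation and column headers
#' are normalized to the bare symbol, with the parenthesized ID retained as
#' metadata. In the `plain` dialect rows are genes (first column = symbol)
#' and columns are cell lines, with no transposition.
#'
#' @param path CSV file with a header row.
#' @param dialect `"depmap_wide"` (default) or `"plain"`.
#' @return a [dependency_matrix()].
#' @export
read_dependency_csv <- function(path, dialect = c("depmap_wide", "plain")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) stop("dependency table needs an ID column plus data columns")
  ids <- raw[[1]]
  num <- parse_numeric_cells(raw[-1], path)
  if (dialect == "depmap_wide") {
    symbols <- strip_gene_id(colnames(num))
    gene_ids <- extract_gene_id(colnames(num))
    dup <- unique(symbols[duplicated(symbols)])
    if (length(dup))
      stop("duplicate gene symbol after normalization: ",
           paste(dup, collapse = ", "))
    scores <- t(num)
    rownames(scores) <- symbols
    colnames(scores) <- ids
    dependency_matrix(scores, gene_ids = gene_ids)
  } else {
    scores <- num
    rownames(scores) <- ids
    dependency_matrix(scores)
  }
}

# Convert a data.frame of character cells into a numeric matrix; "" / "NA"
# become NA, anything else non-numeric is an error with its coordinates.
parse_numeric_cells <- function(df, path) {
  out <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(NULL, colnames(df)))
  for (j in seq_along(df)) {
    cell <- df[[j]]
    missing <- is.na(cell) | cell == "" | cell == "NA"
    val <- suppressWarnings(as.numeric(cell))
    bad <- which(!missing & is.na(val))
    if (length(bad))
      stop(sprintf("non-numeric value %s at data row %d, column '%s' of %s",
                   dQuote(cell[bad[1]]), bad[1], colnames(df)[j], path))
    out[, j] <- val
  }
  out
}

#' Write a dependency matrix in the DepMap wide dialect
#'
#' Inverse of [read_dependency_csv()]: rows are cell lines, columns
#' `"SYMBOL (ID)"` (the bare symbol when no ID metadata is present).
#' @param dep a [dependency_matrix()].
#' @param path output CSV path.
#' @export
write_dependency_csv <- function(dep, path) {
  stopifnot(inherits(dep, "dep_matrix"))
  header <- dep$genes
  if (!is.null(dep$gene_ids)) {
    has_id <- !is.na(dep$gene_ids)
    header[has_id] <- paste0(dep$genes[has_id], " (", dep$gene_ids[has_id], ")")
  }
  wide <- t(dep$scores)
  df <- data.frame(ModelID = rownames(wide), wide, check.names = FALSE)
  colnames(df) <- c("ModelID", header)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Broad/MSigDB dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>member1<TAB>member2...`. Members are
#' deduplicated preserving first occurrence.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`: named list of
#'   `list(description =, genes =)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("GMT line %d has %d field(s); need at least 3", i, length(f)))
    nms[i] <- f[1]
    sets[[i]] <- list(description = f[2], genes = unique(f[-(1:2)]))
  }
  dup <- unique(nms[duplicated(nms)])
  if (length(dup)) stop("duplicate gene-set name(s): ", paste(dup, collapse = ", "))
  names(sets) <- nms
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#' @param sets a `gene_set_collection`.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "gene_set_collection"))
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    paste(c(nm, s$description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- vapply(x, function(s) length(s$genes), integer(1))
  cat(sprintf("Gene-set collection: %d sets (sizes %s)\n", length(x),
              if (length(x)) paste0(min(sizes), "-", max(sizes)) else "-"))
  invisible(x)
}

#' Read a cell-line grouping table
#'
#' TSV with columns `cell_line` and `entity`. Lines whose entity equals
#' `target_label` form the target set; all others form the background.
#'
#' @param path TSV path.
#' @param target_label entity label of the target group (e.g. `"AML"`).
#' @return a `cell_grouping`: list with `target`, `background`,
#'   `target_label`, and the full `table`.
#' @export
read_grouping <- function(path, target_label) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("cell_line", "entity") %in% colnames(df)))
    stop("grouping table needs columns 'cell_line' and 'entity'")
  cell_grouping(df$cell_line, df$entity, target_label)
}

#' Construct a cell-line grouping
#' @param cell_lines character vector of unique cell-line identifiers.
#' @param entities parallel vector of entity labels.
#' @param target_label label defining the target group.
#' @export
cell_grouping <- function(cell_lines, entities, target_label) {
  stopifnot(length(cell_lines) == length(entities))
  dup <- unique(cell_lines[duplicated(cell_lines)])
  if (length(dup)) stop("duplicate cell line(s): ", paste(dup, collapse = ", "))
  target <- cell_lines[entities == target_label]
  background <- cell_lines[entities != target_label]
  if (!length(target))
    stop("no cell line carries target label ", dQuote(target_label))
  if (!length(background))
    stop("background group is empty: every cell line carries the target label")
  structure(list(target = target, background = background,
                 target_label = target_label,
                 table = data.frame(cell_line = cell_lines, entity = entities,
                                    stringsAsFactors = FALSE)),
            class = "cell_grouping")
}

#' @export
print.cell_grouping <- function(x, ...) {
  cat(sprintf("Cell-line grouping: %d %s (target) vs %d background\n",
              length(x$target), x$target_label, length(x$background)))
  invisible(x)
}

#' Construct / validate an expression matrix
#'
#' @param values numeric matrix, rows = genes, columns = samples.
#' @param type `"counts"` (non-negative, as from RNA-seq quantification) or
#'   `"continuous"` (e.g. z-scores, log expression).
#' @return an `expr_matrix` object.
#' @export
expression_matrix <- function(values, type = c("counts", "continuous")) {
  type <- match.arg(type)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbol(s)")
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifier(s)")
  if (type == "counts" && any(values < 0, na.rm = TRUE))
    stop("counts must be non-negative")
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values, type = type),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("Expression matrix (%s): %d genes x %d samples\n",
              x$type, length(x$genes), length(x$samples)))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' Plain layout: first column = gene symbol, remaining columns = samples.
#' @param path TSV path.
#' @param type see [expression_matrix()].
#' @export
read_expression_tsv <- function(path, type = c("counts", "continuous")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  num <- parse_numeric_cells(raw[-1], path)
  rownames(num) <- raw[[1]]
  expression_matrix(num, type = type)
}

#' Write an expression matrix as TSV
#' @param expr an `expr_matrix`.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(gene = expr$genes, expr$values, check.names = FALSE)
  write_table(df, path)
}

#' Construct / validate a clinical table
#'
#' One row per patient sample: a continuous covariate (typically the
#' expression of one query gene), overall-survival time in a consistent
#' unit, and the event indicator (1 = death observed, 0 = censored).
#'
#' @param df data.frame with columns `sample`, `expression`, `os_time`,
#'   `os_event`.
#' @return the validated data.frame with class `clinical_table`.
#' @export
clinical_table <- function(df) {
  need <- c("sample", "expression", "os_time", "os_event")
  if (!all(need %in% colnames(df)))
    stop("clinical table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample)) stop("duplicate sample id(s)")
  if (any(!is.finite(df$os_time)) || any(df$os_time < 0))
    stop("os_time must be finite and >= 0")
  if (!all(df$os_event %in% c(0, 1)))
    stop("os_event must be 0 (censored) or 1 (death observed)")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read a clinical TSV (sample, expression, os_time, os_event)
#' @param path TSV path.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = c(sample = "character"))
  clinical_table(df)
}

#' Write a result table as TSV
#'
#' Header included, stable column order, full-precision numbers (15
#' significant digits), so that reading back reproduces integers
#' bit-identically and reals to at least 12 significant digits, and a
#' write/read/write round trip is byte-identical.
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read back a TSV written by [write_table()]
#' @param path TSV path.
#' @export
read_table <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
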