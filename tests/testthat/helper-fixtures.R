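# Small in-code fixtures shared across test files.

# 3 target + 3 background lines, 3 genes with known medians:
#   SEL: selectively essential in the target lines
#   NEU: neutral everywhere
#   FLAT: constant everywhere (degenerate-contract probe)
tiny_dep <- function() {
  scores <- rbind(
    SEL  = c(-0.9, -0.8, -1.0, 0.0, 0.1, -0.1),
    NEU  = c(0.05, -0.05, 0.0, 0.02, -0.02, 0.0),
    FLAT = rep(-0.2, 6))
  colnames(scores) <- c("T1", "T2", "T3", "B1", "B2", "B3")
  dependency_matrix(scores)
}

tiny_grouping <- function() {
  cell_grouping(c("T1", "T2", "T3", "B1", "B2", "B3"),
                c(rep("AML", 3), rep("OTHER", 3)), "AML")
}

# gene-set collection built directly, bypassing GMT files
make_sets <- function(...) {
  sets <- lapply(list(...), function(g) list(description = "d", genes = g))
  structure(sets, class = "gene_set_collection")
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
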