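# Synthetic-data generators with known ground truth for every input the
# pipeline consumes. All generators are pure functions of their arguments
# including the seed; per-gene random streams are derived from the seed so
# individual genes stay reproducible under reordering.

#' Configuration of a synthetic dependency screen
#'
#' The generated matrix mimics the class structure of Chronos gene-effect
#' data: non-essential genes centred at 0 in every line, common (pan)
#' essentials centred at -1 in every line, and planted entity-selective
#' genes shifted by `-delta` in the target lines only, all with Gaussian
#' noise of SD `sigma`. Defaults follow a 26-line target entity against a
#' 300-line pan-cancer background with delta = 0.8 and sigma = 0.15.
#'
#' @param seed integer seed.
#' @param n_genes total genes.
#' @param n_target_lines,n_background_lines cell lines per group.
#' @param n_planted_selective,n_common_essential planted class sizes
#'   (their sum must not exceed `n_genes`).
#' @param delta mean dependency shift of planted selective genes in the
#'   target lines, score units (positive; applied as `-delta`).
#' @param sigma score noise SD, > 0.
#' @param target_label entity label of the target lines.
#' @return a `screen_sim_config` list.
#' @export
screen_sim_config <- function(seed = 1, n_genes = 500,
                              n_target_lines = 26, n_background_lines = 300,
                              n_planted_selective = 10,
                              n_common_essential = 20,
                              delta = 0.8, sigma = 0.15,
                              target_label = "AML") {
  stopifnot(n_genes >= 1, n_target_lines >= 1, n_background_lines >= 1,
            n_planted_selective >= 0, n_common_essential >= 0,
            n_planted_selective + n_common_essential <= n_genes,
            sigma > 0, delta >= 0)
  structure(as.list(environment()), class = "screen_sim_config")
}

#' Generate a synthetic dependency matrix with ground truth
#'
#' @param cfg a [screen_sim_config()].
#' @return list with `dep` (a [dependency_matrix()]), `grouping` (a
#'   [cell_grouping()]) and `truth` (data.frame `gene`, `class` in
#'   nonessential / common_essential / planted_selective).
#' @export
gen_dependency_matrix <- function(cfg = screen_sim_config()) {
  stopifnot(inherits(cfg, "screen_sim_config"))
  ng <- cfg$n_genes
  nt <- cfg$n_target_lines; nb <- cfg$n_background_lines
  genes <- sprintf("G%05d", seq_len(ng))
  lines <- c(sprintf("TL%04d", seq_len(nt)), sprintf("BL%04d", seq_len(nb)))
  entity <- c(rep(cfg$target_label, nt), rep("OTHER", nb))

  # class assignment: seeded permutation so planted genes are not positional
  set.seed(stream_seed(cfg$seed, 0))
  perm <- sample.int(ng)
  class <- rep("nonessential", ng)
  class[perm[seq_len(cfg$n_planted_selective)]] <- "planted_selective"
  if (cfg$n_common_essential > 0)
    class[perm[cfg$n_planted_selective + seq_len(cfg$n_common_essential)]] <-
      "common_essential"

  scores <- matrix(NA_real_, ng, nt + nb, dimnames = list(genes, lines))
  for (i in seq_len(ng)) {
    set.seed(stream_seed(cfg$seed, i))
    mu_target <- switch(class[i], nonessential = 0, common_essential = -1,
                        planted_selective = -cfg$delta)
    mu_bg <- switch(class[i], nonessential = 0, common_essential = -1,
                    planted_selective = 0)
    scores[i, ] <- stats::rnorm(nt + nb, mean = c(rep(mu_target, nt),
                                                  rep(mu_bg, nb)),
                                sd = cfg$sigma)
  }
  list(dep = dependency_matrix(scores,
                               gene_ids = as.character(seq_len(ng))),
       grouping = cell_grouping(lines, entity, cfg$target_label),
       truth = data.frame(gene = genes, class = class,
                          stringsAsFactors = FALSE))
}

#' Generate a gene-set collection with one planted enriched pathway
#'
#' The first set (`"PLANTED_PATHWAY"`) contains `enrichment_fraction` of the
#' planted selective genes (rounded down) plus random filler genes up to
#' `set_size`; the remaining sets are uniform random draws from all genes.
#'
#' @param truth truth table from [gen_dependency_matrix()].
#' @param n_sets total number of sets (>= 1).
#' @param set_size members per set.
#' @param enrichment_fraction fraction of planted selective genes placed in
#'   the planted pathway (0..1).
#' @param seed integer seed.
#' @return a `gene_set_collection`.
#' @export
gen_gene_sets <- function(truth, n_sets = 20, set_size = 25,
                          enrichment_fraction = 1, seed = 1) {
  stopifnot(n_sets >= 1, set_size >= 1,
            enrichment_fraction >= 0, enrichment_fraction <= 1)
  genes <- truth$gene
  planted <- truth$gene[truth$class == "planted_selective"]
  sets <- vector("list", n_sets)
  set.seed(stream_seed(seed, 0))
  n_in <- floor(enrichment_fraction * length(planted))
  core <- if (n_in > 0) sample(planted, n_in) else character()
  filler_pool <- setdiff(genes, core)
  n_fill <- max(set_size - length(core), 0)
  sets[[1]] <- list(description = "planted enriched pathway",
                    genes = c(core, sample(filler_pool, n_fill)))
  for (j in seq_len(n_sets)[-1]) {
    set.seed(stream_seed(seed, j))
    sets[[j]] <- list(description = sprintf("random set %d", j),
                      genes = sample(genes, min(set_size, length(genes))))
  }
  names(sets) <- c("PLANTED_PATHWAY",
                   if (n_sets > 1) sprintf("RANDOM_SET_%03d", seq_len(n_sets)[-1]))
  structure(sets, class = "gene_set_collection")
}

#' Generate a negative-binomial count matrix with planted effects
#'
#' Control samples draw from NB(mean = `base_mean`, dispersion =
#' `nb_dispersion`); for the `n_de` planted genes the knockdown group's mean
#' is `base_mean * 2^(s * log2_effect)` with sign `s` drawn +/-1 per gene.
#'
#' @param n_genes,n_per_group matrix dimensions (two groups of
#'   `n_per_group` samples).
#' @param n_de number of planted differentially expressed genes.
#' @param log2_effect absolute planted effect on the log2 scale.
#' @param nb_dispersion NB dispersion (size = 1/dispersion).
#' @param base_mean control-group mean count.
#' @param seed integer seed.
#' @return list with `expr` (an [expression_matrix()] of counts), `labels`
#'   (named sample -> control/knockdown) and `truth` (data.frame `gene`,
#'   `log2_effect` signed, 0 for null genes).
#' @export
gen_counts <- function(n_genes = 2000, n_per_group = 3, n_de = 50,
                       log2_effect = 2, nb_dispersion = 0.1,
                       base_mean = 100, seed = 1) {
  stopifnot(n_genes >= 1, n_per_group >= 2, n_de >= 0, n_de <= n_genes,
            nb_dispersion > 0, base_mean > 0)
  genes <- sprintf("G%05d", seq_len(n_genes))
  samples <- c(sprintf("CTRL_%d", seq_len(n_per_group)),
               sprintf("KD_%d", seq_len(n_per_group)))
  labels <- stats::setNames(rep(c("control", "knockdown"),
                                each = n_per_group), samples)
  set.seed(stream_seed(seed, 0))
  de_idx <- sample.int(n_genes, n_de)
  sign <- rep(0, n_genes)
  sign[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE)
  eff <- sign * log2_effect
  size <- 1 / nb_dispersion
  counts <- matrix(0L, n_genes, 2 * n_per_group,
                   dimnames = list(genes, samples))
  for (i in seq_len(n_genes)) {
    set.seed(stream_seed(seed, i))
    mu_kd <- base_mean * 2^eff[i]
    counts[i, ] <- stats::rnbinom(2 * n_per_group,
                                  mu = c(rep(base_mean, n_per_group),
                                         rep(mu_kd, n_per_group)),
                                  size = size)
  }
  list(expr = expression_matrix(counts, type = "counts"),
       labels = labels,
       truth = data.frame(gene = genes, log2_effect = eff,
                          stringsAsFactors = FALSE))
}

#' Generate a survival cohort with a covariate-dependent hazard
#'
#' Covariate z ~ N(0,1) per patient (an expression z-score analogue); event
#' times are exponential with rate `baseline_hazard * exp(beta * z)`;
#' censoring times are independent exponentials with rate
#' `baseline_hazard * censor_rate / (1 - censor_rate)` (giving an expected
#' censoring fraction of about `censor_rate` when beta = 0). Observed time
#' is the minimum, the event indicator marks whether death was observed.
#'
#' @param n_patients cohort size.
#' @param beta log-hazard coefficient of the covariate (positive = higher
#'   expression, worse survival).
#' @param baseline_hazard exponential baseline rate, 1/time-unit.
#' @param censor_rate target censoring fraction in (0,1).
#' @param seed integer seed.
#' @return a [clinical_table()] with the true covariate in `expression`.
#' @export
gen_survival <- function(n_patients = 400, beta = 1, baseline_hazard = 0.05,
                         censor_rate = 0.2, seed = 1) {
  stopifnot(n_patients >= 2, baseline_hazard > 0,
            censor_rate > 0, censor_rate < 1)
  set.seed(stream_seed(seed, 0))
  z <- stats::rnorm(n_patients)
  t_event <- stats::rexp(n_patients, rate = baseline_hazard * exp(beta * z))
  t_cens <- stats::rexp(n_patients,
                        rate = baseline_hazard * censor_rate / (1 - censor_rate))
  clinical_table(data.frame(
    sample = sprintf("P%04d", seq_len(n_patients)),
    expression = z,
    os_time = pmin(t_event, t_cens),
    os_event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE))
}
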