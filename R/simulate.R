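# Seeded synthetic-data generation with planted ground truth.
#
# The generator emulates the data structures of a multi-assay CIN study:
# a screened gene universe with essential/non-essential structure, a
# rooted ontology DAG with gene annotations, a planted CIN gene set whose
# annotation probability is inflated at planted terms, per-assay hit
# tables with configurable sensitivity and false-positive rates, a
# one-to-many yeast-to-human orthology map, a mutation gene table in
# which true candidates can be enriched, and an interaction score matrix
# containing a co-functional query group built from a shared template.
#
# Every generator is a pure function of (config, seed); the random stream
# is partitioned per generator via seeds derived from the master seed, so
# editing one config block leaves the other generators' outputs intact.

#' Simulation configuration
#'
#' Builds the configuration object consumed by the `simulate_*`
#' generators. Defaults mimic the scale of a genome-wide yeast CIN study
#' qualitatively: ~2,000 screened genes, ~300 ontology terms, five assays
#' and three source screens.
#'
#' @param seed Master seed (integer).
#' @param n_genes Size of the screened yeast universe.
#' @param frac_essential Fraction of essential genes in the universe.
#' @param n_terms,dag_depth Ontology size and depth (each non-root term
#'   draws 1-2 parents from shallower levels).
#' @param annotation_rate Mean number of terms annotated per gene (the
#'   per-(gene, term) annotation probability is `annotation_rate /
#'   n_terms`).
#' @param n_cin_genes Number of planted CIN genes.
#' @param planted_multipliers Numeric vector (all >= 1): one planted
#'   enriched term per entry, whose CIN-gene annotation probability is
#'   multiplied by the entry. The realized fold enrichment measured
#'   downstream is attenuated well below the multiplier by false-positive
#'   dilution of the study set and CIN-gene contamination of the
#'   background count; the default of 12 yields a realized fold around 4,
#'   the magnitude of a strongly enriched pathway term.
#' @param sensitivity Named per-assay detection probability for planted
#'   genes.
#' @param fpr Per-assay false-positive rate among non-CIN genes.
#' @param p_strong Probability that a reported hit is STRONG.
#' @param n_sources Number of source screens (assigned round-robin).
#' @param p_ortholog Probability a yeast gene has >= 1 human ortholog.
#' @param fanout_lambda Poisson parameter of the extra-ortholog fan-out
#'   (fan-out is `1 + Poisson(fanout_lambda)`).
#' @param p_functional Probability an orthology row is a functional
#'   (rather than sequence) ortholog.
#' @param n_human_extra Human genes with no yeast source, annotated
#'   independently.
#' @param mutation_base_rate Background probability that a human gene has
#'   a somatic-mutation record.
#' @param candidate_mutation_multiplier Rate multiplier applied to
#'   orthologs of planted CIN genes (1 = null model).
#' @param p_census Probability a mutated gene is also in the census set.
#' @param n_array_genes Columns of the interaction matrix.
#' @param n_queries Planted co-functional query profiles.
#' @param n_unrelated Unrelated background profiles.
#' @param template_sd,noise_sd Standard deviations of the shared template
#'   signal and of the per-profile noise (template_sd >= 3 * noise_sd
#'   gives a clearly co-clustering group).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       frac_essential = 0.2,
                       n_terms = 300L,
                       dag_depth = 5L,
                       annotation_rate = 6,
                       n_cin_genes = 200L,
                       planted_multipliers = rep(12, 10L),
                       sensitivity = c(CTF = 0.6, ALF = 0.5, GCR = 0.5,
                                       BIM = 0.4, LOH = 0.4),
                       fpr = 0.01,
                       p_strong = 0.3,
                       n_sources = 3L,
                       p_ortholog = 0.6,
                       fanout_lambda = 0.3,
                       p_functional = 0.1,
                       n_human_extra = 500L,
                       mutation_base_rate = 0.1,
                       candidate_mutation_multiplier = 3,
                       p_census = 0.2,
                       n_array_genes = 200L,
                       n_queries = 4L,
                       n_unrelated = 20L,
                       template_sd = 3,
                       noise_sd = 1) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              frac_essential = frac_essential, n_terms = as.integer(n_terms),
              dag_depth = as.integer(dag_depth),
              annotation_rate = annotation_rate,
              n_cin_genes = as.integer(n_cin_genes),
              planted_multipliers = planted_multipliers,
              sensitivity = sensitivity, fpr = fpr, p_strong = p_strong,
              n_sources = as.integer(n_sources), p_ortholog = p_ortholog,
              fanout_lambda = fanout_lambda, p_functional = p_functional,
              n_human_extra = as.integer(n_human_extra),
              mutation_base_rate = mutation_base_rate,
              candidate_mutation_multiplier = candidate_mutation_multiplier,
              p_census = p_census, n_array_genes = as.integer(n_array_genes),
              n_queries = as.integer(n_queries),
              n_unrelated = as.integer(n_unrelated),
              template_sd = template_sd, noise_sd = noise_sd)
  stopifnot(cfg$n_terms >= 3L, cfg$frac_essential >= 0, cfg$frac_essential <= 1,
            cfg$fpr >= 0, cfg$fpr <= 1, all(cfg$sensitivity >= 0),
            all(cfg$sensitivity <= 1), all(cfg$planted_multipliers >= 1),
            cfg$mutation_base_rate >= 0, cfg$mutation_base_rate <= 1,
            cfg$candidate_mutation_multiplier >= 1,
            cfg$n_cin_genes <= cfg$n_genes,
            length(cfg$planted_multipliers) < cfg$n_terms)
  class(cfg) <- "sim_config"
  cfg
}

sim_gene_ids <- function(n) sprintf("YGS%04d", seq_len(n))
sim_term_ids <- function(n) sprintf("GO:%07d", seq_len(n))

#' Simulate an ontology with planted enrichment
#'
#' Generates a single-namespace rooted DAG (`dag_depth` levels below the
#' root, each non-root term drawing 1-2 parents from shallower levels),
#' the planted CIN gene set, and raw gene annotations: each (gene, term)
#' pair is annotated with probability `annotation_rate / n_terms`,
#' multiplied at planted terms for planted CIN genes.
#'
#' @param config A `sim_config`.
#' @return A list: `dag` (`ontology_dag`), `annotations` (raw
#'   `annotation_set`), `truth` (list with `cin_genes`,
#'   `planted_terms`, `multipliers`).
#' @export
simulate_ontology <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_terms < 3L) stop("need at least 3 terms", call. = FALSE)
  set.seed(derive_seed(config$seed, "ontology"))
  ids <- sim_term_ids(config$n_terms)
  root <- ids[1L]
  depth <- pmin(config$dag_depth,
                1L + ((seq_len(config$n_terms) - 2L) %% config$dag_depth))
  depth[1L] <- 0L
  e_child <- character(0); e_parent <- character(0); e_rel <- character(0)
  for (i in 2L:config$n_terms) {
    shallower <- which(depth < depth[i])
    np <- min(length(shallower), sample(1:2, 1L))
    ps <- ids[sample(shallower, np)]
    e_child <- c(e_child, rep(ids[i], np))
    e_parent <- c(e_parent, ps)
    e_rel <- c(e_rel, sample(c("is_a", "part_of"), np, replace = TRUE,
                             prob = c(0.85, 0.15)))
  }
  terms <- data.frame(id = ids, name = paste0("synthetic term ", seq_along(ids)),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  dag <- new_ontology_dag(terms, data.frame(child = e_child, parent = e_parent,
                                            relation = e_rel,
                                            stringsAsFactors = FALSE))
  genes <- sim_gene_ids(config$n_genes)
  cin_genes <- sort(sample(genes, config$n_cin_genes))
  n_planted <- length(config$planted_multipliers)
  # plant at maximum-depth terms: they have no descendants, so ancestor
  # closure cannot swamp the planted direct-annotation signal with
  # propagated counts from unrelated subtrees
  plantable <- ids[depth == max(depth)]
  if (length(plantable) < n_planted) plantable <- ids[-1L]
  planted <- if (n_planted > 0L) sort(sample(plantable, n_planted)) else character(0)
  p_base <- min(1, config$annotation_rate / config$n_terms)
  # Bernoulli annotation per (gene, term) on non-root terms
  ann <- vector("list", length(genes))
  names(ann) <- genes
  is_cin <- genes %in% cin_genes
  mult <- stats::setNames(rep(1, length(ids)), ids)
  if (n_planted > 0L) mult[planted] <- config$planted_multipliers
  non_root <- ids[-1L]
  p_non_cin <- rep(p_base, length(non_root))
  p_cin <- pmin(1, p_base * mult[non_root])
  for (g in seq_along(genes)) {
    p <- if (is_cin[g]) p_cin else p_non_cin
    hit <- non_root[stats::runif(length(non_root)) < p]
    ann[[g]] <- hit
  }
  ann <- ann[lengths(ann) > 0L]
  truth <- list(cin_genes = cin_genes, planted_terms = planted,
                multipliers = if (n_planted > 0L)
                  stats::setNames(config$planted_multipliers, planted)
                else numeric(0))
  list(dag = dag, annotations = annotation_set(ann), truth = truth)
}

#' Simulate per-assay screen-hit tables and gene metadata
#'
#' Each planted CIN gene is detected by each assay with that assay's
#' sensitivity; non-CIN genes appear as false positives at `fpr`. Sources
#' are assigned round-robin over `n_sources` and strengths are STRONG
#' with probability `p_strong`. Metadata marks `frac_essential` of the
#' universe essential, biases nuclear localization toward CIN genes, and
#' leaves a few ORFs unverified.
#'
#' @param config A `sim_config`.
#' @param truth Planted truth from [simulate_ontology()].
#' @return A list: `hit_tables` (named list of `cin_hits`, one per
#'   assay), `meta` (gene metadata data frame).
#' @export
simulate_screens <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "screens"))
  genes <- sim_gene_ids(config$n_genes)
  is_cin <- genes %in% truth$cin_genes
  sources <- paste0("S", seq_len(config$n_sources))
  hit_tables <- list()
  for (a in names(config$sensitivity)) {
    p <- ifelse(is_cin, config$sensitivity[[a]], config$fpr)
    hit <- stats::runif(length(genes)) < p
    g <- genes[hit]
    if (length(g) == 0L) {
      hit_tables[[a]] <- cin_hits(character(0), character(0), character(0),
                                  character(0))
      next
    }
    strength <- ifelse(stats::runif(length(g)) < config$p_strong,
                       "STRONG", "WEAK")
    src <- sources[((seq_along(g) - 1L) %% config$n_sources) + 1L]
    hit_tables[[a]] <- cin_hits(g, a, strength, src)
  }
  set.seed(derive_seed(config$seed, "meta"))
  essential <- stats::runif(length(genes)) < config$frac_essential
  nuclear <- stats::runif(length(genes)) < ifelse(is_cin, 0.7, 0.35)
  verified <- stats::runif(length(genes)) < 0.97
  meta <- data.frame(gene = genes, essential = essential, nuclear = nuclear,
                     verified_orf = verified,
                     functional_group = NA_character_,
                     stringsAsFactors = FALSE)
  list(hit_tables = hit_tables, meta = meta)
}

#' Simulate orthology, human annotations, mutations and an interaction matrix
#'
#' Each yeast gene gains `1 + Poisson(fanout_lambda)` human orthologs
#' with probability `p_ortholog`; human genes inherit the raw term
#' annotations of their yeast source, and `n_human_extra` additional
#' human-only genes are annotated independently at the background rate.
#' The mutation table marks human genes mutated at `mutation_base_rate`,
#' multiplied by `candidate_mutation_multiplier` for orthologs of planted
#' CIN genes. The interaction matrix contains `n_queries` profiles built
#' from one shared template plus noise and `n_unrelated` independent
#' profiles.
#'
#' @param config A `sim_config`.
#' @param ontology Output of [simulate_ontology()] (its raw annotations
#'   seed the human annotations).
#' @return A list: `orthology` (`orthology_map`), `human_annotations`
#'   (raw `annotation_set`), `mutations` (`mutation_table`),
#'   `matrix` (interaction matrix), `truth` (adds `query_group`,
#'   `candidate_orthologs` and the mutation-enrichment flag).
#' @export
simulate_downstream <- function(config, ontology) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "downstream"))
  genes <- sim_gene_ids(config$n_genes)
  truth <- ontology$truth
  has_orth <- stats::runif(length(genes)) < config$p_ortholog
  fanout <- (1L + stats::rpois(length(genes), config$fanout_lambda)) * has_orth
  y <- rep(genes, fanout)
  idx <- sequence(fanout[fanout > 0L])
  h <- sprintf("H%s_%d", sub("^YGS", "", y), idx)
  kind <- ifelse(stats::runif(length(y)) < config$p_functional,
                 "FUNCTIONAL", "SEQUENCE")
  orthology <- data.frame(yeast_orf = y, human_symbol = h, kind = kind,
                          stringsAsFactors = FALSE)
  class(orthology) <- c("orthology_map", "data.frame")

  # human genes inherit their yeast source's raw annotations
  yeast_ann <- ontology$annotations$annotations
  human_ann <- stats::setNames(
    lapply(y, function(g) yeast_ann[[g]] %||% character(0)), h)
  extra <- sprintf("HX%04d", seq_len(config$n_human_extra))
  p_base <- min(1, config$annotation_rate / config$n_terms)
  non_root <- ontology$dag$terms$id[-1L]
  for (g in extra) {
    human_ann[[g]] <- non_root[stats::runif(length(non_root)) < p_base]
  }
  human_ann <- human_ann[lengths(human_ann) > 0L]

  human_universe <- c(h, extra)
  candidate_orthologs <- unique(h[y %in% truth$cin_genes])
  p_mut <- ifelse(human_universe %in% candidate_orthologs,
                  min(1, config$mutation_base_rate *
                        config$candidate_mutation_multiplier),
                  config$mutation_base_rate)
  mutated <- human_universe[stats::runif(length(human_universe)) < p_mut]
  census <- mutated[stats::runif(length(mutated)) < config$p_census]
  mut_df <- data.frame(symbol = normalize_symbol(mutated),
                       stringsAsFactors = FALSE)
  mut_df$sources <- lapply(seq_along(mutated), function(i) {
    if (mutated[i] %in% census) c("CENSUS", "COSMIC") else "COSMIC"
  })
  ord <- order(mut_df$symbol)
  mut_df <- mut_df[ord, , drop = FALSE]
  rownames(mut_df) <- NULL
  mutations <- structure(mut_df, class = c("mutation_table", "data.frame"),
                         version = "synthetic")

  # interaction matrix: co-functional query group from a shared template
  queries <- utils::head(truth$cin_genes, config$n_queries)
  template <- stats::rnorm(config$n_array_genes, 0, config$template_sd)
  qrows <- t(vapply(seq_len(config$n_queries), function(i) {
    template + stats::rnorm(config$n_array_genes, 0, config$noise_sd)
  }, numeric(config$n_array_genes)))
  urows <- t(vapply(seq_len(config$n_unrelated), function(i) {
    stats::rnorm(config$n_array_genes, 0,
                 sqrt(config$template_sd^2 + config$noise_sd^2))
  }, numeric(config$n_array_genes)))
  mat <- rbind(qrows, urows)
  rownames(mat) <- c(queries, sprintf("UNREL%02d", seq_len(config$n_unrelated)))
  colnames(mat) <- sprintf("ARR%04d", seq_len(config$n_array_genes))

  truth$query_group <- queries
  truth$candidate_orthologs <- candidate_orthologs
  truth$mutation_enriched <- config$candidate_mutation_multiplier > 1
  list(orthology = orthology, human_annotations = annotation_set(human_ann),
       mutations = mutations, matrix = mat, human_universe = human_universe,
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate and write a complete synthetic input bundle
#'
#' Runs all three generators and writes every input file in the formats
#' the analysis modules read: per-assay screen TSVs, gene metadata, an
#' OBO ontology, yeast and human two-column annotation TSVs, the
#' orthology map, the mutation table, the human universe list, the
#' interaction matrix, the planted truth (JSON) and a config echo.
#'
#' @param config A `sim_config`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory objects and the planted
#'   truth.
#' @export
write_simulation <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  onto <- simulate_ontology(config)
  scr <- simulate_screens(config, onto$truth)
  down <- simulate_downstream(config, onto)
  write_obo(onto$dag, file.path(out_dir, "ontology.obo"))
  write_gene_term_tsv(onto$annotations, file.path(out_dir, "annotations_yeast.tsv"))
  write_gene_term_tsv(down$human_annotations,
                      file.path(out_dir, "annotations_human.tsv"))
  for (a in names(scr$hit_tables)) {
    utils::write.table(as.data.frame(scr$hit_tables[[a]]),
                       file.path(out_dir, paste0("screen_", a, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  utils::write.table(scr$meta, file.path(out_dir, "gene_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(as.data.frame(down$orthology),
                     file.path(out_dir, "orthology.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  mut_flat <- data.frame(
    symbol = rep(down$mutations$symbol, lengths(down$mutations$sources)),
    source = unlist(down$mutations$sources),
    version = "synthetic", stringsAsFactors = FALSE)
  utils::write.table(mut_flat, file.path(out_dir, "mutations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(down$human_universe, file.path(out_dir, "human_universe.txt"))
  write_interaction_matrix(down$matrix, file.path(out_dir, "matrix.tsv"))
  truth <- down$truth
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE)
  writeLines(paste(names(unclass(config)),
                   vapply(unclass(config), function(v)
                     paste(format(v, digits = 10), collapse = ","),
                     character(1L)),
                   sep = " = "),
             file.path(out_dir, "sim_config.txt"))
  invisible(list(ontology = onto, screens = scr, downstream = down,
                 truth = truth))
}
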