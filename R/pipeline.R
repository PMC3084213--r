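# End-to-end pipeline orchestration.
#
# Stages run in order integrate -> enrich -> project -> xref, with
# clustering appended when an interaction matrix is configured. Files are
# the only interface between stages, so any stage can be re-run in
# isolation from the on-disk outputs of the previous one.

#' Read a flat key-value pipeline configuration
#'
#' One `key = value` pair per line; `#` starts a comment. List-valued keys
#' (e.g. `screens`) are comma-separated.
#'
#' @param path Path to the config file.
#' @return A named list of character values.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L) {
    stop("config line without 'key = value': ", lines[bad[1L]], call. = FALSE)
  }
  stats::setNames(lapply(kv, function(m) trimws(m[[3L]])),
                  vapply(kv, function(m) trimws(m[[2L]]), character(1L)))
}

split_paths <- function(x) trimws(strsplit(x, ",", fixed = TRUE)[[1L]])

#' Run the full CIN analysis pipeline
#'
#' Executes integrate -> enrich -> project -> xref (-> cluster when a
#' matrix is supplied) from a configuration list or file, writing stage
#' outputs under `out_dir` and returning a machine-readable run report.
#' All configured inputs are checked before any stage runs.
#'
#' Recognised keys: `screens` (comma-separated hit tables), `meta`,
#' `obo`, `annotations`, `orthology`, `human_annotations`, `mutations`,
#' `human_universe`, optional `matrix`, `queries`, `n_clusters`,
#' `score_cutoff`, `alpha`, `fold_min`, `out_dir`.
#'
#' @param config A named list or the path of a key-value config file.
#' @return A list of class `cin_run_report` (also written as JSON to
#'   `out_dir/run_report.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_pipeline_config(config)
  }
  required <- c("screens", "meta", "obo", "annotations", "orthology",
                "human_annotations", "mutations", "human_universe", "out_dir")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys) > 0L) {
    stop("pipeline config missing key(s): ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  screens <- split_paths(config$screens)
  inputs <- c(screens, config$meta, config$obo, config$annotations,
              config$orthology, config$human_annotations, config$mutations,
              config$human_universe,
              if (!is.null(config$matrix)) config$matrix)
  absent <- inputs[!file.exists(inputs)]
  if (length(absent) > 0L) {
    stop("missing input file(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  alpha <- as.numeric(config$alpha %||% "0.05")
  fold_min <- as.numeric(config$fold_min %||% "3")
  t0 <- Sys.time()
  log_stage <- function(name) {
    message(sprintf("[%s] stage %s", format(Sys.time(), "%H:%M:%S"), name))
  }
  run_stage <- function(name, expr) {
    log_stage(name)
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  report <- list(version = as.character(utils::packageVersion("cincat")),
                 config = lapply(config, as.character),
                 input_digests = as.list(tools::md5sum(inputs)))

  catalogue <- run_stage("integrate", {
    tables <- lapply(screens, read_screen_table)
    meta <- read_gene_meta(config$meta)
    cat <- integrate_screens(tables, meta)
    write_catalogue(cat, file.path(out_dir, "catalogue.tsv"))
    attr(cat, "universe") <- meta
    cat
  })
  universe <- attr(catalogue, "universe")
  summ <- catalogue_summary(catalogue, universe)
  report$catalogue <- list(
    total_genes = summ$total_genes,
    high_confidence = summ$high_confidence,
    high_confidence_fraction = summ$high_confidence_fraction,
    essential_pct = summ$essential_pct,
    nonessential_pct = summ$nonessential_pct,
    per_assay = as.list(summ$per_assay))

  enr <- run_stage("enrich", {
    dag <- parse_obo(config$obo)
    raw <- read_gene_term_tsv(config$annotations)
    closed <- propagate_annotations(dag, raw)
    study <- intersect(catalogue$gene, universe$gene)
    e <- compute_enrichment(study, universe$gene, dag, closed, alpha = alpha)
    write_enrichment(e, file.path(out_dir, "enrichment.tsv"))
    attr(e, "dag") <- dag
    e
  })
  report$enrichment <- list(
    terms_tested = nrow(enr),
    enriched = sum(enr$enriched),
    by_namespace = as.list(enrichment_by_namespace(enr)))

  proj <- run_stage("project", {
    orthology <- read_orthology(config$orthology)
    human_raw <- read_gene_term_tsv(config$human_annotations)
    human_closed <- propagate_annotations(attr(enr, "dag"), human_raw)
    orth_set <- project_orthologs(catalogue, orthology)
    go_set <- project_go_terms(enr, human_closed, fold_min = fold_min)
    write_candidates(orth_set, file.path(out_dir, "candidates_orthology.tsv"))
    write_candidates(go_set, file.path(out_dir, "candidates_go.tsv"))
    list(orth = orth_set, go = go_set)
  })
  ov <- overlap_summary(proj$orth, proj$go)
  report$candidates <- list(
    orthology = nrow(proj$orth),
    go_term = nrow(proj$go),
    go_associations = attr(proj$go, "association_count"),
    go_terms_used = attr(proj$go, "n_terms"),
    overlap = ov)

  xref <- run_stage("xref", {
    mut <- read_mutation_table(config$mutations)
    universe_h <- normalize_symbol(readLines(config$human_universe, warn = FALSE))
    universe_h <- unique(universe_h[nzchar(universe_h)])
    per_set <- lapply(list(orthology = proj$orth, go_term = proj$go),
                      function(set) {
      cr <- crossref_mutations(set, mut)
      bg <- setdiff(universe_h, set$human_gene)
      bg_mut <- sum(bg %in% mut$symbol)
      test <- if (cr$n_candidates > 0L && length(bg) > 0L) {
        suppressWarnings(two_proportion_ztest(cr$n_mutated, cr$n_candidates,
                                              bg_mut, length(bg)))
      } else NULL
      list(n_candidates = cr$n_candidates, n_mutated = cr$n_mutated,
           per_source = as.list(cr$per_source),
           z = if (!is.null(test)) test$z else NA_real_,
           p_value = if (!is.null(test)) test$p_value else NA_real_)
    })
    per_set
  })
  report$xref <- xref

  if (!is.null(config$matrix)) {
    clus <- run_stage("cluster", {
      mat <- read_interaction_matrix(config$matrix)
      metric <- config$metric %||% "centered"
      d <- correlation_distance(mat, metric = metric)
      tree <- average_linkage(d)
      writeLines(linkage_newick(tree), file.path(out_dir, "dendrogram.nwk"))
      queries <- if (!is.null(config$queries)) split_paths(config$queries)
                 else rownames(mat)
      n_clusters <- as.integer(config$n_clusters %||% "5")
      cc <- cocluster(tree, queries, n_clusters)
      cutoff <- as.numeric(config$score_cutoff %||% "2.5")
      sh <- shared_hits(mat[queries, , drop = FALSE], cutoff)
      list(queries = queries, n_clusters = n_clusters,
           cocluster = cc$together, n_shared_hits = sh$n_shared)
    })
    report$cluster <- clus
  } else {
    report$cluster <- list(skipped = TRUE)
  }

  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "cin_run_report"
  json <- report
  json$elapsed_s <- NULL   # keep the on-disk report byte-reproducible
  jsonlite::write_json(unclass(json), file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}

#' @export
print.cin_run_report <- function(x, ...) {
  cat("CIN pipeline run report\n")
  cat(sprintf("  catalogue: %d genes (%d HIGH)\n", x$catalogue$total_genes,
              x$catalogue$high_confidence))
  cat(sprintf("  enrichment: %d/%d terms enriched\n", x$enrichment$enriched,
              x$enrichment$terms_tested))
  cat(sprintf("  candidates: %d orthology / %d GO (overlap %d)\n",
              x$candidates$orthology, x$candidates$go_term,
              x$candidates$overlap$n_intersect))
  if (isTRUE(x$cluster$skipped)) {
    cat("  cluster: skipped (no matrix)\n")
  } else {
    cat(sprintf("  cluster: co-cluster=%s at k=%d, %d shared hits\n",
                x$cluster$cocluster, x$cluster$n_clusters,
                x$cluster$n_shared_hits))
  }
  invisible(x)
}
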