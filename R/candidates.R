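# Cross-species candidate gene projection.
#
# Two complementary routes from the yeast catalogue to human candidates:
# direct orthology of catalogue genes, and membership of human genes in
# CIN-associated ontology terms that pass a fold-enrichment cutoff. The
# two sets overlap only partly; the GO route also captures pathway members
# with no yeast counterpart.

ORTHOLOGY_KINDS <- c("SEQUENCE", "FUNCTIONAL")

#' Read an orthology map
#'
#' Tab-delimited with header columns `yeast_orf`, `human_symbol`, `kind`
#' (SEQUENCE or FUNCTIONAL). One-to-many and many-to-one mappings are
#' allowed; duplicate rows are collapsed. Human symbols are normalized
#' (uppercased, whitespace-stripped).
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `orthology_map`.
#' @export
read_orthology <- function(path) {
  df <- read_tsv_chr(path)
  require_cols(df, c("yeast_orf", "human_symbol", "kind"), "orthology map")
  out <- data.frame(yeast_orf = trimws(df$yeast_orf),
                    human_symbol = normalize_symbol(df$human_symbol),
                    kind = toupper(trimws(df$kind)),
                    stringsAsFactors = FALSE)
  bad <- which(!(out$kind %in% ORTHOLOGY_KINDS))
  if (length(bad) > 0L) {
    stop(sprintf("orthology map %s: unknown kind '%s' at line %d",
                 path, df$kind[bad[1L]], bad[1L] + 1L), call. = FALSE)
  }
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("orthology_map", "data.frame")
  out
}

new_candidate_set <- function(df, method, association_count = NA_integer_,
                              n_terms = NA_integer_, unmapped = character(0)) {
  structure(df, class = c("candidate_set", "data.frame"),
            method = method, association_count = association_count,
            n_terms = n_terms, unmapped = unmapped)
}

#' Project catalogue genes onto human orthologs
#'
#' The candidate set is the union, over catalogue genes, of their mapped
#' human symbols; each candidate records its supporting yeast gene(s) and
#' mapping kind(s). Orthology rows for genes outside the catalogue are
#' ignored, and catalogue genes with no ortholog are listed in the
#' `unmapped` attribute.
#'
#' @param catalogue A `cin_catalogue` (or a bare character vector of
#'   yeast gene ids).
#' @param orthology An `orthology_map`.
#' @return A data frame of class `candidate_set` (method `"ORTHOLOGY"`)
#'   with columns `human_gene`, `support` (list of yeast genes), `kinds`
#'   (list), `n_support`.
#' @export
project_orthologs <- function(catalogue, orthology) {
  genes <- if (inherits(catalogue, "cin_catalogue")) catalogue$gene
           else as.character(catalogue)
  o <- unique(as.data.frame(orthology)[, c("yeast_orf", "human_symbol", "kind")])
  o$human_symbol <- normalize_symbol(o$human_symbol)
  o <- o[o$yeast_orf %in% genes, , drop = FALSE]
  unmapped <- setdiff(genes, o$yeast_orf)
  if (nrow(o) == 0L) {
    df <- data.frame(human_gene = character(), n_support = integer(),
                     stringsAsFactors = FALSE)
    df$support <- list(); df$kinds <- list()
    return(new_candidate_set(df[, c("human_gene", "support", "kinds", "n_support")],
                             "ORTHOLOGY", unmapped = unmapped))
  }
  genes <- sort(unique(o$human_symbol))
  fac <- factor(o$human_symbol, levels = genes)
  support <- lapply(split(o$yeast_orf, fac), function(x) sort(unique(x)))
  kinds <- lapply(split(o$kind, fac), function(x) sort(unique(x)))
  df <- data.frame(human_gene = genes, stringsAsFactors = FALSE)
  df$support <- unname(support)
  df$kinds <- unname(kinds)
  df$n_support <- lengths(df$support)
  new_candidate_set(df, "ORTHOLOGY", unmapped = unmapped)
}

#' Project enriched terms onto human candidate genes
#'
#' Selects enriched terms whose fold enrichment meets `fold_min`
#' (inclusive) and collects every human gene annotated to at least one
#' selected term. The association count is the total number of
#' (gene, selected term) pairs; the number of selected terms contributing
#' at least one human gene is reported in the `n_terms` attribute.
#'
#' @param enrichments An `enrichment_result` data frame.
#' @param human_annots A closed `annotation_set` over the same term-id
#'   space, mapping human symbols to terms.
#' @param fold_min Minimum fold enrichment, inclusive; default 3.
#' @return A data frame of class `candidate_set` (method `"GO_TERM"`) with
#'   columns `human_gene`, `support` (list of supporting term ids),
#'   `n_support`.
#' @export
project_go_terms <- function(enrichments, human_annots, fold_min = 3.0) {
  if (!is.numeric(fold_min) || length(fold_min) != 1L || fold_min < 0) {
    stop("fold_min must be a single non-negative number", call. = FALSE)
  }
  stopifnot(inherits(human_annots, "annotation_set"))
  sel <- enrichments$term[enrichments$enriched & enrichments$fold >= fold_min]
  ann <- human_annots$annotations
  support <- lapply(ann, function(ts) sort(intersect(ts, sel)))
  support <- support[lengths(support) > 0L]
  genes <- normalize_symbol(names(support))
  ord <- order(genes)
  df <- data.frame(human_gene = genes[ord], stringsAsFactors = FALSE)
  df$support <- unname(support[ord])
  df$n_support <- lengths(df$support)
  assoc <- sum(df$n_support)
  n_terms <- length(unique(unlist(df$support, use.names = FALSE)))
  new_candidate_set(df, "GO_TERM", association_count = as.integer(assoc),
                    n_terms = as.integer(n_terms))
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate set (%s): %d human genes", attr(x, "method"), nrow(x)))
  if (!is.na(attr(x, "association_count"))) {
    cat(sprintf(", %d associations over %d terms",
                attr(x, "association_count"), attr(x, "n_terms")))
  }
  cat("\n")
  invisible(x)
}

#' Overlap between two candidate sets
#'
#' @param a,b `candidate_set` objects (or plain character vectors of
#'   symbols) in the same symbol namespace.
#' @return A list: `n_a`, `n_b`, `n_intersect`, `n_union`, `jaccard`
#'   (defined as 0 when both sets are empty).
#' @export
overlap_summary <- function(a, b) {
  ga <- if (inherits(a, "candidate_set")) a$human_gene else normalize_symbol(a)
  gb <- if (inherits(b, "candidate_set")) b$human_gene else normalize_symbol(b)
  ga <- unique(ga); gb <- unique(gb)
  ni <- length(intersect(ga, gb))
  nu <- length(union(ga, gb))
  list(n_a = length(ga), n_b = length(gb), n_intersect = ni, n_union = nu,
       jaccard = if (nu == 0L) 0 else ni / nu)
}

#' Write a candidate set to a tab-delimited file
#' @param candidates A `candidate_set`.
#' @param path Output path.
#' @export
write_candidates <- function(candidates, path) {
  df <- data.frame(human_gene = candidates$human_gene,
                   method = rep(attr(candidates, "method"),
                                length(candidates$human_gene)),
                   evidence = vapply(candidates$support, paste, character(1L),
                                     collapse = ";"),
                   n_support = candidates$n_support,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
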