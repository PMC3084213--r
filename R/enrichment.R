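# Term over-representation analysis.
#
# For each ontology term with at least one annotated study gene, the
# upper tail of the hypergeometric distribution gives the probability of
# drawing at least k term-annotated genes in a study set of size n from a
# background of N genes of which K carry the term. Family-wise error is
# controlled by Bonferroni over the terms actually tested (the convention
# of the GO term-finder tools), optionally over the whole ontology.

#' Exact hypergeometric upper tail
#'
#' Computes `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability
#' that a size-`n` draw without replacement from `N` objects, `K` of which
#' are marked, contains at least `k` marked objects. The sum is accumulated
#' in log space from binomial coefficients, independent of
#' `stats::phyper()`.
#'
#' @param k Observed count of marked objects in the draw.
#' @param K Number of marked objects in the population.
#' @param n Draw size.
#' @param N Population size.
#' @return The tail probability, a number in \[0, 1\].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1L, length(K) == 1L, length(n) == 1L, length(N) == 1L)
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(n, K)) {
    stop(sprintf("invalid hypergeometric counts: k=%d K=%d n=%d N=%d",
                 k, K, n, N), call. = FALSE)
  }
  if (k == 0L) return(1.0)
  i <- seq.int(k, min(n, K))
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1.0, exp(logsumexp(lp)))
}

#' Term enrichment of a study gene set
#'
#' Tests every ontology term carried by at least one study gene for
#' over-representation relative to the background, using the exact
#' hypergeometric upper tail. The background size `N` counts all background
#' genes whether annotated or not (every gene is implicitly annotated to
#' its namespace root, so root terms get `K = N`). Bonferroni correction
#' multiplies by the number of terms tested (`correct_by = "tested"`, the
#' default) or by the number of terms in the ontology
#' (`correct_by = "ontology"`).
#'
#' @param study Character vector of study gene ids; must be a subset of
#'   `background`.
#' @param background Character vector of background gene ids (all genes
#'   screened).
#' @param dag An `ontology_dag`.
#' @param annots A closed `annotation_set` (see
#'   [propagate_annotations()]).
#' @param alpha Family-wise significance level for the `enriched` flag.
#' @param correct_by Bonferroni denominator convention.
#' @return A data frame of class `enrichment_result`, one row per tested
#'   term: `term`, `name`, `namespace`, `k`, `n`, `K`, `N`, `p_raw`,
#'   `p_bonf`, `fold`, `enriched`, sorted by `p_raw` then term id.
#' @export
compute_enrichment <- function(study, background, dag, annots,
                               alpha = 0.05,
                               correct_by = c("tested", "ontology")) {
  correct_by <- match.arg(correct_by)
  stopifnot(inherits(dag, "ontology_dag"), inherits(annots, "annotation_set"))
  if (!annots$closed) {
    stop("annotation set must be closed (run propagate_annotations first)",
         call. = FALSE)
  }
  study <- unique(study)
  background <- unique(background)
  extra <- setdiff(study, background)
  if (length(extra) > 0L) {
    stop("study genes absent from background: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  empty <- data.frame(term = character(), name = character(),
                      namespace = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p_raw = numeric(),
                      p_bonf = numeric(), fold = numeric(),
                      enriched = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_result", "data.frame")
  if (length(study) == 0L) return(empty)

  N <- length(background)
  n <- length(study)
  ann <- annots$annotations
  # every background gene is implicitly annotated to its namespace root(s)
  count_terms <- function(genes) {
    terms <- unlist(ann[intersect(genes, names(ann))], use.names = FALSE)
    tab <- table(terms)
    counts <- stats::setNames(as.integer(tab), names(tab))
    for (r in dag$roots) counts[r] <- length(genes)
    counts
  }
  k_tab <- count_terms(study)
  K_tab <- count_terms(background)
  tested <- names(k_tab)[k_tab >= 1L]
  # only terms present in the ontology are testable
  tested <- intersect(tested, dag$terms$id)
  if (length(tested) == 0L) return(empty)
  K <- K_tab[tested]
  K[is.na(K)] <- 0L
  k <- k_tab[tested]
  # a study gene annotated to a term forces K >= k by closure
  p_raw <- vapply(seq_along(tested), function(i) {
    hypergeometric_tail(k[[i]], K[[i]], n, N)
  }, numeric(1L))
  Tn <- if (correct_by == "tested") length(tested) else nrow(dag$terms)
  p_bonf <- pmin(1.0, p_raw * Tn)
  fold <- (k / n) / (K / N)
  m <- match(tested, dag$terms$id)
  out <- data.frame(term = tested, name = dag$terms$name[m],
                    namespace = dag$terms$namespace[m],
                    k = as.integer(k), n = n, K = as.integer(K), N = N,
                    p_raw = p_raw, p_bonf = p_bonf, fold = fold,
                    enriched = p_bonf < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Per-namespace enriched-term counts
#'
#' @param enrichment An `enrichment_result` data frame.
#' @return Named integer vector of enriched-term counts per namespace.
#' @export
enrichment_by_namespace <- function(enrichment) {
  e <- enrichment[enrichment$enriched, , drop = FALSE]
  tab <- table(factor(e$namespace, levels = GO_NAMESPACES))
  stats::setNames(as.integer(tab), names(tab))
}

#' Write an enrichment table
#' @param enrichment An `enrichment_result`.
#' @param path Output path.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(as.data.frame(enrichment), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
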