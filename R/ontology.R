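# Ontology parsing and annotation propagation.
#
# The ontology is a rooted DAG of terms connected by is_a and part_of
# edges. Gene annotations obey the true-path rule: a gene annotated to a
# term is implicitly annotated to every ancestor, so annotation sets are
# closed under ancestor propagation before any counting.

GO_NAMESPACES <- c("biological_process", "molecular_function",
                   "cellular_component")

new_ontology_dag <- function(terms, edges) {
  parents <- split(seq_len(nrow(edges)), factor(edges$child, levels = terms$id))
  parents <- lapply(parents, function(i) edges$parent[i])
  roots <- terms$id[lengths(parents) == 0L]
  structure(list(terms = terms, edges = edges,
                 parents = stats::setNames(parents, terms$id), roots = roots),
            class = "ontology_dag")
}

#' Parse an OBO 1.2 ontology file
#'
#' Reads `[Term]` stanzas (id, name, namespace, `is_a:` lines and
#' `relationship: part_of` lines). Obsolete terms are dropped together with
#' any edges touching them. The result must be acyclic with exactly one
#' root (parentless term) per namespace present.
#'
#' @param path Path to an OBO 1.2 text file.
#' @return An object of class `ontology_dag` with elements `terms`
#'   (data frame: id, name, namespace), `edges` (child, parent, relation)
#'   and `roots`.
#' @export
parse_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "[Term]")
  if (length(starts) == 0L) stop("no [Term] stanzas found in ", path, call. = FALSE)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); names_ <- character(0); ns <- character(0)
  e_child <- character(0); e_parent <- character(0); e_rel <- character(0)
  for (s in seq_along(starts)) {
    block <- lines[(bounds[s] + 1L):(bounds[s + 1L] - 1L)]
    # stanza ends at the next blank [Typedef]/[Instance] header if present
    stop_at <- grep("^\\[", block)
    if (length(stop_at) > 0L) block <- block[seq_len(stop_at[1L] - 1L)]
    getv <- function(tag) {
      hit <- grep(paste0("^", tag, ":"), block, value = TRUE)
      sub("\\s*!.*$", "", sub(paste0("^", tag, ":\\s*"), "", hit))
    }
    id <- getv("id")
    if (length(id) == 0L) stop("OBO stanza without id near line ", starts[s], call. = FALSE)
    obsolete <- any(grepl("^is_obsolete:\\s*true", block))
    if (obsolete) next
    ids <- c(ids, trimws(id[1L]))
    nm <- getv("name"); names_ <- c(names_, if (length(nm)) trimws(nm[1L]) else NA_character_)
    n <- getv("namespace"); ns <- c(ns, if (length(n)) trimws(n[1L]) else NA_character_)
    isa <- trimws(getv("is_a"))
    rel <- grep("^relationship:\\s*part_of\\s", block, value = TRUE)
    po <- trimws(sub("\\s*!.*$", "", sub("^relationship:\\s*part_of\\s+", "", rel)))
    if (length(isa) > 0L) {
      e_child <- c(e_child, rep(trimws(id[1L]), length(isa)))
      e_parent <- c(e_parent, isa); e_rel <- c(e_rel, rep("is_a", length(isa)))
    }
    if (length(po) > 0L) {
      e_child <- c(e_child, rep(trimws(id[1L]), length(po)))
      e_parent <- c(e_parent, po); e_rel <- c(e_rel, rep("part_of", length(po)))
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate term id: ", ids[which(duplicated(ids))[1L]], call. = FALSE)
  }
  terms <- data.frame(id = ids, name = names_, namespace = ns,
                      stringsAsFactors = FALSE)
  # a parent absent from `ids` may be an obsolete term (edge silently
  # dropped) or genuinely undeclared (error); the raw id: lines tell them apart
  all_declared <- unique(trimws(sub("\\s*!.*$", "",
                    sub("^id:\\s*", "", grep("^id:", lines, value = TRUE)))))
  undeclared <- setdiff(setdiff(e_parent, ids), all_declared)
  if (length(undeclared) > 0L) {
    stop("edge references undeclared term(s): ",
         paste(utils::head(undeclared, 5L), collapse = ", "), call. = FALSE)
  }
  keep <- e_parent %in% ids
  edges <- data.frame(child = e_child[keep], parent = e_parent[keep],
                      relation = e_rel[keep], stringsAsFactors = FALSE)
  edges <- unique(edges)
  assert_acyclic(terms$id, edges)
  dag <- new_ontology_dag(terms, edges)
  ns_roots <- terms$namespace[match(dag$roots, terms$id)]
  for (nsp in unique(stats::na.omit(terms$namespace))) {
    nroot <- sum(ns_roots == nsp, na.rm = TRUE)
    if (nroot != 1L) {
      stop(sprintf("namespace '%s' has %d roots; expected exactly one",
                   nsp, nroot), call. = FALSE)
    }
  }
  dag
}

# Kahn topological sort; stops naming a term on the first detected cycle
assert_acyclic <- function(ids, edges) {
  indeg <- table(factor(edges$child, levels = ids))
  indeg <- stats::setNames(as.integer(indeg), ids)
  kids <- split(edges$child, factor(edges$parent, levels = ids))
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0L) {
    v <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (c in kids[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  if (seen < length(ids)) {
    stop("ontology contains a cycle involving: ",
         paste(utils::head(ids[indeg > 0L], 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology DAG: %d terms, %d edges, root(s): %s\n",
              nrow(x$terms), nrow(x$edges), paste(x$roots, collapse = ", ")))
  invisible(x)
}

#' Ancestors of ontology terms
#'
#' Returns, for each requested term, the set of its ancestors (terms
#' reachable via is_a / part_of edges), excluding the term itself.
#'
#' @param dag An `ontology_dag`.
#' @param ids Term ids; defaults to all terms.
#' @return A named list of character vectors.
#' @export
term_ancestors <- function(dag, ids = dag$terms$id) {
  cache <- ancestor_closure(dag)
  cache[ids]
}

# full ancestor closure, memoized bottom-up over a topological order
ancestor_closure <- function(dag) {
  ids <- dag$terms$id
  parents <- dag$parents
  anc <- vector("list", length(ids))
  names(anc) <- ids
  done <- stats::setNames(rep(FALSE, length(ids)), ids)
  visit <- function(id) {
    if (done[[id]]) return(anc[[id]])
    ps <- parents[[id]]
    res <- character(0)
    for (p in ps) res <- c(res, p, visit(p))
    res <- unique(res)
    anc[[id]] <<- res
    done[[id]] <<- TRUE
    res
  }
  for (id in ids) visit(id)
  anc
}

#' Construct an annotation set
#'
#' @param mapping Named list: gene id -> character vector of term ids, or a
#'   two-column data frame (gene, term).
#' @param closed Whether the mapping is already closed under ancestor
#'   propagation.
#' @return An object of class `annotation_set`.
#' @export
annotation_set <- function(mapping, closed = FALSE) {
  if (is.data.frame(mapping)) {
    stopifnot(ncol(mapping) >= 2L)
    mapping <- split(as.character(mapping[[2L]]), mapping[[1L]])
  }
  mapping <- lapply(mapping, function(x) unique(as.character(x)))
  structure(list(annotations = mapping, closed = closed),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation set: %d genes, %d gene-term pairs (%s)\n",
              length(x$annotations), sum(lengths(x$annotations)),
              if (x$closed) "closed" else "raw"))
  invisible(x)
}

#' Read gene-term annotations from a GAF 2.x file
#'
#' Uses columns 2 (object id) and 5 (term id); `!` comment lines are
#' skipped. An optional exclusion list of evidence codes (column 7) filters
#' annotations before loading; by default nothing is excluded.
#'
#' @param path Path to a GAF file.
#' @param exclude_evidence Character vector of evidence codes to drop
#'   (e.g. `"IEA"`).
#' @return A raw (unclosed) `annotation_set`.
#' @export
read_gaf <- function(path, exclude_evidence = character(0)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (length(lines) == 0L) return(annotation_set(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 7L
  if (!all(ok)) stop("GAF line with fewer than 7 columns at data line ",
                     which(!ok)[1L], call. = FALSE)
  gene <- vapply(parts, `[[`, character(1L), 2L)
  term <- vapply(parts, `[[`, character(1L), 5L)
  evid <- vapply(parts, `[[`, character(1L), 7L)
  keep <- !(evid %in% exclude_evidence)
  annotation_set(data.frame(gene = gene[keep], term = term[keep],
                            stringsAsFactors = FALSE))
}

#' Read gene-term annotations from a minimal two-column TSV
#'
#' Headerless tab-delimited dialect: column 1 gene id, column 2 term id.
#'
#' @param path Path to the TSV file.
#' @return A raw (unclosed) `annotation_set`.
#' @export
read_gene_term_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(annotation_set(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2L
  if (!all(ok)) stop("annotation line without two columns at line ",
                     which(!ok)[1L], call. = FALSE)
  annotation_set(data.frame(
    gene = vapply(parts, `[[`, character(1L), 1L),
    term = vapply(parts, `[[`, character(1L), 2L),
    stringsAsFactors = FALSE))
}

#' Write annotations as a two-column TSV
#' @param annots An `annotation_set`.
#' @param path Output path.
#' @export
write_gene_term_tsv <- function(annots, path) {
  genes <- rep(names(annots$annotations), lengths(annots$annotations))
  terms <- unlist(annots$annotations, use.names = FALSE)
  writeLines(paste(genes, terms, sep = "\t"), path)
  invisible(path)
}

#' Close an annotation set under ancestor propagation
#'
#' Applies the true-path rule: each gene's term set is replaced by the
#' union of its raw terms and all of their ancestors through is_a and
#' part_of edges. Idempotent.
#'
#' @param dag An `ontology_dag`.
#' @param annots An `annotation_set` whose terms all occur in `dag`.
#' @return A closed `annotation_set`.
#' @export
propagate_annotations <- function(dag, annots) {
  stopifnot(inherits(dag, "ontology_dag"), inherits(annots, "annotation_set"))
  used <- unique(unlist(annots$annotations, use.names = FALSE))
  unknown <- setdiff(used, dag$terms$id)
  if (length(unknown) > 0L) {
    offenders <- unlist(lapply(names(annots$annotations), function(g) {
      bad <- intersect(annots$annotations[[g]], unknown)
      if (length(bad)) paste(g, bad, sep = " -> ") else character(0)
    }))
    stop("annotations reference unknown term(s): ",
         paste(utils::head(offenders, 5L), collapse = "; "), call. = FALSE)
  }
  anc <- ancestor_closure(dag)
  closed <- lapply(annots$annotations, function(ts) {
    sort(unique(c(ts, unlist(anc[ts], use.names = FALSE))))
  })
  annotation_set(closed, closed = TRUE)
}

#' Export the ontology edge list for external plotting
#'
#' Writes a TSV (child, parent, relation) suitable for network-drawing
#' tools.
#'
#' @param dag An `ontology_dag`.
#' @param path Output path.
#' @export
write_dag_edges <- function(dag, path) {
  utils::write.table(dag$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an ontology in OBO 1.2 format
#'
#' Minimal writer used by the simulator so generated ontologies round-trip
#' through [parse_obo()].
#'
#' @param dag An `ontology_dag`.
#' @param path Output path.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", dag$terms$name[i]), con)
    writeLines(paste0("namespace: ", dag$terms$namespace[i]), con)
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      if (e$relation[j] == "is_a") {
        writeLines(paste0("is_a: ", e$parent[j]), con)
      } else {
        writeLines(paste0("relationship: part_of ", e$parent[j]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}
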