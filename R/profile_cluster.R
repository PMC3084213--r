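# Genetic-interaction (SGA) profile clustering.
#
# Query mutants are described by their vectors of interaction scores
# against an array of mutants. Profiles are compared by correlation
# distance over pairwise-complete columns and clustered by unweighted
# average linkage (UPGMA) with deterministic lexicographic tie-breaking,
# the procedure of the classical Cluster 3.0 workflow.

#' Read a genetic-interaction score matrix
#'
#' Tab-delimited: first column holds query labels, the header row names
#' the array genes, empty cells are missing scores.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix (queries x array genes) with dimnames.
#' @export
read_interaction_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (ncol(df) < 2L) stop("interaction matrix needs a label column and >= 1 score column",
                          call. = FALSE)
  labels <- as.character(df[[1L]])
  if (anyDuplicated(labels)) stop("duplicate query labels in interaction matrix",
                                  call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- labels
  m
}

#' Write an interaction matrix in the package's TSV dialect
#' @param matrix Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_interaction_matrix <- function(matrix, path) {
  df <- data.frame(query = rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Correlation distance between interaction profiles
#'
#' `d(i, j) = 1 - r(i, j)` where `r` is the Pearson correlation
#' (`metric = "centered"`, the default) or the uncentered correlation
#' (cosine of the raw vectors, `metric = "uncentered"`), computed over the
#' columns where both rows are non-missing. Every row pair must share at
#' least `min_overlap` complete columns and have non-zero variance (or
#' norm) over the shared columns.
#'
#' @param matrix Numeric matrix, rows = query profiles; `NA` allowed.
#' @param metric Correlation flavour; Cluster 3.0 offers both.
#' @param min_overlap Minimum pairwise-complete columns, default 3.
#' @return A symmetric distance matrix with zero diagonal, entries in
#'   \[0, 2\].
#' @export
correlation_distance <- function(matrix, metric = c("centered", "uncentered"),
                                 min_overlap = 3L) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(matrix), nrow(matrix) >= 2L)
  labs <- rownames(matrix)
  if (is.null(labs)) labs <- paste0("R", seq_len(nrow(matrix)))
  n <- nrow(matrix)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- !is.na(matrix[i, ]) & !is.na(matrix[j, ])
      if (sum(ok) < min_overlap) {
        stop(sprintf("rows '%s' and '%s' share only %d complete column(s); need >= %d",
                     labs[i], labs[j], sum(ok), min_overlap), call. = FALSE)
      }
      x <- matrix[i, ok]; y <- matrix[j, ok]
      if (metric == "centered") {
        if (stats::sd(x) == 0 || stats::sd(y) == 0) {
          stop(sprintf("zero variance over the overlap of rows '%s' and '%s'",
                       labs[i], labs[j]), call. = FALSE)
        }
        r <- stats::cor(x, y)
      } else {
        nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
        if (nx == 0 || ny == 0) {
          stop(sprintf("zero norm over the overlap of rows '%s' and '%s'",
                       labs[i], labs[j]), call. = FALSE)
        }
        r <- sum(x * y) / (nx * ny)
      }
      d[i, j] <- d[j, i] <- 1 - r
    }
  }
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerates the closest pair at each step; the distance from a merged
#' cluster to any other cluster is the size-weighted mean of its members'
#' distances (unweighted average linkage, so heights are monotone
#' non-decreasing). Ties on the minimum distance are broken by the
#' lexicographic order of the sorted (node a, node b) id pair. Internal
#' nodes are labelled `N1, N2, ...` in merge order.
#'
#' @param dist Symmetric non-negative distance matrix with labelled rows.
#' @return An object of class `linkage_tree`: `merges` (data frame
#'   `node_a`, `node_b`, `height`, `new_node_id`), `leaves`, and
#'   `members` (leaf sets of every internal node).
#' @export
average_linkage <- function(dist) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  if (any(is.na(dist))) stop("distance matrix contains NA", call. = FALSE)
  if (any(dist < 0)) stop("distance matrix has negative entries", call. = FALSE)
  if (max(abs(dist - t(dist))) > 1e-12) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  labs <- rownames(dist)
  if (is.null(labs)) labs <- paste0("R", seq_len(nrow(dist)))
  n <- length(labs)
  if (n < 2L) stop("need at least two rows to cluster", call. = FALSE)
  active <- labs
  sizes <- stats::setNames(rep(1L, n), labs)
  members <- stats::setNames(as.list(labs), labs)
  D <- dist
  dimnames(D) <- list(labs, labs)
  merges <- data.frame(node_a = character(n - 1L), node_b = character(n - 1L),
                       height = numeric(n - 1L),
                       new_node_id = character(n - 1L),
                       stringsAsFactors = FALSE)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    # find the minimum off-diagonal distance, ties by sorted id pair
    best <- NULL; best_d <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        a <- active[i]; b <- active[j]
        dij <- D[a, b]
        pair <- sort(c(a, b))
        if (dij < best_d ||
            (dij == best_d &&
             (pair[1L] < best[1L] ||
              (pair[1L] == best[1L] && pair[2L] < best[2L])))) {
          best <- pair; best_d <- dij
        }
      }
    }
    a <- best[1L]; b <- best[2L]
    new_id <- paste0("N", step)
    others <- setdiff(active, c(a, b))
    # Lance-Williams update for unweighted average linkage
    new_row <- stats::setNames(numeric(length(others)), others)
    for (o in others) {
      new_row[o] <- (sizes[a] * D[a, o] + sizes[b] * D[b, o]) /
        (sizes[a] + sizes[b])
    }
    D2 <- matrix(0, length(others) + 1L, length(others) + 1L,
                 dimnames = list(c(others, new_id), c(others, new_id)))
    if (length(others) > 0L) {
      D2[others, others] <- D[others, others]
      D2[new_id, others] <- new_row
      D2[others, new_id] <- new_row
    }
    D <- D2
    sizes[new_id] <- sizes[a] + sizes[b]
    members[[new_id]] <- sort(c(members[[a]], members[[b]]))
    active <- c(others, new_id)
    merges[step, ] <- list(a, b, best_d, new_id)
  }
  structure(list(merges = merges, leaves = labs,
                 members = members[grep("^N", names(members))]),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat(sprintf("average-linkage tree: %d leaves, %d merges, max height %.4f\n",
              length(x$leaves), nrow(x$merges), max(x$merges$height)))
  invisible(x)
}

#' Cut a linkage tree into k clusters
#'
#' Removes the `k - 1` last (highest) merges and returns the membership of
#' every leaf in the remaining connected clusters.
#'
#' @param tree A `linkage_tree`.
#' @param n_clusters Number of clusters, between 1 and the leaf count.
#' @return Named integer vector: cluster index (1-based, in order of first
#'   leaf appearance) per leaf.
#' @export
cut_linkage <- function(tree, n_clusters) {
  n <- length(tree$leaves)
  stopifnot(n_clusters >= 1L, n_clusters <= n)
  keep <- seq_len(n - n_clusters)   # heights are non-decreasing
  parent <- stats::setNames(tree$leaves, tree$leaves)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in keep) {
    a <- tree$merges$node_a[i]; b <- tree$merges$node_b[i]
    id <- tree$merges$new_node_id[i]
    parent[[id]] <- id
    ra <- if (a %in% names(parent)) find(a) else a
    rb <- if (b %in% names(parent)) find(b) else b
    parent[[ra]] <- id; parent[[rb]] <- id
  }
  roots <- vapply(tree$leaves, function(l) find(l), character(1L))
  stats::setNames(as.integer(factor(roots, levels = unique(roots))),
                  tree$leaves)
}

#' Do a set of queries fall in one cluster?
#'
#' Cuts the tree into `n_clusters` and reports whether all the named
#' queries share a cluster.
#'
#' @param tree A `linkage_tree`.
#' @param queries Leaf labels of interest.
#' @param n_clusters Number of clusters for the cut.
#' @return A list: `together` (logical) and `assignment` (the full cut).
#' @export
cocluster <- function(tree, queries, n_clusters) {
  unknown <- setdiff(queries, tree$leaves)
  if (length(unknown) > 0L) {
    stop("unknown query label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  assignment <- cut_linkage(tree, n_clusters)
  together <- length(unique(assignment[queries])) == 1L
  list(together = together, assignment = assignment)
}

#' Array genes shared between query interaction profiles
#'
#' An array gene is an interaction for a query when its absolute score
#' meets the cutoff (`side = "both"`, default), or when the signed score
#' passes the cutoff (`side = "negative"` for synthetic sick/lethal,
#' `side = "positive"` for suppression). Returns the genes that are
#' interactions for at least two queries, plus per-pair shared gene lists.
#'
#' @param matrix Numeric matrix (queries x array genes), `NA` allowed.
#' @param score_cutoff Positive threshold on the interaction score.
#' @param side Which tail of the score distribution counts.
#' @return A list: `shared_genes` (each counted once however many queries
#'   share it), `n_shared`, `per_pair` (named list `"q1|q2"`).
#' @export
shared_hits <- function(matrix, score_cutoff,
                        side = c("both", "negative", "positive")) {
  side <- match.arg(side)
  stopifnot(is.numeric(score_cutoff), score_cutoff > 0)
  hit <- switch(side,
                both = abs(matrix) >= score_cutoff,
                negative = matrix <= -score_cutoff,
                positive = matrix >= score_cutoff)
  hit[is.na(hit)] <- FALSE
  counts <- colSums(hit)
  shared <- colnames(matrix)[counts >= 2L]
  labs <- rownames(matrix)
  per_pair <- list()
  if (nrow(matrix) >= 2L) {
    for (i in seq_len(nrow(matrix) - 1L)) {
      for (j in (i + 1L):nrow(matrix)) {
        g <- colnames(matrix)[hit[i, ] & hit[j, ]]
        if (length(g) > 0L) {
          per_pair[[paste(labs[i], labs[j], sep = "|")]] <- g
        }
      }
    }
  }
  list(shared_genes = shared, n_shared = length(shared), per_pair = per_pair)
}

#' Export a linkage tree in newick-like text form
#'
#' Nested parentheses with branch lengths derived from merge heights
#' (leaf branch length = merge height / 2 under the ultrametric
#' interpretation).
#'
#' @param tree A `linkage_tree`.
#' @return A single newick string terminated by `;`.
#' @export
linkage_newick <- function(tree) {
  height <- stats::setNames(rep(0, length(tree$leaves)), tree$leaves)
  label <- stats::setNames(tree$leaves, tree$leaves)
  for (i in seq_len(nrow(tree$merges))) {
    a <- tree$merges$node_a[i]; b <- tree$merges$node_b[i]
    h <- tree$merges$height[i]; id <- tree$merges$new_node_id[i]
    label[[id]] <- sprintf("(%s:%.6g,%s:%.6g)",
                           label[[a]], (h - height[[a]]) / 2,
                           label[[b]], (h - height[[b]]) / 2)
    height[[id]] <- h
  }
  paste0(label[[tree$merges$new_node_id[nrow(tree$merges)]]], ";")
}
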