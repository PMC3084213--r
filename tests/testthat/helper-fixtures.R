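# Fixture builders shared across test files. Everything is generated in
# code; files are written to tempdir() on demand.

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# screen-hit table text with header
screen_tsv <- function(rows) {
  write_lines_tmp(c("gene\tassay\tstrength\tsource", rows))
}

# gene metadata text; genes is a data.frame-like list
meta_tsv <- function(gene, essential, nuclear = TRUE, verified = TRUE) {
  df <- data.frame(gene = gene, essential = essential, nuclear = nuclear,
                   verified_orf = verified)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a small OBO document from an edge list (child, parent, relation)
obo_text <- function(ids, edges, namespace = "biological_process",
                     obsolete = character(0)) {
  out <- c("format-version: 1.2", "")
  for (id in ids) {
    out <- c(out, "[Term]", paste0("id: ", id), paste0("name: term ", id),
             paste0("namespace: ", namespace))
    if (id %in% obsolete) out <- c(out, "is_obsolete: true")
    if (!is.null(edges) && nrow(edges) > 0) {
      e <- edges[edges$child == id, , drop = FALSE]
      for (i in seq_len(nrow(e))) {
        out <- c(out, if (e$relation[i] == "is_a")
          paste0("is_a: ", e$parent[i])
          else paste0("relationship: part_of ", e$parent[i]))
      }
    }
    out <- c(out, "")
  }
  write_lines_tmp(out, ".obo")
}

edge_df <- function(child, parent, relation = "is_a") {
  data.frame(child = child, parent = parent, relation = relation,
             stringsAsFactors = FALSE)
}

# chain c -> b -> a rooted DAG used in several tests
chain_dag <- function() {
  parse_obo(obo_text(c("A", "B", "C"),
                     edge_df(c("B", "C"), c("A", "B"))))
}

# diamond: D -> B -> A, D -> C -> A
diamond_dag <- function() {
  parse_obo(obo_text(c("A", "B", "C", "D"),
                     edge_df(c("B", "C", "D", "D"),
                             c("A", "A", "B", "C"))))
}

# brute-force hypergeometric upper tail by exhaustive enumeration of all
# draws (only feasible for small N); the independent oracle for the
# implementation's log-space sum
hyper_tail_enum <- function(k, K, n, N) {
  marked <- seq_len(K)
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(draws %in% marked, nrow = n))
  mean(hits >= k)
}

# arithmetic oracle on binomial coefficients (plain double arithmetic, no
# log space), valid to ~1e-12 for N <= 60
hyper_tail_choose <- function(k, K, n, N) {
  i <- seq.int(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# brute-force UPGMA: at each step recompute every pairwise cluster
# distance as the mean over member leaf pairs of the original matrix
upgma_bruteforce <- function(d) {
  labs <- rownames(d)
  clusters <- stats::setNames(as.list(labs), labs)
  merges <- NULL
  step <- 0L
  while (length(clusters) > 1L) {
    ids <- names(clusters)
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        a <- ids[i]; b <- ids[j]
        dd <- mean(d[clusters[[a]], clusters[[b]]])
        pair <- sort(c(a, b))
        better <- dd < best_d ||
          (dd == best_d && (pair[1L] < best[1L] ||
                            (pair[1L] == best[1L] && pair[2L] < best[2L])))
        if (better) { best <- pair; best_d <- dd }
      }
    }
    step <- step + 1L
    id <- paste0("N", step)
    clusters[[id]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[1L]]] <- NULL
    clusters[[best[2L]]] <- NULL
    merges <- rbind(merges, data.frame(node_a = best[1L], node_b = best[2L],
                                       height = best_d, new_node_id = id,
                                       stringsAsFactors = FALSE))
  }
  merges
}

random_dist <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  v <- round(stats::runif(n * (n - 1) / 2, 0.05, 2), 2)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  m
}
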