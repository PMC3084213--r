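# Somatic-mutation cross-referencing.
#
# Candidate human genes are intersected with a gene-level somatic-mutation
# table (e.g. COSMIC and the Cancer Gene Census) and the mutated fraction
# is compared with a background gene population by the pooled-variance
# two-proportion z-test.

MUTATION_SOURCES <- c("COSMIC", "CENSUS")

#' Read a somatic-mutation gene table
#'
#' Tab-delimited with header columns `symbol` and `source` (COSMIC or
#' CENSUS) and an optional `version` column carried as an attribute. A
#' symbol may appear once per source; entries are aggregated to one record
#' per symbol with its set of source tags.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `mutation_table` with columns `symbol`
#'   and `sources` (list), plus a `version` attribute.
#' @export
read_mutation_table <- function(path) {
  df <- read_tsv_chr(path)
  require_cols(df, c("symbol", "source"), "mutation table")
  symbol <- normalize_symbol(df$symbol)
  source <- toupper(trimws(df$source))
  bad <- which(!(source %in% MUTATION_SOURCES))
  if (length(bad) > 0L) {
    stop(sprintf("mutation table %s: unknown source '%s' at line %d",
                 path, df$source[bad[1L]], bad[1L] + 1L), call. = FALSE)
  }
  syms <- sort(unique(symbol))
  sources <- lapply(split(source, factor(symbol, levels = syms)),
                    function(s) sort(unique(s)))
  out <- data.frame(symbol = syms, stringsAsFactors = FALSE)
  out$sources <- unname(sources)
  version <- if ("version" %in% names(df) && nrow(df) > 0L)
    df$version[1L] else NA_character_
  structure(out, class = c("mutation_table", "data.frame"), version = version)
}

#' Cross-reference candidates with a mutation table
#'
#' @param candidates A `candidate_set` or character vector of human
#'   symbols.
#' @param table A `mutation_table`.
#' @return A list: `mutated` (sorted symbols found in the table),
#'   `n_candidates`, `n_mutated`, and `per_source` counts (a candidate
#'   tagged with both sources counts once per source but once overall).
#' @export
crossref_mutations <- function(candidates, table) {
  genes <- if (inherits(candidates, "candidate_set"))
    candidates$human_gene else normalize_symbol(candidates)
  genes <- unique(genes)
  hit <- genes %in% table$symbol
  mutated <- sort(genes[hit])
  src <- table$sources[match(mutated, table$symbol)]
  per_source <- vapply(MUTATION_SOURCES, function(s) {
    sum(vapply(src, function(x) s %in% x, logical(1L)))
  }, integer(1L))
  list(mutated = mutated, n_candidates = length(genes),
       n_mutated = length(mutated), per_source = per_source)
}

#' Two-proportion z-test (pooled variance, no continuity correction)
#'
#' Tests whether the proportion `k1/n1` differs from `k2/n2` using the
#' normal approximation with pooled variance:
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` where `p` pools both
#' groups. The squared statistic equals the uncorrected Pearson chi-square
#' of the 2x2 table. When the pooled proportion is 0 or 1 the statistic is
#' undefined; a degenerate result with `p = 1` and `degenerate = TRUE` is
#' returned with a warning.
#'
#' @param k1,n1 Successes and size of group 1 (e.g. mutated candidates /
#'   candidates).
#' @param k2,n2 Successes and size of group 2 (background).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   for one-sided alternatives on `p1 - p2`.
#' @return A list of class `prop_test`: `k1`, `n1`, `k2`, `n2`, `p1`,
#'   `p2`, `pooled`, `z`, `p_value`, `alternative`, `degenerate`.
#' @export
two_proportion_ztest <- function(k1, n1, k2, n2,
                                 alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1
  p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  out <- list(k1 = k1, n1 = n1, k2 = k2, n2 = n2, p1 = p1, p2 = p2,
              pooled = pooled, alternative = alternative)
  if (pooled %in% c(0, 1)) {
    warning("pooled proportion is degenerate (0 or 1); z undefined",
            call. = FALSE)
    out$z <- NA_real_
    out$p_value <- 1.0
    out$degenerate <- TRUE
    class(out) <- "prop_test"
    return(out)
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  out$z <- z
  out$p_value <- p
  out$degenerate <- FALSE
  class(out) <- "prop_test"
  out
}

#' @export
print.prop_test <- function(x, ...) {
  cat(sprintf("two-proportion z-test (%s): p1 = %d/%d = %.4f, p2 = %d/%d = %.4f\n",
              x$alternative, x$k1, x$n1, x$p1, x$k2, x$n2, x$p2))
  if (x$degenerate) {
    cat("  degenerate (pooled proportion 0 or 1); p = 1\n")
  } else {
    cat(sprintf("  z = %.4f, p = %.4g\n", x$z, x$p_value))
  }
  invisible(x)
}
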