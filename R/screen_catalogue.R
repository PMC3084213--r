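# Screen-hit ingestion and CIN catalogue integration.
#
# A "hit" is one (gene, assay, source) observation from a marker-loss screen
# or from the literature. Hits from any number of tables are unioned into a
# per-gene catalogue, each gene gets a confidence class, and summary
# statistics (essential vs non-essential proportions, per-assay counts,
# nuclear breakdown) are derived against a screened-gene universe.

CIN_ASSAYS <- c("CTF", "ALF", "GCR", "BIM", "LOH")
CIN_STRENGTHS <- c("STRONG", "WEAK")

#' Read a screen-hit table
#'
#' Reads a tab-delimited table of chromosome-instability screen hits. The
#' header must name at least `gene`, `assay`, `strength` and `source`;
#' optional `allele` and `temperature` columns are carried through. Assays
#' are restricted to the five marker-loss phenotypes (CTF, ALF, GCR, BiM,
#' LOH) and strengths to STRONG/WEAK; any other token is a parse error that
#' names the offending line.
#'
#' @param path Path to a tab-delimited text file with a header row.
#' @return A `data.frame` of class `cin_hits` with columns `gene`, `assay`,
#'   `strength`, `source`, `allele`, `temperature`, one row per hit, in file
#'   order.
#' @export
read_screen_table <- function(path) {
  df <- read_tsv_chr(path)
  require_cols(df, c("gene", "assay", "strength", "source"), "screen table")
  n <- nrow(df)
  if (n == 0L) {
    return(new_cin_hits(data.frame(gene = character(), assay = character(),
                                   strength = character(), source = character(),
                                   allele = character(),
                                   temperature = numeric(),
                                   stringsAsFactors = FALSE)))
  }
  gene <- trimws(df$gene)
  assay <- toupper(trimws(df$assay))
  strength <- toupper(trimws(df$strength))
  source <- trimws(df$source)
  # +1 for the header row so messages cite physical line numbers
  line <- seq_len(n) + 1L
  if (any(gene == "")) {
    stop(sprintf("screen table %s: empty gene id at line %d",
                 path, line[which(gene == "")[1L]]), call. = FALSE)
  }
  bad <- which(!(assay %in% CIN_ASSAYS))
  if (length(bad) > 0L) {
    stop(sprintf("screen table %s: unknown assay '%s' at line %d (expected one of %s)",
                 path, df$assay[bad[1L]], line[bad[1L]],
                 paste(CIN_ASSAYS, collapse = "/")), call. = FALSE)
  }
  bad <- which(!(strength %in% CIN_STRENGTHS))
  if (length(bad) > 0L) {
    stop(sprintf("screen table %s: unknown strength '%s' at line %d (expected STRONG or WEAK)",
                 path, df$strength[bad[1L]], line[bad[1L]]), call. = FALSE)
  }
  key <- paste(gene, assay, source, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stop(sprintf("screen table %s: duplicate (gene, assay, source) = (%s, %s, %s) at line %d",
                 path, gene[d], assay[d], source[d], line[d]), call. = FALSE)
  }
  out <- data.frame(gene = gene, assay = assay, strength = strength,
                    source = source,
                    allele = if ("allele" %in% names(df)) trimws(df$allele) else NA_character_,
                    temperature = if ("temperature" %in% names(df))
                      suppressWarnings(as.numeric(df$temperature)) else NA_real_,
                    stringsAsFactors = FALSE)
  new_cin_hits(out)
}

new_cin_hits <- function(df) {
  class(df) <- c("cin_hits", "data.frame")
  df
}

#' Construct a screen-hit table in code
#'
#' Convenience constructor used by the simulator and by tests; applies the
#' same enumeration checks as [read_screen_table()].
#'
#' @param gene,assay,strength,source Character vectors, recycled to a common
#'   length.
#' @param allele,temperature Optional per-hit metadata.
#' @return A `cin_hits` data frame.
#' @export
cin_hits <- function(gene, assay, strength, source,
                     allele = NA_character_, temperature = NA_real_) {
  n <- length(gene)
  if (n == 0L) {
    assay <- strength <- source <- allele <- character(0)
    temperature <- numeric(0)
  }
  df <- data.frame(gene = as.character(gene), assay = toupper(as.character(assay)),
                   strength = toupper(as.character(strength)),
                   source = as.character(source),
                   allele = as.character(allele),
                   temperature = as.numeric(temperature),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$assay %in% CIN_ASSAYS), all(df$strength %in% CIN_STRENGTHS),
            all(nzchar(df$gene)))
  key <- paste(df$gene, df$assay, df$source, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (gene, assay, source) hit", call. = FALSE)
  new_cin_hits(df)
}

#' Read a gene-metadata table
#'
#' The metadata table describes the screened universe: one row per gene with
#' its essentiality, nuclear localization, verified-ORF status and an
#' optional free-text functional group.
#'
#' @param path Tab-delimited file with header columns `gene`, `essential`,
#'   `nuclear`, `verified_orf` and optionally `functional_group`.
#' @return A data frame with one row per unique gene.
#' @export
read_gene_meta <- function(path) {
  df <- read_tsv_chr(path)
  require_cols(df, c("gene", "essential", "nuclear", "verified_orf"),
               "gene metadata")
  gene <- trimws(df$gene)
  if (anyDuplicated(gene)) {
    stop(sprintf("gene metadata %s: duplicate gene id '%s'",
                 path, gene[which(duplicated(gene))[1L]]), call. = FALSE)
  }
  data.frame(gene = gene,
             essential = parse_flag(df$essential, "essential"),
             nuclear = parse_flag(df$nuclear, "nuclear"),
             verified_orf = parse_flag(df$verified_orf, "verified_orf"),
             functional_group = if ("functional_group" %in% names(df))
               trimws(df$functional_group) else NA_character_,
             stringsAsFactors = FALSE)
}

#' Integrate screen-hit tables into a CIN catalogue
#'
#' Unions the evidence from any number of hit tables into one record per
#' gene, attaches gene metadata, and assigns confidence classes. Evidence is
#' deduplicated on (gene, assay, source); when the same observation is
#' reported with both strengths, STRONG wins. Genes missing from the
#' metadata are retained with a warning and `NA` metadata; genes whose ORF
#' is not verified are retained but flagged.
#'
#' @param hit_tables A list of `cin_hits` data frames (a single table may be
#'   passed bare).
#' @param meta Gene metadata as returned by [read_gene_meta()].
#' @return A data.frame of class `cin_catalogue`: one row per gene with
#'   list-columns `assays`, `sources`, `strengths`, scalar columns
#'   `n_sources`, `any_strong`, `confidence`, and the metadata columns. The
#'   deduplicated evidence table is attached as attribute `evidence`.
#' @export
integrate_screens <- function(hit_tables, meta) {
  if (inherits(hit_tables, "data.frame")) hit_tables <- list(hit_tables)
  if (!is.list(hit_tables) || length(hit_tables) == 0L) {
    stop("integrate_screens: need at least one hit table", call. = FALSE)
  }
  hits <- do.call(rbind, lapply(hit_tables, function(h) {
    as.data.frame(h)[, c("gene", "assay", "strength", "source")]
  }))
  if (nrow(hits) > 0L) {
    # dedupe identical observations across tables; STRONG beats WEAK
    ord <- order(hits$gene, hits$assay, hits$source,
                 match(hits$strength, CIN_STRENGTHS))
    hits <- hits[ord, , drop = FALSE]
    key <- paste(hits$gene, hits$assay, hits$source, sep = "\r")
    hits <- hits[!duplicated(key), , drop = FALSE]
    rownames(hits) <- NULL
  }
  genes <- sort(unique(hits$gene))
  idx <- split(seq_len(nrow(hits)), factor(hits$gene, levels = genes))
  assays <- lapply(idx, function(i) sort(unique(hits$assay[i])))
  sources <- lapply(idx, function(i) sort(unique(hits$source[i])))
  strengths <- lapply(idx, function(i) hits$strength[i])
  cat <- data.frame(gene = genes, stringsAsFactors = FALSE)
  cat$assays <- unname(assays)
  cat$sources <- unname(sources)
  cat$strengths <- unname(strengths)
  cat$n_sources <- vapply(sources, length, integer(1L), USE.NAMES = FALSE)
  cat$any_strong <- vapply(strengths, function(s) any(s == "STRONG"),
                           logical(1L), USE.NAMES = FALSE)
  m <- match(genes, meta$gene)
  unknown <- genes[is.na(m)]
  if (length(unknown) > 0L) {
    warning(sprintf("%d catalogue gene(s) absent from metadata: %s",
                    length(unknown),
                    paste(utils::head(unknown, 5L), collapse = ", ")),
            call. = FALSE)
  }
  cat$in_meta <- !is.na(m)
  cat$essential <- meta$essential[m]
  cat$nuclear <- meta$nuclear[m]
  cat$verified_orf <- meta$verified_orf[m]
  cat$functional_group <- meta$functional_group[m]
  class(cat) <- c("cin_catalogue", "data.frame")
  hits$allele <- rep(NA_character_, nrow(hits))
  hits$temperature <- rep(NA_real_, nrow(hits))
  attr(cat, "evidence") <- new_cin_hits(hits)
  classify_confidence(cat)
}

#' Assign confidence classes to a catalogue
#'
#' A gene is HIGH confidence when it was identified by at least two
#' independent experiments (distinct source labels) or showed a strong
#' phenotype in any single one; otherwise LOW. The rule is monotone: adding
#' evidence can never demote a gene.
#'
#' @param catalogue A `cin_catalogue`.
#' @return The catalogue with its `confidence` column (re)computed.
#' @export
classify_confidence <- function(catalogue) {
  stopifnot(inherits(catalogue, "cin_catalogue"))
  if (nrow(catalogue) > 0L &&
      any(catalogue$n_sources == 0L | lengths(catalogue$strengths) == 0L)) {
    stop("catalogue record with no evidence", call. = FALSE)
  }
  catalogue$confidence <- ifelse(
    catalogue$n_sources >= 2L | catalogue$any_strong, "HIGH", "LOW")
  catalogue
}

#' Summarize a CIN catalogue against its screened universe
#'
#' Computes the headline proportions: how many essential and non-essential
#' genes of the screened universe are in the catalogue, the fraction of
#' high-confidence records, per-assay gene counts, and a nuclear versus
#' non-nuclear strength breakdown. Percentages follow the reporting
#' convention of rounding to the nearest integer at or above 10% and to one
#' decimal below.
#'
#' @param catalogue A `cin_catalogue`.
#' @param universe Gene metadata for the screened universe (all genes
#'   assayed, hit or not), as from [read_gene_meta()].
#' @return A list of class `cin_summary`.
#' @export
catalogue_summary <- function(catalogue, universe) {
  stopifnot(inherits(catalogue, "cin_catalogue"))
  ess_univ <- sum(universe$essential, na.rm = TRUE)
  non_univ <- sum(!universe$essential, na.rm = TRUE)
  m <- match(catalogue$gene, universe$gene)
  ess_flag <- universe$essential[m]
  ess_cin <- sum(ess_flag, na.rm = TRUE)
  non_cin <- sum(!ess_flag, na.rm = TRUE)
  unknown_ess <- sum(is.na(ess_flag))
  pct <- function(k, n) if (n > 0L) round_pct(100 * k / n) else NA_real_
  n_tot <- nrow(catalogue)
  per_assay <- vapply(CIN_ASSAYS, function(a) {
    sum(vapply(catalogue$assays, function(x) a %in% x, logical(1L)))
  }, integer(1L))
  nuc <- isTRUE_vec(catalogue$nuclear)
  strong <- catalogue$any_strong
  nuclear_breakdown <- c(
    nuclear_strong = sum(nuc & strong, na.rm = TRUE),
    nuclear_weak = sum(nuc & !strong, na.rm = TRUE),
    other_strong = sum(!nuc & strong, na.rm = TRUE),
    other_weak = sum(!nuc & !strong, na.rm = TRUE))
  out <- list(
    total_genes = n_tot,
    verified_genes = sum(isTRUE_vec(catalogue$verified_orf)),
    essential_cin = ess_cin, essential_universe = ess_univ,
    nonessential_cin = non_cin, nonessential_universe = non_univ,
    unknown_essentiality = unknown_ess,
    essential_pct = pct(ess_cin, ess_univ),
    nonessential_pct = pct(non_cin, non_univ),
    high_confidence = sum(catalogue$confidence == "HIGH"),
    high_confidence_fraction = if (n_tot > 0L)
      sum(catalogue$confidence == "HIGH") / n_tot else NA_real_,
    per_assay = per_assay,
    nuclear_breakdown = nuclear_breakdown)
  class(out) <- "cin_summary"
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.cin_summary <- function(x, ...) {
  cat("CIN catalogue summary\n")
  cat(sprintf("  genes: %d (%d verified ORFs)\n", x$total_genes, x$verified_genes))
  cat(sprintf("  essential: %d/%d (%s%%)   non-essential: %d/%d (%s%%)\n",
              x$essential_cin, x$essential_universe,
              format(x$essential_pct), x$nonessential_cin,
              x$nonessential_universe, format(x$nonessential_pct)))
  cat(sprintf("  high confidence: %d (%.0f%%)\n", x$high_confidence,
              100 * x$high_confidence_fraction))
  cat("  per assay:", paste(sprintf("%s=%d", names(x$per_assay), x$per_assay),
                            collapse = " "), "\n")
  invisible(x)
}

#' @export
print.cin_catalogue <- function(x, ...) {
  cat(sprintf("CIN catalogue: %d genes (%d HIGH confidence)\n",
              nrow(x), sum(x$confidence == "HIGH")))
  NextMethod()
}

#' Recover the evidence table of a catalogue
#'
#' Returns the deduplicated (gene, assay, source, strength) hit table that
#' the catalogue was integrated from, suitable for re-integration
#' (integration is idempotent).
#'
#' @param catalogue A `cin_catalogue`.
#' @return A `cin_hits` data frame.
#' @export
catalogue_evidence <- function(catalogue) {
  stopifnot(inherits(catalogue, "cin_catalogue"))
  attr(catalogue, "evidence")
}

#' Write a catalogue to a tab-delimited file
#'
#' One row per gene with semicolon-joined evidence fields.
#'
#' @param catalogue A `cin_catalogue`.
#' @param path Output path.
#' @export
write_catalogue <- function(catalogue, path) {
  join <- function(col) vapply(col, paste, character(1L), collapse = ";")
  df <- data.frame(gene = catalogue$gene,
                   assays = join(catalogue$assays),
                   sources = join(catalogue$sources),
                   strengths = join(catalogue$strengths),
                   n_sources = catalogue$n_sources,
                   confidence = catalogue$confidence,
                   essential = catalogue$essential,
                   nuclear = catalogue$nuclear,
                   verified_orf = catalogue$verified_orf,
                   functional_group = catalogue$functional_group,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
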