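# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# read a tab-delimited file with a header row, keeping everything character
read_tsv_chr <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE,
                    na.strings = NULL)
}

# required-column check with a uniform error message
require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# strict logical parser for metadata flags (TRUE/FALSE/1/0/yes/no, any case)
parse_flag <- function(x, column) {
  out <- rep(NA, length(x))
  lx <- tolower(trimws(x))
  out[lx %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[lx %in% c("false", "f", "0", "no", "n")] <- FALSE
  bad <- which(is.na(out) & !(lx %in% c("", "na")))
  if (length(bad) > 0L) {
    stop(sprintf("column '%s': unparseable logical value '%s' (row %d)",
                 column, x[bad[1L]], bad[1L]), call. = FALSE)
  }
  as.logical(out)
}

# uppercase + whitespace-strip normalization for human gene symbols
normalize_symbol <- function(x) toupper(trimws(x))

# percent formatted the way the source literature prints it:
# nearest integer at >= 10%, one decimal place below 10%
round_pct <- function(p) {
  ifelse(is.na(p), NA_real_, ifelse(p >= 10, round(p), round(p, 1)))
}

# log-sum-exp, numerically stable
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# derive a generator-specific seed from the master seed so that the random
# stream is partitioned per generator (changing one config block must not
# perturb the other generators' outputs)
derive_seed <- function(seed, label) {
  offs <- c(ontology = 104729L, screens = 224737L, downstream = 350377L,
            meta = 479909L)
  off <- offs[[label]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}
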