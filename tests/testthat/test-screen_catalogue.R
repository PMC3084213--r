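# Catalogue ingestion, integration, confidence and summaries.

test_that("read_screen_table maps rows, validates enums and spots duplicates", {
  path <- screen_tsv(c("YPR175W\tCTF\tSTRONG\tthis_study",
                       "YOR060C\tGCR\tWEAK\tsmith2004"))
  hits <- read_screen_table(path)
  expect_s3_class(hits, "cin_hits")
  expect_equal(hits$gene, c("YPR175W", "YOR060C"))
  expect_equal(hits$assay, c("CTF", "GCR"))
  expect_equal(hits$strength, c("STRONG", "WEAK"))
  expect_equal(hits$source, c("this_study", "smith2004"))

  # header-only file -> empty table
  empty <- read_screen_table(screen_tsv(character(0)))
  expect_equal(nrow(empty), 0L)

  # enumeration violations cite the physical line
  expect_error(read_screen_table(screen_tsv("Y1\tXYZ\tSTRONG\ts1")),
               "unknown assay 'XYZ' at line 2")
  expect_error(read_screen_table(screen_tsv("Y1\tCTF\tMEDIUM\ts1")),
               "unknown strength")
  expect_error(read_screen_table(
    screen_tsv(c("Y1\tCTF\tSTRONG\ts1", "Y1\tCTF\tWEAK\ts1"))),
    "duplicate \\(gene, assay, source\\)")
})

test_that("integrate_screens unions evidence across tables", {
  meta <- read_gene_meta(meta_tsv(paste0("Y", 1:10), essential = TRUE))
  a <- cin_hits("Y1", "CTF", "WEAK", "tableA")
  b <- cin_hits("Y1", "GCR", "WEAK", "tableB")
  cat1 <- integrate_screens(list(a, b), meta)
  expect_equal(nrow(cat1), 1L)
  expect_equal(cat1$assays[[1]], c("CTF", "GCR"))
  expect_equal(cat1$sources[[1]], c("tableA", "tableB"))

  # disjoint tables of sizes 3 and 4 -> 7 records
  a <- cin_hits(paste0("Y", 1:3), "CTF", "WEAK", "A")
  b <- cin_hits(paste0("Y", 4:7), "ALF", "WEAK", "B")
  expect_equal(nrow(integrate_screens(list(a, b), meta)), 7L)

  expect_error(integrate_screens(list(), meta), "at least one")
  expect_warning(
    integrate_screens(list(cin_hits("UNKNOWN1", "CTF", "WEAK", "A")), meta),
    "absent from metadata")
})

test_that("planted fixture: 10 genes each reported by 2 of 3 screens", {
  genes <- sprintf("Y%02d", 1:10)
  meta <- read_gene_meta(meta_tsv(genes, essential = FALSE))
  # gene i is reported by screens (i mod 3) and (i+1 mod 3)
  pick <- function(i) c(i %% 3L, (i + 1L) %% 3L) + 1L
  screens <- lapply(1:3, function(s) {
    g <- genes[vapply(1:10, function(i) s %in% pick(i), logical(1))]
    cin_hits(g, c("CTF", "ALF", "GCR")[s], "WEAK", paste0("S", s))
  })
  cat_ <- integrate_screens(screens, meta)
  expect_equal(nrow(cat_), 10L)
  expect_equal(cat_$n_sources, rep(2L, 10L))
  # enumerate record-by-record against the construction rule
  for (i in 1:10) {
    rec <- cat_[cat_$gene == genes[i], ]
    expect_equal(rec$sources[[1]], paste0("S", sort(pick(i))))
  }
  # all have 2 sources -> every record HIGH
  expect_true(all(cat_$confidence == "HIGH"))
})

test_that("classify_confidence follows the two-experiments-or-strong rule", {
  meta <- read_gene_meta(meta_tsv(paste0("Y", 1:3), essential = TRUE))
  cat_ <- integrate_screens(list(
    cin_hits(c("Y1", "Y2", "Y3"), "CTF", c("WEAK", "STRONG", "WEAK"), "A"),
    cin_hits("Y3", "ALF", "WEAK", "B")), meta)
  conf <- setNames(cat_$confidence, cat_$gene)
  expect_equal(conf[["Y1"]], "LOW")    # 1 source, WEAK
  expect_equal(conf[["Y2"]], "HIGH")   # 1 source, STRONG
  expect_equal(conf[["Y3"]], "HIGH")   # 2 sources, both WEAK
})

test_that("integration is idempotent and order-invariant", {
  set.seed(11)
  genes <- sprintf("Y%03d", 1:40)
  meta <- read_gene_meta(meta_tsv(genes, essential = rep(c(TRUE, FALSE), 20)))
  tabs <- lapply(1:3, function(s) {
    g <- sample(genes, 15)
    cin_hits(g, sample(c("CTF", "ALF", "GCR"), 15, replace = TRUE),
             sample(c("STRONG", "WEAK"), 15, replace = TRUE), paste0("S", s))
  })
  cat1 <- integrate_screens(tabs, meta)
  # re-integrating the catalogue's own evidence reproduces it
  cat2 <- integrate_screens(list(catalogue_evidence(cat1)), meta)
  expect_equal(cat1, cat2, ignore_attr = "evidence")
  # permuting input tables leaves the catalogue unchanged
  cat3 <- integrate_screens(tabs[c(3, 1, 2)], meta)
  expect_equal(cat1, cat3, ignore_attr = "evidence")
})

test_that("confidence is monotone under added evidence", {
  set.seed(12)
  meta <- read_gene_meta(meta_tsv(paste0("Y", 1:20), essential = TRUE))
  base <- cin_hits(paste0("Y", 1:20), "CTF",
                   sample(c("STRONG", "WEAK"), 20, replace = TRUE), "A")
  extra <- cin_hits(paste0("Y", 1:20), "GCR",
                    sample(c("STRONG", "WEAK"), 20, replace = TRUE), "B")
  before <- integrate_screens(list(base), meta)$confidence
  after <- integrate_screens(list(base, extra), meta)$confidence
  expect_false(any(before == "HIGH" & after == "LOW"))
})

test_that("catalogue_summary reproduces printed-style proportions and reconciles", {
  # universe: 1156 essential, 4800 non-essential; catalogue: 323 + 369
  ess <- sprintf("E%04d", 1:1156)
  non <- sprintf("N%04d", 1:4800)
  meta <- read_gene_meta(meta_tsv(c(ess, non),
                                  essential = rep(c(TRUE, FALSE), c(1156, 4800))))
  hits <- cin_hits(c(ess[1:323], non[1:369]), "CTF", "WEAK", "S1")
  cat_ <- integrate_screens(list(hits), meta)
  s <- catalogue_summary(cat_, meta)
  expect_equal(s$essential_pct, 28)      # 323/1156, integer rounding >= 10%
  expect_equal(s$nonessential_pct, 7.7)  # 369/4800, one decimal < 10%
  expect_equal(s$essential_cin + s$nonessential_cin + s$unknown_essentiality,
               s$total_genes)

  # universe with no essential genes -> proportion missing, not zero
  meta2 <- read_gene_meta(meta_tsv(non[1:50], essential = FALSE))
  cat2 <- integrate_screens(list(cin_hits(non[1:5], "CTF", "WEAK", "S1")), meta2)
  s2 <- catalogue_summary(cat2, meta2)
  expect_true(is.na(s2$essential_pct))

  # empty catalogue -> zero counts, missing fractions
  cat0 <- suppressWarnings(integrate_screens(
    list(new_hits <- cin_hits(character(0), character(0), character(0),
                              character(0))), meta2))
  s0 <- catalogue_summary(cat0, meta2)
  expect_equal(s0$total_genes, 0L)
  expect_true(is.na(s0$high_confidence_fraction))
})

test_that("catalogue round-trips through its TSV writer", {
  meta <- read_gene_meta(meta_tsv(c("Y1", "Y2"), essential = c(TRUE, FALSE)))
  cat_ <- integrate_screens(list(
    cin_hits(c("Y1", "Y2"), c("CTF", "ALF"), c("STRONG", "WEAK"), "A")), meta)
  path <- tempfile(fileext = ".tsv")
  write_catalogue(cat_, path)
  back <- utils::read.delim(path)
  expect_equal(back$gene, c("Y1", "Y2"))
  expect_equal(back$confidence, c("HIGH", "LOW"))
  expect_equal(back$assays, c("CTF", "ALF"))
})
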