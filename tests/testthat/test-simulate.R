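# Synthetic-data generator: determinism, planted signal, stream partition.

test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(seed = 7, n_genes = 100, n_terms = 20, n_cin_genes = 10,
                    planted_multipliers = c(4, 4))
  a <- simulate_ontology(cfg)
  b <- simulate_ontology(cfg)
  expect_identical(a$dag, b$dag)
  expect_identical(a$annotations$annotations, b$annotations$annotations)
  expect_identical(a$truth, b$truth)
  sa <- simulate_screens(cfg, a$truth)
  sb <- simulate_screens(cfg, b$truth)
  expect_identical(sa, sb)
  da <- simulate_downstream(cfg, a)
  db <- simulate_downstream(cfg, b)
  expect_identical(da$matrix, db$matrix)
  expect_identical(da$mutations, db$mutations)
})

test_that("the random stream is partitioned per generator", {
  cfg1 <- sim_config(seed = 7, n_genes = 100, n_terms = 20, n_cin_genes = 10)
  cfg2 <- sim_config(seed = 7, n_genes = 100, n_terms = 20, n_cin_genes = 10,
                     fpr = 0.2)   # screens block changed
  a <- simulate_ontology(cfg1)
  b <- simulate_ontology(cfg2)
  expect_identical(a$dag, b$dag)  # ontology untouched by a screens knob
})

test_that("n_terms < 3 is rejected and the DAG is well formed", {
  expect_error(sim_config(n_terms = 2), "n_terms")
  cfg <- sim_config(seed = 3, n_genes = 50, n_terms = 30, n_cin_genes = 5)
  onto <- simulate_ontology(cfg)
  # single root, acyclic by construction (parents always shallower)
  expect_equal(onto$dag$roots, onto$dag$terms$id[1])
  # round-trips through the OBO layer (parse re-checks acyclicity)
  p <- tempfile(fileext = ".obo")
  write_obo(onto$dag, p)
  expect_s3_class(parse_obo(p), "ontology_dag")
})

test_that("planted annotation counts match the binomial expectation", {
  # multiplier 4 at annotation prob 0.1 over 200 CIN genes: k ~ Bin(200, 0.4)
  cfg <- sim_config(seed = 101, n_genes = 2000, n_terms = 60,
                    annotation_rate = 6, n_cin_genes = 200,
                    planted_multipliers = 4)
  onto <- simulate_ontology(cfg)
  t <- onto$truth$planted_terms
  ann <- onto$annotations$annotations
  k <- sum(vapply(onto$truth$cin_genes, function(g)
    t %in% ann[[g]], logical(1)))
  expected <- 200 * 0.4
  expect_lt(abs(k - expected), 3 * sqrt(200 * 0.4 * 0.6))
})

test_that("screen tables follow sensitivity and false-positive settings", {
  genes <- sprintf("YGS%04d", 1:200)
  cfg <- sim_config(seed = 9, n_genes = 200, n_terms = 10, n_cin_genes = 20,
                    planted_multipliers = numeric(0),
                    sensitivity = c(CTF = 1.0), fpr = 0)
  onto <- simulate_ontology(cfg)
  scr <- simulate_screens(cfg, onto$truth)
  expect_named(scr$hit_tables, "CTF")
  expect_setequal(scr$hit_tables$CTF$gene, onto$truth$cin_genes)

  # empty planted set and zero FPR -> empty tables
  cfg0 <- sim_config(seed = 9, n_genes = 200, n_terms = 10, n_cin_genes = 0,
                     planted_multipliers = numeric(0),
                     sensitivity = c(CTF = 1.0), fpr = 0)
  onto0 <- simulate_ontology(cfg0)
  scr0 <- simulate_screens(cfg0, onto0$truth)
  expect_equal(nrow(scr0$hit_tables$CTF), 0L)
})

test_that("detection by >= 1 of two half-sensitive assays approaches 0.75", {
  cfg <- sim_config(seed = 13, n_genes = 1500, n_terms = 10,
                    n_cin_genes = 400, planted_multipliers = numeric(0),
                    sensitivity = c(CTF = 0.5, ALF = 0.5), fpr = 0)
  onto <- simulate_ontology(cfg)
  scr <- simulate_screens(cfg, onto$truth)
  detected <- unique(c(scr$hit_tables$CTF$gene, scr$hit_tables$ALF$gene))
  frac <- length(detected) / 400
  expect_lt(abs(frac - 0.75), 3 * sqrt(0.75 * 0.25 / 400))
})

test_that("fixed fan-out of one and no extra humans mirrors the yeast universe", {
  cfg <- sim_config(seed = 17, n_genes = 150, n_terms = 10, n_cin_genes = 10,
                    planted_multipliers = numeric(0),
                    p_ortholog = 1, fanout_lambda = 0, n_human_extra = 0)
  onto <- simulate_ontology(cfg)
  down <- simulate_downstream(cfg, onto)
  expect_equal(length(down$human_universe), 150L)
  expect_equal(nrow(down$orthology), 150L)
})

test_that("write_simulation emits files every reader accepts", {
  cfg <- sim_config(seed = 5, n_genes = 120, n_terms = 25, n_cin_genes = 15,
                    n_human_extra = 30, n_array_genes = 30, n_unrelated = 6)
  dir <- tempfile()
  res <- write_simulation(cfg, dir)
  expect_s3_class(read_screen_table(file.path(dir, "screen_CTF.tsv")),
                  "cin_hits")
  expect_s3_class(parse_obo(file.path(dir, "ontology.obo")), "ontology_dag")
  expect_s3_class(read_gene_term_tsv(file.path(dir, "annotations_yeast.tsv")),
                  "annotation_set")
  expect_s3_class(read_orthology(file.path(dir, "orthology.tsv")),
                  "orthology_map")
  expect_s3_class(read_mutation_table(file.path(dir, "mutations.tsv")),
                  "mutation_table")
  m <- read_interaction_matrix(file.path(dir, "matrix.tsv"))
  expect_equal(dim(m), c(10, 30))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$cin_genes, res$truth$cin_genes)
})
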