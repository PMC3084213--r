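# Correlation distance, UPGMA linkage, shared hits and co-clustering.

test_that("correlation distance matches hand-derived values", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1),
             d = c(1, 2, 4))
  d <- correlation_distance(m)
  expect_equal(d["a", "b"], 0)                       # identical rows
  expect_equal(d["a", "c"], 2)                       # perfect anticorrelation
  # x=(1,2,3), y=(1,2,4): r = 7/sqrt(2*14/...) hand value 0.981981
  expect_equal(d["a", "d"], 1 - 0.9819805, tolerance = 1e-6)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 2))
})

test_that("pairwise-complete handling, overlap and variance guards", {
  m <- rbind(a = c(1, 2, 3, NA, 5), b = c(2, 4, 6, 8, NA))
  d <- correlation_distance(m)     # overlap = 3 complete columns
  expect_equal(d["a", "b"], 0, tolerance = 1e-12)
  m2 <- rbind(a = c(1, 2, NA, NA, 5), b = c(2, 4, 6, 8, NA))
  expect_error(correlation_distance(m2), "share only 2 complete")
  m3 <- rbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_error(correlation_distance(m3), "zero variance")
})

test_that("uncentered metric is the cosine of the raw vectors", {
  m <- rbind(a = c(1, 0, 1), b = c(2, 0, 2), c = c(0, 1, 0))
  d <- correlation_distance(m, metric = "uncentered")
  expect_equal(d["a", "b"], 0)     # parallel vectors
  expect_equal(d["a", "c"], 1)     # orthogonal vectors
})

test_that("average_linkage reproduces hand-traced merges", {
  # two leaves at distance 0.4
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- average_linkage(d2)
  expect_equal(t2$merges$height, 0.4)
  expect_equal(sort(c(t2$merges$node_a, t2$merges$node_b)), c("A", "B"))

  # d(AB)=1, d(AC)=4, d(BC)=5 -> (A,B) at 1 then with C at (4+5)/2
  d3 <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- average_linkage(d3)
  expect_equal(t3$merges$height, c(1, 4.5))
  expect_equal(t3$merges$node_a[2], "C")
  expect_equal(t3$merges$node_b[2], "N1")

  # three identical rows: both merges at height 0
  d0 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t0 <- average_linkage(d0)
  expect_equal(t0$merges$height, c(0, 0))
  # lexicographic tie-break: first merge is (A, B)
  expect_equal(sort(c(t0$merges$node_a[1], t0$merges$node_b[1])), c("A", "B"))
})

test_that("linkage validates its input", {
  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(average_linkage(bad), "not symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(average_linkage(neg), "negative")
})

test_that("UPGMA heights are monotone and match the brute-force oracle", {
  for (seed in 1:25) {
    n <- sample(3:6, 1)
    d <- random_dist(n, seed)
    tree <- average_linkage(d)
    expect_true(all(diff(tree$merges$height) >= -1e-12))
    oracle <- upgma_bruteforce(d)
    expect_equal(tree$merges$node_a, oracle$node_a, info = paste("seed", seed))
    expect_equal(tree$merges$node_b, oracle$node_b, info = paste("seed", seed))
    expect_equal(tree$merges$height, oracle$height, tolerance = 1e-12)
  }
})

test_that("cut_linkage and cocluster behave at the boundaries", {
  d3 <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- average_linkage(d3)
  # one cluster: always together
  expect_true(cocluster(tree, c("A", "B", "C"), 1)$together)
  # as many clusters as leaves: only singletons co-cluster
  expect_true(cocluster(tree, "A", 3)$together)
  expect_false(cocluster(tree, c("A", "B"), 3)$together)
  # toy cut: A and B merge first, so at k=2 they share a cluster
  cc <- cocluster(tree, c("A", "B"), 2)
  expect_true(cc$together)
  expect_equal(length(unique(cc$assignment)), 2L)
  expect_error(cocluster(tree, "ZZ", 2), "unknown query")
})

test_that("shared_hits counts genes shared by >= 2 queries once", {
  m <- rbind(q1 = c(5, 0, 3, 0, 0), q2 = c(4, 0, 0, 0, 1),
             q3 = c(6, 0, 3, 0, 0), q4 = c(0, 0, 0, 2, 0))
  colnames(m) <- paste0("g", 1:5)
  sh <- shared_hits(m, 2.5)
  # g1 significant in q1,q2,q3 (counted once); g3 in q1,q3
  expect_setequal(sh$shared_genes, c("g1", "g3"))
  expect_equal(sh$n_shared, 2L)
  expect_equal(length(sh$per_pair), 3L)  # q1|q2, q1|q3, q2|q3
  expect_setequal(sh$per_pair[["q1|q3"]], c("g1", "g3"))

  # no scores above the cutoff / infinite cutoff
  expect_equal(shared_hits(m, 100)$n_shared, 0L)
  expect_equal(shared_hits(m, Inf)$n_shared, 0L)
  # signed option: q4's +2 only counts on the positive side
  expect_equal(shared_hits(m, 2, side = "negative")$n_shared, 0L)
})

test_that("matrix TSV round-trips with missing cells", {
  m <- rbind(q1 = c(1.5, NA, -2), q2 = c(0, 3.25, -1))
  colnames(m) <- c("g1", "g2", "g3")
  path <- tempfile(fileext = ".tsv")
  write_interaction_matrix(m, path)
  back <- read_interaction_matrix(path)
  expect_equal(back, m)
})

test_that("newick export contains all leaves and parses as nested parens", {
  d <- random_dist(5, 99)
  tree <- average_linkage(d)
  nwk <- linkage_newick(tree)
  expect_true(endsWith(nwk, ";"))
  for (l in tree$leaves) expect_true(grepl(l, nwk, fixed = TRUE))
  expect_equal(lengths(regmatches(nwk, gregexpr("(", nwk, fixed = TRUE))),
               lengths(regmatches(nwk, gregexpr(")", nwk, fixed = TRUE))))
})

test_that("planted co-functional queries co-cluster at k = 5", {
  # 4 template-plus-noise queries among 20 unrelated profiles, 200 columns,
  # signal SD 3x noise SD
  hits <- 0L
  n_rep <- 40L
  for (seed in seq_len(n_rep)) {
    set.seed(1000 + seed)
    template <- rnorm(200, 0, 3)
    q <- t(sapply(1:4, function(i) template + rnorm(200, 0, 1)))
    u <- t(sapply(1:20, function(i) rnorm(200, 0, sqrt(10))))
    m <- rbind(q, u)
    rownames(m) <- c(paste0("Q", 1:4), paste0("U", 1:20))
    tree <- average_linkage(correlation_distance(m))
    if (cocluster(tree, paste0("Q", 1:4), 5)$together) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
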