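test_that("the worked RSS example evaluates to 0.696", {
  onto <- rss_demo_ontology()
  expect_equal(onto$max_depth, 20)
  comp <- rss(onto, "GO:0000002", "GO:0043653", components = TRUE)
  expect_equal(comp$alpha, 4)
  expect_equal(comp$beta, 1)
  expect_equal(comp$gamma, 3)
  expect_equal(round(comp$rss, 3), 0.696)
  expect_equal(comp$rss, 20 / 23 * 4 / 5)
})

test_that("RSS is symmetric, bounded, and 1 for identical leaves", {
  onto <- rss_demo_ontology()
  # identical leaf: gamma = 0, beta = 0, alpha > 0
  expect_equal(rss(onto, "GO:0043653", "GO:0043653"), 1.0)
  expect_equal(rss(onto, "GO:0000002", "GO:0043653"),
               rss(onto, "GO:0043653", "GO:0000002"))
  expect_error(rss(onto, "GO:0000002", "GO:MISSING"), "not in ontology")
  # the root carries no specificity
  expect_equal(rss(onto, onto$root, onto$root), 0)
})

test_that("self-RSS is non-decreasing with term depth along a chain", {
  # pure chain ontology: depth d term has self-RSS d / maxD
  terms <- c("R", sprintf("C%02d", 1:12))
  edges <- data.frame(child = terms[-1], parent = terms[-length(terms)],
                      stringsAsFactors = FALSE)
  onto <- build_ontology(terms, edges)
  vals <- vapply(terms, function(t) rss(onto, t, t), 1)
  expect_true(all(diff(vals) >= -1e-12))
  expect_equal(unname(vals), c(0, (1:12) / 12))
})

test_that("RSS matches exhaustive-path brute force on random DAGs", {
  for (seed in 1:8) {
    sim <- simulate_ontology(n_terms = 18, depth = 5, branching = 2,
                             p_extra_parent = 0.3, seed = seed)
    onto <- sim$ontology
    edges <- as.data.frame(igraph::as_edgelist(onto$graph),
                           stringsAsFactors = FALSE)
    colnames(edges) <- c("child", "parent")
    set.seed(seed + 1000)
    for (i in 1:6) {
      tt <- sample(onto$terms, 2)
      got <- rss(onto, tt[1], tt[2])
      want <- oracle_rss(onto$terms, edges, tt[1], tt[2])
      expect_equal(got, want, info = paste("seed", seed, tt[1], tt[2]))
      expect_gte(got, 0)
      expect_lte(got, 1)
    }
  }
})

test_that("OBO and GAF files round-trip through the readers", {
  onto <- rss_demo_ontology()
  f <- withr::local_tempfile()
  write_obo(onto, f)
  back <- read_obo(f, namespace = "biological_process")
  expect_setequal(back$terms, onto$terms)
  expect_equal(back$max_depth, onto$max_depth)
  expect_equal(rss(back, "GO:0000002", "GO:0043653"),
               rss(onto, "GO:0000002", "GO:0043653"))

  ann <- data.frame(protein = c("P1", "P1", "P2"),
                    go_id = c("GO:0000002", "GO:0043653", "GO:CHAIN05"),
                    aspect = c("P", "P", "P"), stringsAsFactors = FALSE)
  g <- withr::local_tempfile()
  write_gaf(ann, g)
  gaf <- read_gaf(g)
  expect_equal(nrow(gaf), 3L)
  lst <- gaf_annotations(gaf, "P", back)
  expect_setequal(lst$P1, c("GO:0000002", "GO:0043653"))
})

test_that("protein RSS is the best term-pair match", {
  onto <- rss_demo_ontology()
  ann <- list(P1 = c("GO:0000002"), P2 = c("GO:0043653"),
              P3 = c("GO:0000002", "GO:CHAIN20"))
  expect_equal(protein_rss(onto, ann, "P1", "P2"),
               rss(onto, "GO:0000002", "GO:0043653"))
  # max over term pairs: P3's deep chain term matches itself in P4
  ann$P4 <- c("GO:CHAIN20")
  pairwise <- c(rss(onto, "GO:0000002", "GO:CHAIN20"),
                rss(onto, "GO:CHAIN20", "GO:CHAIN20"))
  expect_equal(protein_rss(onto, ann, "P3", "P4"), max(pairwise))
  expect_warning(v <- protein_rss(onto, ann, "P1", "P99"), "unannotated")
  expect_true(is.na(v))
})

test_that("joint RSS combines the two namespaces", {
  expect_equal(joint_rss(1, 1), 1)
  expect_equal(joint_rss(0, 0.8), 0)
  expect_equal(joint_rss(0.49, 1), 0.7)
  expect_equal(joint_rss(0.5, 0.3, method = "product"), 0.15)
})

test_that("negative sets keep only pairs dissimilar in both namespaces", {
  # chain of depth 4 plus a two-leaf fork at depth 1:
  # rss(mid, leaf) = (4/5) * (1/2) = 0.4 exactly (boundary case)
  terms <- c("R", "C1", "C2", "C3", "C4", "M", "L")
  edges <- data.frame(child = c("C1", "C2", "C3", "C4", "M", "L"),
                      parent = c("R", "C1", "C2", "C3", "R", "M"),
                      stringsAsFactors = FALSE)
  onto <- build_ontology(terms, edges)
  expect_equal(rss(onto, "M", "L"), 0.4)

  ann_same <- list(P1 = "M", P2 = "L", P3 = "C4", P4 = "M")
  # pair (P1,P2): rss = 0.4 -> NOT negative (strict <)
  # pair (P1,P3): M vs C4 -> mrca R, alpha 0 -> rss 0 -> negative
  neg <- build_negative_set(c("P1", "P2", "P3"), ann_same, ann_same,
                            onto, onto, positives = NULL, rss_max = 0.4)
  keys <- pair_key(neg$a, neg$b)
  expect_false(pair_key("P1", "P2") %in% keys)
  expect_true(pair_key("P1", "P3") %in% keys)

  # positives are excluded even when dissimilar
  neg2 <- build_negative_set(c("P1", "P2", "P3"), ann_same, ann_same,
                             onto, onto,
                             positives = data.frame(a = "P3", b = "P1"),
                             rss_max = 0.4)
  expect_false(pair_key("P1", "P3") %in% pair_key(neg2$a, neg2$b))

  # exhaustive-filter oracle over all pairs
  prots <- c("P1", "P2", "P3", "P4")
  neg3 <- build_negative_set(prots, ann_same, ann_same, onto, onto)
  combos <- t(combn(prots, 2))
  want <- sum(apply(combos, 1, function(p) {
    b <- protein_rss(onto, ann_same, p[1], p[2])
    c2 <- protein_rss(onto, ann_same, p[1], p[2])
    b < 0.4 && c2 < 0.4
  }))
  expect_equal(nrow(neg3), want)
  expect_true(all(neg3$rss_bp < 0.4 & neg3$rss_cc < 0.4))
})

test_that("simulated ontologies are valid rooted DAGs with annotations", {
  for (seed in c(3, 9)) {
    sim <- simulate_ontology(n_terms = 40, depth = 6, branching = 2,
                             proteins = paste0("P", 1:10), seed = seed)
    onto <- sim$ontology
    expect_true(igraph::is_dag(onto$graph))
    expect_gte(onto$max_depth, 6)
    expect_true(all(sim$annotations$go_id %in% onto$terms))
    expect_true(all(table(sim$annotations$protein) >= 1))
  }
  # determinism
  a <- simulate_ontology(n_terms = 30, seed = 5)
  b <- simulate_ontology(n_terms = 30, seed = 5)
  expect_identical(igraph::as_edgelist(a$ontology$graph),
                   igraph::as_edgelist(b$ontology$graph))
})
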