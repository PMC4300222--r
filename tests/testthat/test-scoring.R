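test_that("Ssim normalizes by self-alignment and clamps to [0, 1]", {
  # candidate as strong as the self-alignment scores exactly 1
  expect_equal(compute_ssim(3e-68, 3e-68, 3e-68, 3e-68), 1.0)
  # short-protein worked case: E' = 4e-49 against self E = 3e-68
  expect_equal(compute_ssim(4e-49, 4e-49, 3e-68, 3e-68), 0.51375,
               tolerance = 1e-4)
  # cross-alignment stronger than self -> clamped
  expect_equal(compute_ssim(1e-120, 1e-120, 1e-100, 1e-100), 1.0)
  expect_error(compute_ssim(1e-50, 1e-50, 2, 1e-100), "self-alignment")
})

test_that("Ssim is non-increasing as member E-values grow", {
  e <- 10^seq(-80, -20, by = 5)
  vals <- compute_ssim(e, 1e-60, 1e-100, 1e-100)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("joint sequence identity combines symmetrically", {
  expect_equal(joint_si(1, 1), 1)
  expect_equal(joint_si(0.25, 1), 0.5)
  expect_equal(joint_si(0.4, 0.9), 0.6)
  expect_equal(joint_si(0.3, 0.7), joint_si(0.7, 0.3))
  expect_equal(joint_si(0.4, 0.9, method = "product"), 0.36)
})

# build a one-template candidate frame with controlled similarity order:
# e_a_prime = 10^-nl[i] against self 1e-100 fixes s_sim = nl[i]/100
cand_frame <- function(nl, si = rep(0.5, length(nl)),
                       pairs = sprintf("x%03d", seq_along(nl))) {
  data.frame(a_prime = pairs, b_prime = pairs,
             template_a = "A", template_b = "B", source_org = "src",
             e_a_prime = 10^-nl, e_b_prime = 1e-100,
             si_a = si, si_b = si,
             e_a_self = 1e-100, e_b_self = 1e-100,
             joint_evalue = 1e-60, joint_si = si,
             stringsAsFactors = FALSE)
}

test_that("Srank follows 1 - log(r)/log(rmax) with boundary values", {
  ranked <- rank_candidates(cand_frame(nl = 100 - (1:100)))
  expect_equal(ranked$r_max, rep(100L, 100))
  expect_equal(ranked$s_rank[ranked$rank == 1], 1)
  expect_equal(ranked$s_rank[ranked$rank == 100], 0)
  expect_equal(ranked$s_rank[ranked$rank == 10], 0.5)
  # base invariance: identical under log2
  expect_equal(ranked$s_rank,
               1 - log2(ranked$rank) / log2(ranked$r_max))
  # a single-candidate template ranks 1 with Srank 1
  single <- rank_candidates(cand_frame(nl = 60))
  expect_equal(single$rank, 1L)
  expect_equal(single$s_rank, 1)
})

test_that("rank ties break by joint identity, then canonical pair id", {
  cand <- cand_frame(nl = c(80, 80, 80, 90),
                     si = c(0.5, 0.9, 0.5, 0.4),
                     pairs = c("p3", "p2", "p1", "p4"))
  ranked <- rank_candidates(cand)
  expect_equal(ranked$a_prime[ranked$rank == 1], "p4")  # highest s_sim
  expect_equal(ranked$a_prime[ranked$rank == 2], "p2")  # si tie-break
  expect_equal(ranked$a_prime[ranked$rank == 3], "p1")  # pair-id order
  expect_equal(ranked$a_prime[ranked$rank == 4], "p3")
})

test_that("Scon sums normalized distances of supporting sources", {
  cfg <- distance_config("mouse", c(human = 0.765, fly = 0.235))
  expect_equal(compute_scon(c("human", "fly"), cfg), 1.0)
  expect_equal(compute_scon("human", cfg), 0.765)
  expect_equal(compute_scon("fly", cfg), 0.235)
  expect_equal(compute_scon(character(0), cfg), 0)
  expect_error(compute_scon("yeast", cfg), "not in distance config")
})

test_that("per-pair aggregation takes the best template and unions sources", {
  cfg <- distance_config("mouse", c(human = 0.765, fly = 0.235))
  # same target pair from two templates in different organisms
  cand <- rbind(
    data.frame(a_prime = "m1", b_prime = "m2", template_a = "H1",
               template_b = "H2", source_org = "human",
               e_a_prime = 10^-87.4, e_b_prime = 1e-100,
               si_a = 0.9, si_b = 0.9, e_a_self = 1e-100,
               e_b_self = 1e-100, joint_evalue = 1e-90, joint_si = 0.9,
               stringsAsFactors = FALSE),
    data.frame(a_prime = "m1", b_prime = "m2", template_a = "F1",
               template_b = "F2", source_org = "fly",
               e_a_prime = 1e-50, e_b_prime = 1e-100,
               si_a = 0.5, si_b = 0.5, e_a_self = 1e-100,
               e_b_self = 1e-100, joint_evalue = 1e-70, joint_si = 0.5,
               stringsAsFactors = FALSE))
  ranked <- rank_candidates(cand)
  pairs <- aggregate_pair_scores(ranked, cfg)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$s_con, 1.0)            # union of both sources
  expect_equal(pairs$template_org, "human") # best-template provenance
  expect_equal(pairs$s_sim, 0.874, tolerance = 1e-9)
  expect_equal(pairs$n_templates, 2L)
  # rank 1 in its template, human-only support, Ssim 0.874 -> S = 2.639
  solo <- aggregate_pair_scores(ranked[ranked$source_org == "human", ],
                                cfg)
  expect_equal(solo$s_total, 0.874 + 1 + 0.765, tolerance = 1e-9)
  expect_equal(round(solo$s_total, 3), 2.639)
})

test_that("total score respects weights and bounds", {
  sc <- make_scored_study(21)
  pairs <- sc$result$pairs
  expect_true(all(pairs$s_sim >= 0 & pairs$s_sim <= 1))
  expect_true(all(pairs$s_rank >= 0 & pairs$s_rank <= 1))
  expect_true(all(pairs$s_con >= 0 & pairs$s_con <= 1))
  expect_true(all(pairs$s_total >= 0 & pairs$s_total <= 3))
  expect_equal(pairs$s_total, pairs$s_sim + pairs$s_rank + pairs$s_con,
               tolerance = 1e-12)
  # doubled similarity weight shifts the total accordingly
  pairs2 <- aggregate_pair_scores(sc$result$ranked, sc$study$distances,
                                  weights = c(2, 1, 1))
  m <- match(pair_key(pairs$a, pairs$b), pair_key(pairs2$a, pairs2$b))
  expect_true(all(pairs2$s_total[m] >= pairs$s_total - 1e-12))
})

test_that("prediction threshold is inclusive at S >= s_min", {
  pairs <- data.frame(a = c("a", "b", "c"), b = c("x", "y", "z"),
                      s_total = c(2.3, 2.299999, 2.9),
                      stringsAsFactors = FALSE)
  kept <- filter_predicted(pairs)
  expect_equal(kept$s_total, c(2.9, 2.3))
  # survivor count equals a brute-force count on a random fixture
  sc <- make_scored_study(22)
  all_pairs <- sc$result$pairs
  expect_equal(nrow(filter_predicted(all_pairs, 2.3)),
               sum(all_pairs$s_total >= 2.3))
})

test_that("planted orthologs take rank 1 in every template", {
  st <- simulate_interolog_study(seed = 44, ortholog_fraction = 1)
  cand <- do.call(rbind, lapply(names(st$templates), function(o) {
    suppressWarnings(enumerate_candidates(st$templates[[o]],
                                          st$homology[[o]]))
  }))
  ranked <- rank_candidates(cand)
  top <- ranked[ranked$rank == 1L, ]
  truek <- pair_key(st$positives$a, st$positives$b)
  expect_equal(mean(pair_key(top$a_prime, top$b_prime) %in% truek), 1.0)
  expect_true(all(top$s_rank == 1))
})
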