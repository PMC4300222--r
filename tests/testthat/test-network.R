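path_graph <- function(edges) {
  reconstruct_network(data.frame(a = vapply(edges, `[[`, "", 1L),
                                 b = vapply(edges, `[[`, "", 2L),
                                 stringsAsFactors = FALSE))
}

test_that("reconstruction collapses duplicates and counts nodes", {
  g <- reconstruct_network(data.frame(
    a = c("p1", "p2", "p3", "p3"),
    b = c("p2", "p3", "p4", "p4"),
    s_total = c(2.5, 2.4, 2.6, 2.6)))
  expect_equal(igraph::vcount(g), 4L)
  expect_equal(igraph::ecount(g), 3L)
  # reversed duplicates collapse too
  g2 <- reconstruct_network(data.frame(a = c("x", "y"), b = c("y", "x")))
  expect_equal(igraph::ecount(g2), 1L)
})

test_that("power-law fits refuse degenerate degree distributions", {
  star <- path_graph(list(c("c", "l1"), c("c", "l2"), c("c", "l3"),
                          c("c", "l4")))
  expect_error(degree_exponent(star), "distinct degrees")
})

test_that("the exponent is recovered on a noiseless power law", {
  set.seed(5)
  k <- 1:64
  seq_deg <- rep(k, times = round(3000 * k^-2))
  if (sum(seq_deg) %% 2 == 1) seq_deg <- c(seq_deg, 1)
  g <- igraph::sample_degseq(seq_deg, method = "configuration")
  igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  fit <- degree_exponent(g)
  expect_equal(fit$gamma, 2, tolerance = 0.05 / 2)
  expect_gt(fit$r_squared, 0.99)
})

test_that("module connectivity is m / C(n,2) over all members", {
  g <- path_graph(list(c("a", "b"), c("b", "c"), c("c", "d"),
                       c("d", "a")))                       # 4-cycle
  expect_equal(round(module_connectivity(c("a", "b", "c", "d"), g), 2),
               0.67)
  # complete 4-clique
  k4 <- path_graph(list(c("a", "b"), c("a", "c"), c("a", "d"),
                        c("b", "c"), c("b", "d"), c("c", "d")))
  expect_equal(module_connectivity(c("a", "b", "c", "d"), k4), 1.0)
  # path on 4 members: 3 edges
  p4 <- path_graph(list(c("a", "b"), c("b", "c"), c("c", "d")))
  expect_equal(module_connectivity(c("a", "b", "c", "d"), p4), 0.5)
  # members absent from the network still count in n
  expect_equal(module_connectivity(c("a", "b", "c", "d", "ghost",
                                     "ghost2"), p4),
               3 / choose(6, 2))
  expect_warning(v <- module_connectivity("solo", p4), "fewer than 2")
  expect_true(is.na(v))
})

test_that("one-layer extension adds exactly the direct neighbors", {
  p3 <- path_graph(list(c("a", "b"), c("b", "c")))
  ext <- one_layer_extension("b", p3)
  expect_setequal(ext$members, c("a", "b", "c"))
  expect_equal(ext$n_edges, 2L)
  # isolated module: extension adds nothing
  g <- path_graph(list(c("a", "b"), c("x", "y")))
  ext2 <- one_layer_extension(c("a", "b"), g)
  expect_setequal(ext2$members, c("a", "b"))
  expect_equal(ext2$n_edges, 1L)
  # matches a BFS-depth-1 oracle on random graphs
  for (seed in 1:6) {
    set.seed(seed)
    el <- data.frame(a = sample(letters[1:15], 25, replace = TRUE),
                     b = sample(letters[1:15], 25, replace = TRUE),
                     stringsAsFactors = FALSE)
    el <- el[el$a != el$b, ]
    el <- el[!duplicated(pair_key(el$a, el$b)), ]
    g <- reconstruct_network(el)
    mem <- sample(unique(c(el$a, el$b)), 3)
    got <- one_layer_extension(mem, g)
    want <- oracle_extension(mem, el)
    expect_setequal(got$members, want$members)
    expect_equal(got$n_edges, want$n_edges)
  }
})

test_that("connectivity ratio reproduces the worked module example", {
  # 4-member module with 4 internal edges inside a 26-node, 49-edge
  # one-layer neighborhood: Ct = 0.67, extended = 49/325 = 0.1508,
  # ratio = 4.42 (displayed as 0.67/0.15 = 4.5 at two decimals)
  mod <- c("m1", "m2", "m3", "m4")
  edges <- list(c("m1", "m2"), c("m2", "m3"), c("m3", "m4"),
                c("m4", "m1"))
  extras <- sprintf("e%02d", 1:22)
  for (i in seq_along(extras)) {
    edges <- c(edges, list(c(mod[(i %% 4) + 1], extras[i])))
  }
  # 4 + 22 = 26 edges so far; add 23 more among the extras
  more <- list()
  k <- 0
  for (i in 1:21) {
    if (k >= 23) break
    more <- c(more, list(c(extras[i], extras[i + 1])))
    k <- k + 1
  }
  more <- c(more, list(c(extras[1], extras[3]), c(extras[2], extras[4])))
  g <- path_graph(c(edges, more))
  expect_equal(igraph::vcount(g), 26L)
  expect_equal(igraph::ecount(g), 49L)
  cm <- module_connectivity(mod, g)
  ext <- one_layer_extension(mod, g)
  cext <- module_connectivity(ext$members, g)
  expect_equal(round(cm, 2), 0.67)
  expect_equal(cext, 49 / 325)
  expect_equal(round(cext, 2), 0.15)
  expect_equal(connectivity_ratio(mod, g), cm / cext, tolerance = 1e-12)
  expect_equal(round(round(cm, 2) / round(cext, 2), 1), 4.5)
})

test_that("the whole network as a module has ratio 1", {
  g <- path_graph(list(c("a", "b"), c("b", "c"), c("a", "c")))
  expect_equal(connectivity_ratio(c("a", "b", "c"), g), 1.0)
})

test_that("ratio is at least the module connectivity", {
  for (seed in 1:5) {
    sim <- simulate_modular_network(n_modules = 4, module_size = 6,
                                    p_in = 0.9, p_out = 0.05, seed = seed)
    for (i in seq_len(nrow(sim$modules))) {
      mem <- sim$modules$members[[i]]
      ct <- suppressWarnings(module_connectivity(mem, sim$network))
      ratio <- suppressWarnings(connectivity_ratio(mem, sim$network))
      if (!is.na(ratio)) expect_gte(ratio, ct - 1e-12)
    }
  }
})

test_that("cohesive planted modules have ratio above 1", {
  sim <- simulate_modular_network(n_modules = 5, module_size = 8,
                                  p_in = 1, p_out = 0.02, seed = 42)
  res <- average_connectivity_ratio(sim$modules, sim$network)
  expect_equal(nrow(res$table), 5L)
  expect_gt(res$mean_ratio, 1)
  expect_equal(res$mean_ratio, mean(res$table$ratio, na.rm = TRUE))
  # per-module values equal direct recomputation
  for (i in 1:5) {
    expect_equal(res$table$ratio[i],
                 suppressWarnings(
                   connectivity_ratio(sim$modules$members[[i]],
                                      sim$network)))
  }
  # fully isolated complete module: extension adds nothing, ratio 1
  iso <- simulate_modular_network(n_modules = 3, module_size = 5,
                                  p_in = 1, p_out = 0, seed = 7)
  r <- average_connectivity_ratio(iso$modules, iso$network)
  expect_true(all(abs(r$table$ratio - 1) < 1e-12))
})
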