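test_that("build_graph combines channels by noisy-OR with inclusive threshold", {
  genes <- c("A", "B", "C")
  edges <- data.frame(protein1 = "A", protein2 = "B",
                      experiments = 600L, databases = 500L, fusion = 0L,
                      combined_score = 800L, stringsAsFactors = FALSE)
  # 1 - 0.4 * 0.5 = 0.8 >= 0.7: kept
  g <- build_graph(edges, genes)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 3)         # isolate C included
  # boundary: 0.699 dropped, 0.700 kept
  edges$experiments <- 699L; edges$databases <- 0L
  expect_equal(igraph::ecount(build_graph(edges, genes)), 0)
  edges$experiments <- 700L
  expect_equal(igraph::ecount(build_graph(edges, genes)), 1)
  # empty gene set -> empty graph; edges outside the set dropped
  expect_equal(igraph::vcount(build_graph(edges, character(0))), 0)
  expect_equal(igraph::ecount(build_graph(edges, c("A", "Z"))), 0)
  expect_error(build_graph(edges, genes, channels = c("experiments", "text")),
               "unknown channel")
  # self-loops and duplicate pairs dropped
  messy <- edge_table(list(c("A", "B"), c("B", "A"), c("A", "A")))
  expect_equal(igraph::ecount(build_graph(messy, genes)), 1)
})

test_that("main_graph takes the largest component with lexicographic ties", {
  five_three <- edge_table(list(c("A", "B"), c("B", "C"), c("C", "D"),
                                c("D", "E"), c("X", "Y"), c("Y", "Z")))
  g <- build_graph(five_three, c("A", "B", "C", "D", "E", "X", "Y", "Z"))
  expect_setequal(igraph::V(main_graph(g))$name, c("A", "B", "C", "D", "E"))
  # connected graph: itself
  tri <- build_graph(edge_table(list(c("A", "B"), c("B", "C"), c("A", "C"))),
                     c("A", "B", "C"))
  expect_equal(igraph::vcount(main_graph(tri)), 3)
  # two size-2 components: the one containing the smallest name (A) wins
  tie <- build_graph(edge_table(list(c("B", "C"), c("A", "D"))),
                     c("A", "B", "C", "D"))
  expect_setequal(igraph::V(main_graph(tie))$name, c("A", "D"))
  # empty in, empty out
  expect_equal(igraph::vcount(main_graph(build_graph(edge_table(list()),
                                                     character(0)))), 0)
})

test_that("graph_stats matches hand-enumerated values", {
  tri <- build_graph(edge_table(list(c("A", "B"), c("B", "C"), c("A", "C"))),
                     c("A", "B", "C"))
  s <- graph_stats(tri)
  expect_equal(s$char_path_length, 1)
  expect_equal(s$avg_neighbors, 2)
  expect_equal(s$fraction, 1)
  # path A-B-C-D: distances 1,1,1,2,2,3 -> CPL 10/6
  path <- build_graph(edge_table(list(c("A", "B"), c("B", "C"),
                                      c("C", "D"))),
                      c("A", "B", "C", "D"))
  sp <- graph_stats(path)
  expect_equal(sp$char_path_length, 10 / 6)
  expect_equal(sp$avg_neighbors, 1.5)
  expect_equal(as.integer(sp$shortest_path_histogram), c(3L, 2L, 1L))
  expect_equal(names(sp$shortest_path_histogram), c("1", "2", "3"))
  # single node: degenerate, CPL reported as 0 with a flag
  single <- build_graph(edge_table(list()), "A")
  ss <- graph_stats(single)
  expect_true(ss$degenerate)
  expect_equal(ss$char_path_length, 0)
  expect_equal(ss$n_main, 1)
})

test_that("graph_stats agrees with a Floyd-Warshall oracle on random graphs", {
  withr::with_seed(80, {
    sizes <- sample(5:30, 30, replace = TRUE)
    densities <- stats::runif(30, 0.05, 0.3)
  })
  for (i in 1:30) {
    rg <- random_named_graph(sizes[i], p = densities[i], seed = 500 + i)
    s <- graph_stats(rg$graph)
    D <- oracle_floyd_warshall(rg$adj)
    # restrict the oracle to the main component
    comp <- igraph::components(rg$graph)
    main_id <- which.max(comp$csize)
    idx <- which(comp$membership == main_id)
    dd <- D[idx, idx][upper.tri(D[idx, idx])]
    if (length(idx) >= 2) {
      expect_equal(s$char_path_length, mean(dd))
      expect_equal(as.integer(s$shortest_path_histogram),
                   as.integer(table(dd)))
      expect_equal(s$avg_neighbors, mean(rowSums(rg$adj[idx, idx])))
    }
    # structural invariants
    expect_equal(s$avg_neighbors,
                 2 * igraph::ecount(main_graph(rg$graph)) / max(1, s$n_main))
    expect_lte(s$n_main, s$n_total)
    expect_gte(s$fraction, 0)
    expect_lte(s$fraction, 1)
    expect_equal(sum(s$degree_histogram), s$n_main)
  }
})

test_that("removing an edge never shortens any distance", {
  rg <- random_named_graph(15, 0.25, seed = 901)
  d_full <- igraph::distances(rg$graph)
  edges_to_try <- withr::with_seed(902, sample(igraph::ecount(rg$graph), 5))
  for (e in edges_to_try) {
    g2 <- igraph::delete_edges(rg$graph, e)
    expect_true(all(igraph::distances(g2) >= d_full - 1e-12))
  }
})

test_that("powerlaw_fit recovers exact and degenerate spectra", {
  # exact n(k) = 100 k^-2 over k in {1,2,4,8}
  h <- stats::setNames(100 * c(1, 2, 4, 8)^-2, c(1, 2, 4, 8))
  fit <- powerlaw_fit(h)
  expect_equal(fit$slope, -2)
  expect_equal(fit$r2, 1)
  # flat histogram: slope 0
  flat <- stats::setNames(rep(5, 4), 1:4)
  expect_equal(powerlaw_fit(flat)$slope, 0)
  # insufficient support
  expect_error(powerlaw_fit(stats::setNames(c(3, 1), 1:2)), "3 distinct")
  # degree 0 and zero-count bins excluded
  with_zero <- stats::setNames(c(7, 100, 25, 0, 6.25), c(0, 1, 2, 3, 4))
  expect_equal(powerlaw_fit(with_zero)$slope, -2)
})

test_that("main_fraction_point covers the degenerate layouts", {
  # fully connected set
  full <- edge_table(list(c("A", "B"), c("A", "C"), c("B", "C")))
  expect_equal(main_fraction_point(c("A", "B", "C"), full)$fraction, 1)
  # edgeless set: main graph is a singleton
  res <- main_fraction_point(c("A", "B", "C", "D"), edge_table(list()))
  expect_equal(res$n_main, 1)
  expect_equal(res$fraction, 1 / 4)
})

test_that("planted-module and random individuals separate in main fraction", {
  cfg <- sim_config(seed = 11)
  genes <- sprintf("G%03d", 1:150)
  ppi <- synth_ppi(cfg, genes)
  sets <- synth_gene_sets(cfg, ppi$planted_module_genes, genes)
  labels <- vapply(sets, attr, "", "label")
  frac <- vapply(sets, function(s) main_fraction_point(s, ppi$edges)$fraction,
                 0)
  expect_gt(min(frac[labels == "familial_patient"]),
            max(frac[labels == "control"]))
  expect_gt(mean(frac[labels == "familial_patient"]) -
              mean(frac[labels == "control"]), 0.2)
})

test_that("compare_groups delegates to the right tests", {
  mk <- function(n_main, fraction, degrees) {
    structure(list(n_main = n_main, n_total = 10, fraction = fraction,
                   degree_histogram = table(degrees)),
              class = "main_graph_stats")
  }
  a <- list(mk(5, .5, c(1, 2, 2)), mk(6, .6, c(1, 1, 3)))
  expect_equal(compare_groups(a, a, "neighbors", "ks"), 1)
  # disjoint-range n_main, 5 vs 3 individuals: exact MWU p = 2/56
  big <- lapply(6:10, function(k) mk(k, .8, 1))
  small <- lapply(1:3, function(k) mk(k, .2, 1))
  expect_equal(compare_groups(big, small, "n_main", "mwu"), 2 / 56)
  expect_equal(compare_groups(small, big, "n_main", "mwu"), 2 / 56)
})
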