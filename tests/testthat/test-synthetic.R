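test_that("planted partitions: disjoint cliques at p_in = 1, p_out = 0, with closed-form Q", {
  pp <- generate_planted_partition(3, c(4, 5, 6), p_in = 1, p_out = 0, seed = 1)
  m_i <- choose(c(4, 5, 6), 2)
  m <- sum(m_i)
  expect_equal(nrow(pp$network$edges), m)
  # every within pair present, no cross edges
  expect_true(all(pp$membership[pp$network$edges$from] ==
                  pp$membership[pp$network$edges$to]))
  q_closed <- sum(m_i / m - (m_i / m)^2)
  expect_equal(modularity_q(pp$network, pp$membership), q_closed, tolerance = 1e-12)
})

test_that("planted partitions hit their binomial edge-count expectations", {
  within <- vapply(1:30, function(s) {
    pp <- generate_planted_partition(3, 10, 0.5, 0.02, seed = 100 + s)
    sum(pp$membership[pp$network$edges$from] == pp$membership[pp$network$edges$to])
  }, numeric(1))
  mu <- 3 * 0.5 * choose(10, 2)   # 67.5
  sd1 <- sqrt(3 * choose(10, 2) * 0.5 * 0.5)
  expect_lt(abs(mean(within) - mu), 3 * sd1 / sqrt(30))

  pp1 <- generate_planted_partition(3, 10, 0.5, 0.02, seed = 100 + 1)
  expect_lt(abs(sum(pp1$membership[pp1$network$edges$from] ==
                    pp1$membership[pp1$network$edges$to]) - mu), 3 * sd1)
})

test_that("generators are seed-deterministic", {
  a <- generate_planted_partition(3, 8, 0.6, 0.05, seed = 7)
  b <- generate_planted_partition(3, 8, 0.6, 0.05, seed = 7)
  expect_identical(a$network$edges, b$network$edges)

  n1 <- generate_background_network(300, 6, "power_law", seed = 9)
  n2 <- generate_background_network(300, 6, "power_law", seed = 9)
  expect_identical(n1$edges, n2$edges)

  t1 <- generate_two_species_lists(5, 20, 15, sprintf("G%03d", 1:100), seed = 11)
  t2 <- generate_two_species_lists(5, 20, 15, sprintf("G%03d", 1:100), seed = 11)
  expect_identical(t1$list_a$symbols, t2$list_a$symbols)
  expect_identical(t1$list_b$symbols, t2$list_b$symbols)

  g1 <- generate_gmt(10, c(5, 20), namespace = sprintf("G%03d", 1:100), seed = 13)
  g2 <- generate_gmt(10, c(5, 20), namespace = sprintf("G%03d", 1:100), seed = 13)
  expect_identical(g1$terms, g2$terms)
})

test_that("uniform background hits the requested edge count and mean degree", {
  net <- generate_background_network(1000, 10, "uniform_random", seed = 15)
  M <- choose(1000, 2)
  p <- 10 / 999
  expect_lt(abs(nrow(net$edges) - M * p), 3 * sqrt(M * p * (1 - p)))
  expect_lt(abs(mean(node_degrees(net)) - 10) / 10, 0.1)

  pl <- generate_background_network(1000, 10, "power_law", seed = 16)
  expect_lt(abs(mean(node_degrees(pl)) - 10) / 10, 0.1)
})

test_that("the power-law model is heavier-tailed than the uniform model at matched mean", {
  net_u <- generate_background_network(800, 8, "uniform_random", seed = 17)
  net_p <- generate_background_network(800, 8, "power_law", seed = 17)
  du <- node_degrees(net_u)
  dp <- node_degrees(net_p)
  ks <- suppressWarnings(ks.test(as.numeric(du), as.numeric(dp)))
  expect_gt(unname(ks$statistic), 0)
  expect_gt(max(dp), max(du))       # hubs exist
  expect_gt(stats::var(dp), stats::var(du))
})

test_that("hit lists respect the contamination budget and carry truth labels", {
  pp <- generate_planted_partition(1, 40, 0.5, 0.1, seed = 19, prefix = "M")
  bg <- generate_background_network(200, 5, "uniform_random", seed = 19)
  net <- merge_networks(bg, pp$network)
  module <- names(pp$membership)

  pure <- generate_hit_list(net, module, contamination = 0, seed = 20)
  expect_setequal(pure$symbols, module)
  expect_true(all(attr(pure, "truth") == "module"))

  mixed <- generate_hit_list(net, module, contamination = 0.5, list_size = 60,
                             seed = 21)
  expect_equal(length(mixed$symbols), 60L)
  expect_equal(sum(attr(mixed, "truth") == "module"), 30L)
  expect_equal(sum(attr(mixed, "truth") == "contaminant"), 30L)

  expect_error(generate_hit_list(net, module[1:5], contamination = 0,
                                 list_size = 10, seed = 1),
               "module has only")
})

test_that("a module-bearing hit list sits at the extreme tail of the density null", {
  bg <- generate_background_network(500, 5, "uniform_random", seed = 23)
  set.seed(23)
  module <- sample(bg$nodes, 20)
  net <- plant_modules(bg, list(module), p_in = 0.5, seed = 24)
  hl <- generate_hit_list(net, module, contamination = 0, seed = 25)
  sub <- induce_subnetwork(net, hl)
  pn <- permutation_density_test(net, sub$n_hits_in_network,
                                 observed = nrow(sub$network$edges),
                                 n_samples = 1e4, seed = 26)
  expect_equal(pn$p_empirical, 1 / (1e4 + 1))
})

test_that("two-species lists intersect in exactly the planted core", {
  two <- generate_two_species_lists(26, 1269, 128, sprintf("G%05d", 1:20000),
                                    seed = 27)
  expect_equal(length(two$list_a$symbols), 1269L)
  expect_equal(length(two$list_b$symbols), 128L)
  expect_setequal(intersect(two$list_a$symbols, two$list_b$symbols), two$core)
  expect_equal(length(two$core), 26L)

  none <- generate_two_species_lists(0, 30, 20, sprintf("G%03d", 1:200), seed = 28)
  expect_equal(length(intersect(none$list_a$symbols, none$list_b$symbols)), 0L)
  expect_equal(overlap_test(none$list_a, none$list_b, 20000)$p, 1)
})

test_that("generated GMT libraries contain planted terms verbatim; zero decoys means planted only", {
  uni <- sprintf("G%03d", 1:150)
  planted <- list(CORE = uni[1:10], SHELL = uni[11:25])
  lib <- generate_gmt(0, c(5, 20), planted = planted, namespace = uni, seed = 29)
  expect_equal(length(lib$terms), 2L)
  expect_setequal(lib$terms$CORE, planted$CORE)

  lib2 <- generate_gmt(8, c(5, 20), planted = planted, namespace = uni, seed = 30)
  expect_equal(length(lib2$terms), 10L)
  expect_setequal(lib2$terms$SHELL, planted$SHELL)
  expect_true(all(lengths(lib2$terms) >= 5 | names(lib2$terms) %in% names(planted)))
})

test_that("generator output round-trips through the package's external formats", {
  pp <- generate_planted_partition(2, 6, 0.8, 0.1, seed = 31)
  f <- withr::local_tempfile()
  write_edge_list(pp$network, f)
  back <- read_edge_list(f)
  expect_equal(back$edges, pp$network$edges)

  lib <- generate_gmt(5, c(4, 10), namespace = sprintf("G%03d", 1:50), seed = 32)
  g <- withr::local_tempfile()
  write_gmt(lib, g)
  expect_equal(read_gmt(g)$terms, lib$terms)

  two <- generate_two_species_lists(3, 10, 8, sprintf("G%03d", 1:50), seed = 33)
  h <- withr::local_tempfile()
  write_gene_list(two$list_a, h)
  expect_identical(read_gene_list(h)$symbols, two$list_a$symbols)
})

test_that("module recovery scoring is exact on a hand-built partition", {
  mem <- setNames(c(1, 1, 1, 2, 2, 3), sprintf("N%d", 1:6))
  sc <- score_module_recovery(mem, list(good = sprintf("N%d", 1:3),
                                        split = sprintf("N%d", c(4, 6)),
                                        absent = c("Q1", "Q2")))
  expect_equal(sc$ari[sc$module == "good"], 1)
  expect_lt(sc$ari[sc$module == "split"], 1)
  expect_true(is.na(sc$ari[sc$module == "absent"]))
})
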