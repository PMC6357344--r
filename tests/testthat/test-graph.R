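test_that("linkage tallies accumulate chain support by joint state", {
  chains <- list(
    list(sites = c(0L, 1L), states = c(TRUE, TRUE), supp = c(1, 1), support = 1),
    list(sites = c(0L, 1L), states = c(FALSE, FALSE), supp = c(1, 1), support = 1),
    list(sites = c(0L, 1L), states = c(FALSE, TRUE), supp = c(1, 1), support = 1))
  lk <- count_linkage(chains)
  expect_equal(lk$n_aa, 1); expect_equal(lk$n_bb, 1)
  expect_equal(lk$n_ab, 1); expect_equal(lk$n_ba, 0)
  expect_equal(lk$F, 3)

  expect_equal(nrow(count_linkage(list(list(sites = 5L, states = TRUE,
                                            supp = 2, support = 2)))), 0L)

  mult4 <- count_linkage(list(list(sites = c(2L, 3L), states = c(TRUE, FALSE),
                                   supp = c(4, 4), support = 4)))
  expect_equal(mult4$n_ba, 4)
  expect_equal(mult4$F, 4)
})

test_that("edge weight follows the error-aware connection probabilities", {
  w <- edge_weight(list(n_a = 8, n_b = 2, F = 10), epsilon = 0.01)
  expect_equal(w, 0.57624, tolerance = 1e-10)
  # the two connection probabilities always sum to one
  f_a <- (((1 - 0.01)^2 + 0.01^2) * 8 + 2 * 0.01 * 0.99 * 2) / 10
  expect_equal(f_a, 0.78812, tolerance = 1e-10)

  expect_equal(edge_weight(list(n_a = 7, n_b = 13, F = 20), epsilon = 0.5), 0)
  expect_equal(edge_weight(list(n_a = 5, n_b = 5, F = 10), epsilon = 0.17), 0)
  expect_error(edge_weight(list(n_a = 0, n_b = 0, F = 0), 0.01), "F")
})

test_that("weights are bounded, antisymmetric in the mode counts, and f_A + f_B = 1", {
  set.seed(41)
  n <- 10000
  na <- stats::rpois(n, 8); nb <- stats::rpois(n, 4)
  keep <- na + nb > 0
  na <- na[keep]; nb <- nb[keep]
  eps <- stats::runif(sum(keep), 0, 0.49)
  cs <- (1 - eps)^2 + eps^2; cf <- 2 * eps * (1 - eps)
  f_a <- (cs * na + cf * nb) / (na + nb)
  f_b <- (cs * nb + cf * na) / (na + nb)
  expect_true(all(abs(f_a + f_b - 1) < 1e-12))
  w <- edge_weight(list(n_a = na, n_b = nb, F = na + nb), epsilon = 0.01)
  expect_true(all(w >= -1 & w <= 1))
  w_swap <- edge_weight(list(n_a = nb, n_b = na, F = na + nb), epsilon = 0.01)
  expect_equal(w, -w_swap)
})

test_that("the coverage threshold gates edges at the boundary", {
  chains <- list(
    list(sites = c(0L, 1L), states = c(TRUE, TRUE), supp = c(2, 2), support = 2),
    list(sites = c(1L, 2L), states = c(TRUE, TRUE), supp = c(1, 1), support = 1))
  lk <- count_linkage(chains)
  g <- build_graph(lk, founding_sites = 0:2, epsilon = 0.01, cov_threshold = 2)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$i, 0L)
  g1 <- build_graph(lk, founding_sites = 0:2, epsilon = 0.01, cov_threshold = 1)
  expect_equal(nrow(g1$edges), 2L)
  empty <- build_graph(lk, founding_sites = integer(), epsilon = 0.01)
  expect_equal(nrow(empty$edges), 0L)
})

test_that("phase propagates by edge sign from the anchored seed", {
  lk <- data.table::data.table(i = c(0L, 1L), j = c(1L, 2L),
                               n_aa = c(8, 0), n_ab = c(0, 8), n_ba = c(0, 0),
                               n_bb = c(2, 2))
  lk[, `:=`(n_a = n_aa + n_bb, n_b = n_ab + n_ba)]
  lk[, F := n_a + n_b]
  g <- build_graph(lk, 0:2, epsilon = 0)
  f <- grow_spanning_forest(g)
  asg <- f$assignment
  expect_equal(nrow(asg), 3L)
  expect_equal(length(unique(asg$tree)), 1L)
  # positive edge 0-1 keeps the state, negative edge 1-2 flips it
  expect_equal(asg[asg$vertex == 0L, phase], asg[asg$vertex == 1L, phase])
  expect_false(asg[asg$vertex == 2L, phase] == asg[asg$vertex == 1L, phase])
})

test_that("a triangle keeps its two heaviest edges", {
  edges <- data.table::data.table(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L),
                                  W = c(0.9, 0.6, 0.5), F = c(10, 10, 10))
  f <- structure(list(edges = edges, vertices = 0:2, epsilon = 0.01,
                      cov_threshold = 2), class = "phasing_graph")
  forest <- grow_spanning_forest(f)
  expect_equal(forest_total_weight(forest, edges), 1.5)
  single <- structure(list(edges = edges[0], vertices = 7L, epsilon = 0.01,
                           cov_threshold = 2), class = "phasing_graph")
  sf <- grow_spanning_forest(single)
  expect_equal(nrow(sf$assignment), 1L)
  expect_true(is.na(sf$assignment$parent))
})

test_that("greedy forest weight matches the independent spanning-tree oracle", {
  set.seed(43)
  for (trial in 1:100) {
    nv <- sample(3:10, 1)
    edges <- random_graph_edges(nv, p_edge = 0.6)
    g <- structure(list(edges = edges, vertices = seq_len(nv) - 1L,
                        epsilon = 0.01, cov_threshold = 1),
                   class = "phasing_graph")
    forest <- grow_spanning_forest(g)
    expect_equal(forest_total_weight(forest, edges),
                 igraph_msf_weight(edges, nv), tolerance = 1e-9)
  }
})

test_that("noise-free single-clone founding sites phase into the true haplotype", {
  sim <- simulate_tumor(clean_single_clone_config(seed = 37, length = 6000L))
  v <- extract_vpes(sim)
  chains <- do.call(c, lapply(group_by_start(v), build_short_chains))
  lk <- count_linkage(chains)
  sites <- sim$truth$sites
  g <- build_graph(lk, sites$site, epsilon = 0, cov_threshold = 2)
  f <- grow_spanning_forest(g)
  asg <- f$assignment
  # within every tree, the phase equals one true haplotype up to global flip
  for (tr in unique(asg$tree)) {
    sub <- asg[asg$tree == tr & !is.na(asg$phase), ]
    if (nrow(sub) < 2L) next
    side_b <- sites$side[sub$vertex + 1L]       # side carrying the mutation
    got_b <- sub$phase == "B"
    # the tracked haplotype is one fixed side: B exactly where that side mutated
    fl <- xor(got_b, side_b == side_b[1])
    expect_true(all(fl) || all(!fl))
  }
})
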