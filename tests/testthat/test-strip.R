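test_that("literal level-stripping sums match hand evaluation", {
  r <- c(0.3, 0.5, 0.2)
  st <- strip_counts(list(n_a = 15, n_b = 5, F = 20), r, k = 0L,
                     mode = "as-printed")
  expect_equal(st$p_a, 20 * (0.3 + 0.35))
  expect_equal(st$p_b, 20 * 0.35)
  expect_equal(st$n_a_hat, 2)
  expect_equal(st$n_b_hat, 0)   # 5 - 7 clamped at zero
})

test_that("non-carrier stripping removes the even cis/trans split of parental clones", {
  r <- c(0.3, 0.5, 0.2)
  st <- strip_counts(list(n_a = 15, n_b = 5, F = 20), r, k = 0L,
                     mode = "uninformative-read")
  expect_equal(st$p_a, 3)   # half of r_0 times |F|
  expect_equal(st$p_b, 3)
  expect_equal(st$n_a_hat, 12)
  expect_equal(st$n_b_hat, 2)
})

test_that("clones carrying neither variant strip only the cis side", {
  r <- c(0.3, 0.5, 0.2)
  # pair of clone-1 and clone-2 variants: clone 0 reads are all (A,A)
  st <- strip_counts(list(n_a = 11, n_b = 9, F = 20), r, k = 1L,
                     mode = "uninformative-read", lower = 1L)
  expect_equal(st$p_a, 20 * (0.3 + 0.25))
  expect_equal(st$p_b, 20 * 0.25)
  # trans-linked truth: expected counts (A: r0 + r1/2, B: r1/2 + r2) * |F|
  # survive stripping with the correct (negative) orientation
  expect_lt(st$n_a_hat, st$n_b_hat)
})

test_that("stripping is a no-op when no parental mass exists", {
  st <- strip_counts(list(n_a = 9, n_b = 3, F = 12), c(1e-12, 0.6, 0.4 - 1e-12),
                     k = 0L, mode = "uninformative-read")
  expect_equal(st$n_a_hat, 9, tolerance = 1e-9)
  expect_equal(st$n_b_hat, 3, tolerance = 1e-9)
  expect_error(strip_counts(list(n_a = 1, n_b = 1, F = 2), c(0.3, 0.5, 0.2),
                            k = 5L), "range")
  expect_error(strip_counts(list(n_a = 1, n_b = 1, F = 2), c(0.3, 0.3), k = 0L),
               "sum to 1")
})

test_that("stripped weights follow the adjusted-count probabilities", {
  w <- stripped_weight(list(n_a_hat = 12, n_b_hat = 2), epsilon = 0.01)
  expect_equal(w, 0.686, tolerance = 5e-4)
  expect_equal(stripped_weight(list(n_a_hat = 5, n_b_hat = 5), 0.01), 0)
  expect_true(is.na(stripped_weight(list(n_a_hat = 0, n_b_hat = 0), 0.01)))
  # the two adjusted connection probabilities sum to one
  set.seed(47)
  na <- stats::runif(200, 0, 20); nb <- stats::runif(200, 0, 20)
  eps <- stats::runif(200, 0, 0.4)
  cs <- (1 - eps)^2 + eps^2; cf <- 2 * eps * (1 - eps)
  fa <- (cs * na + cf * nb) / (na + nb)
  fb <- (cs * nb + cf * na) / (na + nb)
  expect_true(all(abs(fa + fb - 1) < 1e-12))
})

test_that("the stripped graph keeps strict-threshold edges among unphased sites", {
  mk_structure <- function() {
    base::structure(list(
      I = 2L,
      assignments = data.table::data.table(site = 0:2, clone = c(0L, 0L, 1L)),
      means = c(0.5, 0.25), proportions = c(0.5, 0.5),
      flagged_hom = integer(), dropped = integer()),
      class = "clonal_structure")
  }
  # counts chosen so |W'| lands exactly at, then just above, delta
  lk <- data.table::data.table(
    i = c(0L, 1L), j = c(2L, 2L),
    n_aa = c(11, 12), n_ab = c(9, 8), n_ba = c(0, 0), n_bb = c(0, 0))
  lk[, `:=`(n_a = n_aa + n_bb, n_b = n_ab + n_ba)]
  lk[, F := n_a + n_b]
  cs <- mk_structure()
  # strip half of r_0: p = 5 from each side; (6,4) -> W' = 0.2; (7,3) -> 0.4
  g <- build_stripped_graph(lk, cs, epsilon = 0, delta = 0.2)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$i, 1L)
  g2 <- build_stripped_graph(lk, cs, epsilon = 0, delta = 0.19)
  expect_equal(nrow(g2$edges), 2L)
  # founding-founding pairs are never re-edged here
  lk00 <- data.table::data.table(i = 0L, j = 1L, n_aa = 20, n_ab = 0,
                                 n_ba = 0, n_bb = 0, n_a = 20, n_b = 0, F = 20)
  expect_equal(nrow(build_stripped_graph(lk00, cs, 0, 0.1)$edges), 0L)
})

test_that("tree extension inherits phase across stripped edges and adapts thresholds", {
  cs <- base::structure(list(
    I = 2L,
    assignments = data.table::data.table(site = 0:2, clone = c(0L, 0L, 1L)),
    means = c(0.5, 0.25), proportions = c(0.5, 0.5),
    flagged_hom = integer(), dropped = integer()),
    class = "clonal_structure")
  lk <- data.table::data.table(
    i = c(0L, 1L), j = c(1L, 2L),
    n_aa = c(20, 14), n_ab = c(0, 6), n_ba = c(0, 0), n_bb = c(20, 0))
  lk[, `:=`(n_a = n_aa + n_bb, n_b = n_ab + n_ba)]
  lk[, F := n_a + n_b]
  g <- build_graph(lk, 0:1, epsilon = 0, cov_threshold = 2)
  forest <- grow_spanning_forest(g)
  ext <- extend_tree(forest, lk, cs, epsilon = 0, strip_config())
  asg <- ext$assignment
  expect_setequal(asg$vertex, 0:2)
  # positive stripped edge 1-2: site 2 copies site 1's phase
  expect_equal(asg[asg$vertex == 2L, phase], asg[asg$vertex == 1L, phase])
  expect_true(all(asg$tree == asg$tree[1]))

  # empty stripped graph leaves the forest unchanged
  lk0 <- lk[1]
  ext0 <- extend_tree(forest, lk0, cs, epsilon = 0, strip_config())
  expect_identical(sort(ext0$assignment$vertex), sort(forest$assignment$vertex))

  # a site attachable only once the coverage threshold halves to 1
  lk1 <- data.table::rbindlist(list(lk[1], data.table::data.table(
    i = 1L, j = 2L, n_aa = 0.8, n_ab = 0.2, n_ba = 0, n_bb = 0,
    n_a = 0.8, n_b = 0.2, F = 1)))
  ext1 <- extend_tree(forest, lk1, cs, epsilon = 0,
                      strip_config(cov_threshold = 2, cov_floor = 1))
  expect_true(2L %in% ext1$assignment$vertex)
  expect_gte(ext1$halvings, 1L)
  ext1b <- extend_tree(forest, lk1, cs, epsilon = 0,
                       strip_config(adaptive = FALSE))
  expect_false(2L %in% ext1b$assignment$vertex)
})

test_that("descendant sites attach with the true phase on clean three-clone data", {
  cfg <- sim_config(reference_length = 30000, seed = 53, epsilon = 0,
                    libraries = list(library_spec(600, read_length = 150, coverage = 100),
                                     library_spec(900, read_length = 150, coverage = 60)))
  sim <- simulate_tumor(cfg)
  sites <- sim$truth$sites
  v <- extract_vpes(sim)
  chains <- do.call(c, lapply(group_by_start(v), build_short_chains))
  lk <- count_linkage(chains)
  # use the true clonal structure to isolate the stripping stage
  cs <- base::structure(list(
    I = 3L, assignments = sites[, .(site, clone = sub)],
    means = c(0.5, 0.35, 0.1), proportions = c(0.3, 0.5, 0.2),
    flagged_hom = integer(), dropped = integer()), class = "clonal_structure")
  g <- build_graph(lk, sites[sub == 0L, site], epsilon = 0, cov_threshold = 2)
  forest <- grow_spanning_forest(g)
  ext <- extend_tree(forest, lk, cs, epsilon = 0, strip_config())
  recon <- build_haplotypes(ext, cs, sites)
  m <- score(recon, sim$truth)
  expect_gte(m$accuracy_rate, 0.95)
})
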