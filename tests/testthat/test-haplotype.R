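mk_forest <- function(vertex, tree, phase, parent = rep(NA_integer_, length(vertex))) {
  base::structure(list(assignment = data.table::data.table(
    vertex = vertex, tree = tree, phase = phase, parent = parent)),
    class = "spanning_forest")
}

mk_sites <- function(pos, sub = rep(0L, length(pos))) {
  data.table::data.table(site = seq_along(pos) - 1L, pos = as.integer(pos),
                         ref = "A", alt = "G", sub = sub,
                         side = rep(0L, length(pos)))
}

test_that("each multi-site tree becomes one position-sorted fragment", {
  sites <- mk_sites(c(10, 20, 30, 40, 50))
  f <- mk_forest(0:4, rep(1L, 5), c("B", "A", "B", "A", "A"))
  lin <- linearize_tree(f, sites)
  expect_equal(nrow(lin), 5L)
  expect_equal(unique(lin$fragment), 1L)
  expect_equal(lin$pos, sites$pos)

  f3 <- mk_forest(0:5, c(1L, 1L, 2L, 2L, 3L, 3L), rep("B", 6))
  expect_equal(length(unique(linearize_tree(f3, mk_sites(1:6 * 10))$fragment)), 3L)

  # singleton trees are not fragments
  fs <- mk_forest(0:2, c(1L, 1L, 2L), c("B", "A", "B"))
  expect_equal(nrow(linearize_tree(fs, mk_sites(c(10, 20, 30)))), 2L)
})

test_that("the companion haplotype is the heterozygous complement", {
  placed <- data.table::data.table(site = 0:2, state = c("B", "A", "B"),
                                   sub = c(0L, 0L, 0L))
  anc <- derive_ancestors(placed, I = 1L)
  expect_identical(anc$matrix[1, ], c("B", "A", "B"))
  expect_identical(anc$matrix[2, ], c("A", "B", "A"))
})

test_that("ancestor derivation applies the inheritance formulas", {
  # three clones, one site arising in clone 1, carried by the last clone's father
  placed <- data.table::data.table(site = 0L, state = "B", sub = 1L)
  anc <- derive_ancestors(placed, I = 3L)
  col <- anc$matrix[, 1]
  # father chains: clone 2 B, clone 1 B (sub <= 1), clone 0 A (sub > 0)
  expect_identical(col[c(5, 3, 1)], c("B", "B", "A"))
  # companions all A: complement of B for carriers, pre-mutation A otherwise
  expect_identical(col[c(6, 4, 2)], c("A", "A", "A"))

  # a founding mutation propagates to one haplotype of every clone
  f0 <- derive_ancestors(data.table::data.table(site = 0L, state = "B", sub = 0L), I = 3L)
  expect_identical(f0$matrix[, 1], c("B", "A", "B", "A", "B", "A"))

  # a reference state in the child always stays reference in the parent
  fa <- derive_ancestors(data.table::data.table(site = 0L, state = "A", sub = 1L), I = 3L)
  expect_identical(fa$matrix[1, 1], "A")
  # and the mutation lives on the companion side of the carrier clones
  expect_identical(fa$matrix[, 1], c("A", "A", "A", "B", "A", "B"))
})

test_that("derived haplotypes always satisfy the inheritance invariant", {
  set.seed(59)
  for (trial in 1:1000) {
    I <- sample(1:4, 1)
    n <- sample(1:12, 1)
    placed <- data.table::data.table(
      site = seq_len(n) - 1L,
      state = sample(c("A", "B"), n, replace = TRUE),
      sub = sample(seq_len(I) - 1L, n, replace = TRUE))
    m <- derive_ancestors(placed, I)$matrix
    if (I > 1L) {
      for (i in seq_len(I - 1L)) {
        parent_b <- m[2 * (i - 1) + 1, ] == "B"
        child_b <- m[2 * i + 1, ] == "B"
        expect_true(all(child_b[parent_b]))
        parent_b2 <- m[2 * (i - 1) + 2, ] == "B"
        child_b2 <- m[2 * i + 2, ] == "B"
        expect_true(all(child_b2[parent_b2]))
      }
    }
    # heterozygous where arisen, double-reference before
    for (i in seq_len(I) - 1L) {
      het <- placed$sub <= i
      expect_true(all((m[2 * i + 1, het] != m[2 * i + 2, het])))
      expect_true(all(m[2 * i + 1, !het] == "A" & m[2 * i + 2, !het] == "A"))
    }
  }
})

test_that("scoring a perfect reconstruction gives unit rates and the right span", {
  sim <- simulate_tumor(clean_single_clone_config(seed = 61, length = 5000L))
  sites <- sim$truth$sites
  # build the reconstruction directly from truth: tracked haplotype = side-1
  f <- mk_forest(sites$site, rep(1L, nrow(sites)),
                 ifelse(sites$side == 1L, "B", "A"))
  cs <- base::structure(list(I = 1L,
                             assignments = sites[, .(site, clone = 0L)],
                             means = 0.5, proportions = 1,
                             flagged_hom = integer(), dropped = integer()),
                        class = "clonal_structure")
  recon <- build_haplotypes(f, cs, sites)
  m <- score(recon, sim$truth)
  expect_equal(m$recognition_rate, 1.0)
  expect_equal(m$accuracy_rate, 1.0)
  expect_equal(m$fragment_count, 1L)
  expect_equal(m$longest_length, max(sites$pos) - min(sites$pos) + 1L)

  # flipping the whole fragment leaves the score unchanged
  f_flip <- mk_forest(sites$site, rep(1L, nrow(sites)),
                      ifelse(sites$side == 1L, "A", "B"))
  m_flip <- score(build_haplotypes(f_flip, cs, sites), sim$truth)
  expect_equal(m_flip$accuracy_rate, 1.0)
})

test_that("recognition counts placed sites and spans use reference coordinates", {
  sites <- mk_sites(c(100, 5000, 10167, 15000), sub = rep(0L, 4))
  truth <- base::structure(list(
    sites = sites,
    haplotypes = matrix(c("B", "A"), nrow = 2, ncol = 4)[, , drop = FALSE],
    I = 1L), class = "truth_set")
  truth$haplotypes <- matrix("A", 2, 4); truth$haplotypes[1, ] <- "B"
  cs <- base::structure(list(I = 1L, assignments = sites[, .(site, clone = 0L)],
                             means = 0.5, proportions = 1,
                             flagged_hom = integer(), dropped = integer()),
                        class = "clonal_structure")
  # only the first two sites placed -> recognition 0.5
  f <- mk_forest(0:2, c(1L, 1L, 2L), c("B", "B", "B"))
  recon <- build_haplotypes(f, cs, sites)
  m <- score(recon, truth)
  expect_equal(m$recognition_rate, 0.5)
  expect_equal(m$fragment_count, 1L)
  # span of positions 100..10167 printed in bp
  f2 <- mk_forest(0:2, c(1L, 1L, 1L), c("B", "B", "B"))
  m2 <- score(build_haplotypes(f2, cs, sites), truth)
  expect_equal(m2$longest_length, 10068L)
  # no site is double-placed across fragments
  expect_equal(sum(recon$fragments$n_sites), nrow(recon$placed))
})
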