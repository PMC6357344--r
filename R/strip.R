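#' Strip the expected parental-clone contribution from linkage counts
#'
#' When a pair of sites involves a mutation younger than the founding
#' clone, reads from clones that predate the younger mutation dilute the
#' linkage signal. Stripping removes their expected contribution before
#' re-weighting, level by level from the founding clone outward; clones
#' `0..k` are treated as parental.
#'
#' Two modes are provided. `"uninformative-read"` (default) removes the
#' expected counts of the non-carrier clones: a clone carrying neither
#' variant reads (A,A) on both haplotypes (contributing `r_i` to `N^A`),
#' while a clone carrying only the older variant splits evenly between the
#' (B,A) and (A,A) patterns (contributing `r_i / 2` to each of `N^B` and
#' `N^A`). `lower` is the clone label of the older variant; with
#' `lower = 0` both strips reduce to the symmetric
#' `|F| * 1/2 * sum_{0 <= i <= k} r_i` from each of `N^A` and `N^B`.
#' `"as-printed"` applies the literal level-stripping sums
#' `P^A = |F| (sum_{i <= k} r_i + 1/2 sum_{i > k} r_i)`,
#' `P^B = |F| (1/2 sum_{i > k} r_i)`; since these total `|F|`, the adjusted
#' counts rely on the clamp at zero and the mode is kept for fidelity
#' checks rather than inference.
#'
#' @param counts List/data.frame with `n_a`, `n_b`, `F` (vectorised).
#' @param r Sub-clone proportions summing to 1.
#' @param k Last clone treated as parental, in `0..I-1` (vectorised).
#' @param mode `"uninformative-read"` or `"as-printed"`.
#' @param lower Clone label of the older variant of the pair (vectorised;
#'   used by `"uninformative-read"` only).
#' @return A data.table with `p_a`, `p_b` (stripped amounts) and `n_a_hat`,
#'   `n_b_hat` (adjusted counts, clamped at 0).
#' @export
strip_counts <- function(counts, r, k,
                         mode = c("uninformative-read", "as-printed"),
                         lower = 0L) {
  mode <- match.arg(mode)
  if (abs(sum(r) - 1) > 1e-6) stop("proportions must sum to 1")
  I <- length(r)
  if (any(k < 0L | k >= I)) stop("k out of range 0..I-1")
  cs <- c(0, cumsum(r))                 # cs[m+1] = sum of r_0..r_{m-1}
  if (mode == "as-printed") {
    parental <- cs[k + 2L]              # sum_{0 <= i <= k} r_i
    younger <- 1 - parental
    p_a <- counts$F * (parental + 0.5 * younger)
    p_b <- counts$F * 0.5 * younger
  } else {
    lower <- pmin(lower, k + 1L)
    older_only <- cs[k + 2L] - cs[lower + 1L]   # clones lower..k
    neither <- cs[lower + 1L]                   # clones < lower
    p_a <- counts$F * (neither + 0.5 * older_only)
    p_b <- counts$F * 0.5 * older_only
  }
  data.table::data.table(p_a = p_a, p_b = p_b,
                         n_a_hat = pmax(counts$n_a - p_a, 0),
                         n_b_hat = pmax(counts$n_b - p_b, 0))
}

#' Linkage weight from stripped counts
#'
#' Same error-aware connection probabilities as [edge_weight()] but with
#' the adjusted counts and their sum as denominator:
#' `f'_A = (((1-e)^2+e^2) N^A_hat + 2e(1-e) N^B_hat) / (N^A_hat + N^B_hat)`;
#' `W' = f'_A - f'_B`. Pairs whose adjusted counts vanish give `NA` (no
#' effective edge).
#'
#' @param stripped Output of [strip_counts()].
#' @param epsilon Per-base error probability.
#' @return Numeric vector of stripped weights (`NA` where undefined).
#' @export
stripped_weight <- function(stripped, epsilon) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  tot <- stripped$n_a_hat + stripped$n_b_hat
  c_same <- (1 - epsilon)^2 + epsilon^2
  c_flip <- 2 * epsilon * (1 - epsilon)
  f_a <- (c_same * stripped$n_a_hat + c_flip * stripped$n_b_hat) / tot
  f_b <- (c_same * stripped$n_b_hat + c_flip * stripped$n_a_hat) / tot
  ifelse(tot > 0, f_a - f_b, NA_real_)
}

#' Configuration of the stripping and tree-extension stage
#'
#' @param delta Stripped-weight threshold; an edge needs `|W'| > delta`.
#' @param cov_threshold Coverage threshold for stripped edges.
#' @param delta_floor,cov_floor Lower bounds reached by adaptive halving.
#' @param max_halvings How many times the thresholds may be halved when
#'   sites remain unattached.
#' @param adaptive Enable the adaptive loosening.
#' @param mode Stripping mode, see [strip_counts()].
#' @return A `strip_config` list.
#' @export
strip_config <- function(delta = 0.1, cov_threshold = 2,
                         delta_floor = 0.025, cov_floor = 1,
                         max_halvings = 2L, adaptive = TRUE,
                         mode = c("uninformative-read", "as-printed")) {
  if (delta <= 0 || delta >= 1) stop("delta must be in (0, 1)")
  if (delta_floor > delta || cov_floor > cov_threshold)
    stop("floors must not exceed the initial thresholds")
  structure(list(delta = delta, cov_threshold = cov_threshold,
                 delta_floor = delta_floor, cov_floor = cov_floor,
                 max_halvings = as.integer(max_halvings),
                 adaptive = isTRUE(adaptive), mode = match.arg(mode)),
            class = "strip_config")
}

#' Build the stripped phasing graph over not-yet-phased sites
#'
#' For every counted pair that involves at least one non-founding site,
#' the parental level is the larger clone label minus one and the older
#' variant's label bounds the asymmetric strip; the stripped weight is
#' computed and an edge kept when `|F| >= cov_threshold` and
#' `|W'| > delta` (strict). Pairs of two founding sites are handled by the
#' initial graph and are not re-edged here.
#'
#' @param link Pair-count table from [count_linkage()].
#' @param structure A `clonal_structure`.
#' @param epsilon Per-base error probability.
#' @param delta Stripped-weight threshold.
#' @param cov_threshold Coverage threshold.
#' @param mode Stripping mode.
#' @return A `phasing_graph` whose edge weights are `W'`.
#' @export
build_stripped_graph <- function(link, structure, epsilon = 0.01,
                                 delta = 0.1, cov_threshold = 2,
                                 mode = "uninformative-read") {
  asg <- structure$assignments
  usable <- setdiff(asg$site, structure$flagged_hom)
  cl <- asg$clone[match(usable, asg$site)]
  names(cl) <- usable
  e <- link[i %in% usable & j %in% usable]
  e <- data.table::copy(e)
  if (nrow(e) > 0L) {
    ci <- cl[as.character(e$i)]
    cj <- cl[as.character(e$j)]
    e[, `:=`(clone_i = ci, clone_j = cj)]
    e <- e[pmax(clone_i, clone_j) > 0L & F >= cov_threshold]
  }
  if (nrow(e) > 0L) {
    a <- pmin(e$clone_i, e$clone_j)
    b <- pmax(e$clone_i, e$clone_j)
    st <- strip_counts(e, structure$proportions, k = b - 1L, mode = mode,
                       lower = a)
    e[, W := stripped_weight(st, epsilon)]
    e <- e[!is.na(W) & abs(W) > delta]
  } else {
    e[, W := numeric(0)]
  }
  vertices <- sort(unique(usable))
  structure(list(edges = e, vertices = vertices, epsilon = epsilon,
                 cov_threshold = cov_threshold, delta = delta),
            class = "phasing_graph")
}

#' Extend the founding spanning forest with descendant sites
#'
#' The forest `T` built on founding sites is extended to `T'` by the same
#' frontier-greedy rule on the stripped graph `G'`: the already-phased
#' vertices seed the growth and a new vertex inherits the phase of its
#' attachment point (flipped on a negative edge). If sites remain
#' unattached the coverage and weight thresholds are halved (not below
#' their floors) and the edge set rebuilt. Finally, sites unreachable from
#' `T` but linked among themselves are phased into new trees of their own.
#'
#' @param forest A `spanning_forest` from [grow_spanning_forest()].
#' @param link Pair-count table from [count_linkage()].
#' @param structure A `clonal_structure`.
#' @param epsilon Per-base error probability.
#' @param config A [strip_config()].
#' @return A `spanning_forest` whose vertex set contains the forest's.
#' @export
extend_tree <- function(forest, link, structure, epsilon = 0.01,
                        config = strip_config()) {
  asg <- forest$assignment
  delta <- config$delta
  cov <- config$cov_threshold
  halvings <- 0L
  gp <- NULL
  repeat {
    gp <- build_stripped_graph(link, structure, epsilon, delta, cov,
                               mode = config$mode)
    vertices <- sort(union(gp$vertices, asg$vertex))
    grown <- .grow_forest(gp$edges, vertices,
                          init = asg[, .(vertex, tree, phase)],
                          allow_seed = FALSE)
    unattached <- setdiff(gp$vertices, grown$vertex)
    if (length(unattached) == 0L || !config$adaptive ||
        halvings >= config$max_halvings) break
    delta <- max(delta / 2, config$delta_floor)
    cov <- max(cov / 2, config$cov_floor)
    halvings <- halvings + 1L
  }
  # phase leftover sites among themselves into fresh trees (only sites that
  # still have an effective edge; isolated sites stay unplaced)
  leftover <- setdiff(gp$vertices, grown$vertex)
  leftover <- intersect(leftover, union(gp$edges$i, gp$edges$j))
  if (length(leftover)) {
    sub_edges <- gp$edges[i %in% leftover & j %in% leftover]
    extra <- .grow_forest(sub_edges, sort(leftover), allow_seed = TRUE,
                          next_tree = max(grown$tree, 0L) + 1L)
    grown <- rbind(grown, extra)
  }
  parents <- asg[, .(vertex, parent)]
  grown <- merge(grown, parents, by = "vertex", all.x = TRUE,
                 suffixes = c("", ".init"))
  grown[!is.na(parent.init), parent := parent.init]
  grown[, parent.init := NULL]
  data.table::setorder(grown, tree, vertex)
  structure(list(assignment = grown, delta = delta, cov_threshold = cov,
                 halvings = halvings),
            class = "spanning_forest")
}
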