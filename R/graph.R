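#' Tally linkage modes for site pairs covered by short chains
#'
#' For every pair of sites co-covered by a chain (up to `window` site-index
#' distance apart) the chain contributes its local supporting multiplicity
#' (the smaller of the per-site supports at the two sites) to the count of
#' its joint state: `n_aa`/`n_bb` are the cis modes, `n_ab`/`n_ba` trans.
#' `F = n_aa + n_ab + n_ba + n_bb` is the pair's coverage level.
#'
#' @param chains List of chains from [arrange_groups()] (or
#'   [build_short_chains()]).
#' @param window Largest site-index distance of counted pairs; linkage at
#'   longer range would be supported by no read anyway.
#' @return A data.table: `i`, `j` (site indices, `i < j`), `n_aa`, `n_ab`,
#'   `n_ba`, `n_bb`, `n_a = n_aa + n_bb`, `n_b = n_ab + n_ba`, `F`.
#' @export
count_linkage <- function(chains, window = 50L) {
  rows <- lapply(chains, function(ch) {
    L <- length(ch$sites)
    if (L < 2L) return(NULL)
    maxd <- min(L - 1L, window)
    ii <- integer(0); jj <- integer(0)
    for (d in seq_len(maxd)) {
      t <- seq_len(L - d)
      keep <- (ch$sites[t + d] - ch$sites[t]) <= window
      ii <- c(ii, t[keep]); jj <- c(jj, t[keep] + d)
    }
    if (!length(ii)) return(NULL)
    data.table::data.table(
      i = ch$sites[ii], j = ch$sites[jj],
      mode = paste0(ifelse(ch$states[ii], "b", "a"),
                    ifelse(ch$states[jj], "b", "a")),
      w = pmin(ch$supp[ii], ch$supp[jj]))
  })
  dt <- data.table::rbindlist(rows)
  if (nrow(dt) == 0L) {
    return(data.table::data.table(i = integer(), j = integer(),
                                  n_aa = numeric(), n_ab = numeric(),
                                  n_ba = numeric(), n_bb = numeric(),
                                  n_a = numeric(), n_b = numeric(), F = numeric()))
  }
  agg <- dt[, .(w = sum(w)), by = .(i, j, mode)]
  out <- data.table::dcast(agg, i + j ~ mode, value.var = "w", fill = 0)
  for (m in c("aa", "ab", "ba", "bb"))
    if (!m %in% names(out)) out[, (m) := 0]
  data.table::setnames(out, c("aa", "ab", "ba", "bb"),
                       c("n_aa", "n_ab", "n_ba", "n_bb"))
  out[, `:=`(n_a = n_aa + n_bb, n_b = n_ab + n_ba)]
  out[, F := n_a + n_b]
  data.table::setorder(out, i, j)
  out[]
}

#' Error-aware linkage weight of a site pair
#'
#' With per-base error probability `epsilon`, a read truly in the cis mode
#' is observed cis with probability `(1-e)^2 + e^2` and trans with
#' probability `2 e (1-e)` (one of the two bases flipped). The connection
#' probabilities are
#' `f_A = (((1-e)^2+e^2) N^A + 2e(1-e) N^B) / |F|` and symmetrically `f_B`;
#' the weight is `W = f_A - f_B`. `f_A + f_B = 1`, so `W` lies in `[-1, 1]`;
#' its sign encodes the linkage mode (positive: cis, {(A,A),(B,B)}),
#' its magnitude the reliability.
#'
#' @param counts A list/data.frame with `n_a`, `n_b`, `F` (vectorised).
#' @param epsilon Per-base error probability in `[0, 1)`.
#' @return Numeric vector of weights.
#' @export
edge_weight <- function(counts, epsilon) {
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  if (any(counts$F <= 0)) stop("edge weight undefined for |F| = 0")
  c_same <- (1 - epsilon)^2 + epsilon^2
  c_flip <- 2 * epsilon * (1 - epsilon)
  f_a <- (c_same * counts$n_a + c_flip * counts$n_b) / counts$F
  f_b <- (c_same * counts$n_b + c_flip * counts$n_a) / counts$F
  f_a - f_b
}

#' Build the weighted phasing graph over founding-clone sites
#'
#' Vertices are the founding-clone sites (clone label 0, homozygous-flagged
#' sites excluded); an edge joins a pair when its chain coverage reaches
#' `cov_threshold`, weighted by [edge_weight()]. The graph is typically
#' disconnected.
#'
#' @param link Pair-count table from [count_linkage()].
#' @param founding_sites Integer site indices of the founding clone.
#' @param epsilon Per-base error probability.
#' @param cov_threshold Minimum coverage `|F|` for an edge (default 2).
#' @return A `phasing_graph`: `edges` (data.table `i`, `j`, `W`, `F`, mode
#'   counts), `vertices`, `epsilon`, `cov_threshold`.
#' @export
build_graph <- function(link, founding_sites, epsilon = 0.01, cov_threshold = 2) {
  founding_sites <- sort(unique(as.integer(founding_sites)))
  e <- link[i %in% founding_sites & j %in% founding_sites & F >= cov_threshold]
  e <- data.table::copy(e)
  if (nrow(e) > 0L) e[, W := edge_weight(.SD, epsilon)] else e[, W := numeric(0)]
  structure(list(edges = e, vertices = founding_sites, epsilon = epsilon,
                 cov_threshold = cov_threshold),
            class = "phasing_graph")
}

# Greedy frontier growth shared by the founding tree and its extension.
# edges: data.table i, j, W, F. vertices: integer vertex ids.
# init: optional data.table (vertex, tree, phase) of already-phased seeds.
# allow_seed: open new trees for unreached vertices (seed = vertex with
# maximal summed incident |W|, anchored to state B).
.grow_forest <- function(edges, vertices, init = NULL, allow_seed = TRUE,
                         next_tree = 1L) {
  nv <- length(vertices)
  vid <- seq_len(nv)
  lookup <- function(v) match(v, vertices)
  in_forest <- rep(FALSE, nv)
  phase <- rep(NA, nv)          # TRUE = B
  tree <- rep(NA_integer_, nv)
  parent <- rep(NA_integer_, nv)
  ne <- nrow(edges)
  if (ne > 0L) {
    dfrom <- c(lookup(edges$i), lookup(edges$j))
    dto <- c(lookup(edges$j), lookup(edges$i))
    keep <- !is.na(dfrom) & !is.na(dto)
    dfrom <- dfrom[keep]; dto <- dto[keep]
    dabs <- rep(abs(edges$W), 2L)[keep]
    dpos <- rep(edges$W > 0, 2L)[keep]
    dF <- rep(edges$F, 2L)[keep]
    adj <- split(seq_along(dfrom), dfrom)
  } else {
    dfrom <- dto <- integer(0); dabs <- dF <- numeric(0); dpos <- logical(0)
    adj <- list()
  }
  strength <- numeric(nv)
  if (length(dfrom)) {
    s <- tapply(dabs, dfrom, sum)
    strength[as.integer(names(s))] <- s
  }
  cand <- integer(0)
  push <- function(v) {
    a <- adj[[as.character(v)]]
    if (!is.null(a)) cand <<- c(cand, a)
  }
  if (!is.null(init) && nrow(init) > 0L) {
    iv <- lookup(init$vertex)
    ok <- !is.na(iv)
    in_forest[iv[ok]] <- TRUE
    phase[iv[ok]] <- init$phase[ok] == "B"
    tree[iv[ok]] <- init$tree[ok]
    for (v in iv[ok]) push(v)
    next_tree <- max(next_tree, max(init$tree) + 1L)
  }
  repeat {
    if (length(cand)) cand <- cand[!in_forest[dto[cand]]]
    if (!length(cand)) {
      if (!allow_seed) break
      left <- which(!in_forest)
      if (!length(left)) break
      seed <- left[order(-strength[left], left)][1L]
      in_forest[seed] <- TRUE
      phase[seed] <- TRUE          # anchored to B; phase is defined up to flip
      tree[seed] <- next_tree
      next_tree <- next_tree + 1L
      push(seed)
      next
    }
    ca <- dabs[cand]
    m <- max(ca)
    sel <- cand[ca == m]
    if (length(sel) > 1L) {
      sf <- dF[sel]
      sel <- sel[sf == max(sf)]
      if (length(sel) > 1L) sel <- sel[order(dto[sel], dfrom[sel])]
    }
    eid <- sel[1L]
    v <- dto[eid]; u <- dfrom[eid]
    in_forest[v] <- TRUE
    phase[v] <- if (dpos[eid]) phase[u] else !phase[u]
    tree[v] <- tree[u]
    parent[v] <- u
    push(v)
  }
  keep <- in_forest
  data.table::data.table(vertex = vertices[keep],
                         tree = tree[keep],
                         phase = ifelse(phase[keep], "B", "A"),
                         parent = vertices[parent[keep]])
}

#' Grow the greedy maximum spanning forest of a phasing graph
#'
#' Per connected component, the vertex with the largest summed incident
#' `|W|` seeds a tree with its phase anchored to B (each tree's phase is
#' recoverable only up to a global flip). The frontier edge with maximal
#' `|W|` (ties: larger `|F|`, then smaller site index) is added repeatedly,
#' propagating the phase by edge sign: a positive edge copies the state, a
#' negative one flips it. The result is a maximum spanning tree of each
#' component under `|W|`.
#'
#' @param graph A `phasing_graph` from [build_graph()].
#' @return A `spanning_forest`: data.table `vertex`, `tree`, `phase`
#'   ("A"/"B" on the tracked haplotype), `parent`.
#' @export
grow_spanning_forest <- function(graph) {
  out <- .grow_forest(graph$edges, graph$vertices, allow_seed = TRUE)
  structure(list(assignment = out), class = "spanning_forest")
}
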