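# Shared fixture builders. Everything is generated in code; no data files.

# Small two-library tumor mixture used by several end-to-end tests.
small_mix_config <- function(seed = 7, epsilon = 0.01, I = 3L,
                             proportions = c(0.3, 0.5, 0.2),
                             length = 20000L) {
  sim_config(reference_length = length,
             n_subclones = I, proportions = proportions,
             libraries = list(library_spec(600, read_length = 150, coverage = 100),
                              library_spec(900, read_length = 150, coverage = 50)),
             epsilon = epsilon, seed = seed)
}

# Noise-free single-clone sample: every read reports its haplotype exactly.
clean_single_clone_config <- function(seed = 11, length = 10000L) {
  sim_config(reference_length = length,
             germline_rate = 0.002, somatic_rate = 0.01,
             n_subclones = 1L, proportions = 1,
             libraries = list(library_spec(500, read_length = 120, coverage = 80)),
             epsilon = 0, seed = seed)
}

# Hand-built observation table (pair_id, site, state) for VPE tests.
obs_table <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(rows, function(r) {
    data.table::data.table(pair_id = r[[1]], site = as.integer(r[[2]]),
                           state = r[[3]])
  }))
}

# VPE table from plain lists, mirroring extract_vpes() output.
vpe_table <- function(sites_list, states_list, mult = NULL) {
  n <- length(sites_list)
  if (is.null(mult)) mult <- rep(1L, n)
  data.table::data.table(
    vpe_id = seq_len(n),
    start = vapply(sites_list, `[`, integer(1), 1L),
    sites = lapply(sites_list, as.integer),
    states = states_list,
    mult = as.integer(mult),
    n_sites = lengths(sites_list))
}

# Random connected-ish weighted graph for the spanning-forest oracle.
random_graph_edges <- function(n_vertices, p_edge = 0.5) {
  pairs <- t(utils::combn(n_vertices, 2L))
  keep <- stats::runif(nrow(pairs)) < p_edge
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) {
    return(data.table::data.table(i = integer(), j = integer(),
                                  W = numeric(), F = numeric()))
  }
  data.table::data.table(i = pairs[, 1] - 1L, j = pairs[, 2] - 1L,
                         W = stats::runif(nrow(pairs), -1, 1),
                         F = sample(2:30, nrow(pairs), replace = TRUE))
}

# Total |W| of a maximum spanning forest computed by igraph (independent
# textbook oracle: minimum spanning tree on negated absolute weights).
igraph_msf_weight <- function(edges, n_vertices) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$i + 1L, to = edges$j + 1L),
    directed = FALSE, vertices = data.frame(name = seq_len(n_vertices)))
  mst <- igraph::mst(g, weights = -abs(edges$W))
  # recover |W| of kept edges by matching endpoints
  em <- igraph::as_edgelist(mst)
  key <- paste(pmin(as.integer(em[, 1]), as.integer(em[, 2])),
               pmax(as.integer(em[, 1]), as.integer(em[, 2])))
  ref <- paste(edges$i + 1L, edges$j + 1L)
  sum(abs(edges$W)[match(key, ref)])
}

forest_total_weight <- function(forest, edges) {
  asg <- forest$assignment
  att <- asg[!is.na(asg$parent)]
  if (nrow(att) == 0L) return(0)
  key <- paste(pmin(att$vertex, att$parent), pmax(att$vertex, att$parent))
  ref <- paste(edges$i, edges$j)
  sum(abs(edges$W)[match(key, ref)])
}
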