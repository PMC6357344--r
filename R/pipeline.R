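#' Reconstruct clonal haplotypes from a mixed tumor sample
#'
#' Runs the full pipeline: collapse read-pairs to VPEs, estimate the clonal
#' structure from variant allele frequencies, assemble VPEs into short
#' chains, phase founding-clone sites through the weighted linkage graph
#' and its greedy maximum spanning forest, strip parental read depth to
#' phase descendant sites, and derive the 2I clonal haplotypes. When the
#' input carries a simulated truth the reconstruction is scored against it.
#'
#' @param x A `clonehap_sim` from [simulate_tumor()], or a list with
#'   elements `obs` (observation table), `sites` (site table) and
#'   optionally `truth`.
#' @param epsilon Per-base error probability used in the edge weights;
#'   defaults to the simulation's epsilon when available.
#' @param cov_threshold Coverage threshold for founding-graph edges.
#' @param strip Stripping/extension settings, a [strip_config()].
#' @param max_clusters,fixed_I Clustering options, see [cluster_vafs()].
#' @param window Pair-counting window, see [count_linkage()].
#' @param seed Seed for the (deterministic-by-default) clustering stage.
#' @return A `clonehap_fit` with the clonal structure, chains, forest,
#'   haplotype set, and metrics (when truth is known).
#' @export
phase_clones <- function(x, epsilon = NULL, cov_threshold = 2,
                         strip = strip_config(), max_clusters = 6L,
                         fixed_I = NULL, window = 50L, seed = 1L) {
  if (inherits(x, "clonehap_sim")) {
    sites <- x$truth$sites
    truth <- x$truth
    if (is.null(epsilon)) epsilon <- x$config$epsilon
    input <- x
  } else {
    sites <- data.table::as.data.table(x$sites)
    truth <- x$truth
    if (is.null(epsilon)) epsilon <- 0.01
    input <- x$obs
  }
  vpes <- extract_vpes(input, sites)
  vaf <- compute_vaf(input, sites)
  cstruct <- cluster_vafs(vaf, max_clusters = max_clusters, fixed_I = fixed_I,
                          seed = seed)
  groups <- group_by_start(vpes)
  chain_groups <- lapply(groups, build_short_chains)
  chains <- do.call(c, chain_groups)
  arranged <- arrange_groups(chain_groups, cstruct$I)
  link <- count_linkage(chains, window = window)
  founding <- setdiff(cstruct$assignments[clone == 0L, site], cstruct$flagged_hom)
  graph <- build_graph(link, founding, epsilon, cov_threshold)
  forest <- grow_spanning_forest(graph)
  extended <- extend_tree(forest, link, cstruct, epsilon, strip)
  recon <- build_haplotypes(extended, cstruct, sites)
  metrics <- if (!is.null(truth)) score(recon, truth) else NULL
  base::structure(list(structure = cstruct, vpes = vpes, vaf = vaf,
                       chains = chains, arranged = arranged, link = link,
                       graph = graph,
                       forest = forest, extended = extended,
                       haplotypes = recon, metrics = metrics,
                       params = list(epsilon = epsilon,
                                     cov_threshold = cov_threshold,
                                     strip = strip, window = window,
                                     seed = seed)),
                  class = "clonehap_fit")
}

#' @export
print.clonehap_fit <- function(x, ...) {
  cat("Clonal haplotype reconstruction\n")
  cat(sprintf("  sub-clones: %d (proportions %s)\n", x$structure$I,
              paste(sprintf("%.2f", x$structure$proportions), collapse = ":")))
  cat(sprintf("  VPEs: %d (total multiplicity %d); chains: %d\n",
              nrow(x$vpes), sum(x$vpes$mult), length(x$chains)))
  cat(sprintf("  placed sites: %d in %d fragment(s)\n",
              nrow(x$haplotypes$placed), nrow(x$haplotypes$fragments)))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' @export
summary.clonehap_fit <- function(object, ...) {
  print(object)
  cat("\nCluster mean VAFs:", paste(sprintf("%.3f", object$structure$means),
                                    collapse = "  "), "\n")
  f <- object$haplotypes$fragments
  if (nrow(f)) {
    cat("Fragment spans (bp):\n")
    print(f[, .(fragment, start, end, span, n_sites)])
  }
  invisible(object)
}

#' Run the pipeline end to end with artifacts on disk
#'
#' File-based front end: either simulates a sample (when `config$simulate`
#' is a [sim_config()]) or reads alignments and sites from disk, then runs
#' [phase_clones()] and writes every intermediate (VPE TSV, VAF TSV,
#' cluster TSV, chain TSV, graph edge list, haplotype matrix, fragment BED,
#' metrics JSON) under `config$out_dir`.
#'
#' @param config A list: either `simulate` (a `sim_config`) or `reads` +
#'   `sites` paths; `out_dir`; optional `epsilon`, `cov_threshold`,
#'   `strip`, `max_clusters`, `fixed_I`, `seed`.
#' @return The `clonehap_fit`, invisibly.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  if (is.null(out)) stop("config$out_dir is required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    sim <- simulate_tumor(config$simulate)
    write_reference_fasta(sim$reference, file.path(out, "reference.fa"))
    write_truth_vcf(sim$truth, file.path(out, "truth.vcf"))
    write_truth_haplotypes(sim$truth, file.path(out, "truth_haplotypes.tsv"))
    jsonlite::write_json(list(reference_length = sim$config$reference_length,
                              germline_rate = sim$config$germline_rate,
                              somatic_rate = sim$config$somatic_rate,
                              n_subclones = sim$config$n_subclones,
                              proportions = sim$config$proportions,
                              epsilon = sim$config$epsilon,
                              seed = sim$config$seed),
                         file.path(out, "sim_config.json"), auto_unbox = TRUE)
    x <- sim
  } else {
    if (is.null(config$reads) || is.null(config$sites))
      stop("config needs either simulate or reads + sites")
    sites <- load_sites(config$sites)
    aln <- read_alignments(config$reads)
    truth <- NULL
    if (!is.null(config$truth_haplotypes) && all(!is.na(sites$sub))) {
      truth <- list(sites = sites,
                    haplotypes = read_truth_haplotypes(config$truth_haplotypes))
      class(truth) <- "truth_set"
    }
    x <- list(obs = aln, sites = sites, truth = truth)
  }
  fit <- phase_clones(x,
                      epsilon = config$epsilon,
                      cov_threshold = config$cov_threshold %||% 2,
                      strip = config$strip %||% strip_config(),
                      max_clusters = config$max_clusters %||% 6L,
                      fixed_I = config$fixed_I,
                      seed = config$seed %||% 1L)
  write_vpe_tsv(fit$vpes, file.path(out, "vpe.tsv"))
  data.table::fwrite(fit$vaf, file.path(out, "vaf.tsv"), sep = "\t")
  st <- fit$structure
  sites_dt <- if (inherits(x, "clonehap_sim")) x$truth$sites else x$sites
  cl <- merge(st$assignments, sites_dt[, .(site, pos)], by = "site")
  data.table::fwrite(cl[, .(position = pos + 1L, clone)],
                     file.path(out, "clusters.tsv"), sep = "\t")
  jsonlite::write_json(list(I = st$I, means = st$means,
                            proportions = st$proportions),
                       file.path(out, "clonal_structure.json"),
                       auto_unbox = TRUE, digits = NA)
  write_chain_tsv(fit$arranged, file.path(out, "chains.tsv"))
  data.table::fwrite(fit$graph$edges, file.path(out, "graph_edges.tsv"), sep = "\t")
  write_haplotype_tsv(fit$haplotypes, file.path(out, "haplotypes.tsv"))
  write_fragments_bed(fit$haplotypes, file.path(out, "fragments.bed"))
  if (!is.null(fit$metrics)) {
    jsonlite::write_json(unclass(fit$metrics), file.path(out, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(fit)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
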