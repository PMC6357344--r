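#' Estimate the clonal structure from variant allele frequencies
#'
#' Fits a one-dimensional Gaussian mixture to the per-site VAFs and picks
#' the number of components by BIC (unless `fixed_I` is given). Under
#' linear clonal evolution the sites of a sub-clone share a VAF mode at
#' half the cumulative proportion of the clones carrying them, so clusters
#' are relabelled by decreasing mean: clone 0 (founding, plus germline
#' heterozygous sites) has the highest mean. Sites with VAF near 1 are
#' flagged as homozygous-alt: they are uninformative for linkage and are
#' excluded from phasing.
#'
#' @param vaf VAF table from [compute_vaf()] (columns `site`, `vaf`).
#' @param max_clusters Largest number of sub-clones considered.
#' @param fixed_I Force this number of sub-clones instead of BIC selection.
#' @param seed Optional seed (the mixture fit is deterministic, but a seed
#'   keeps the pipeline contract of seeding every stochastic stage).
#' @param hom_threshold VAF above which a site is flagged homozygous.
#' @return A `clonal_structure`: `I`, `assignments` (data.table `site`,
#'   `clone`), `means` (strictly decreasing cluster mean VAFs),
#'   `proportions`, `flagged_hom` (site indices), `dropped` (sites with
#'   undefined VAF).
#' @export
cluster_vafs <- function(vaf, max_clusters = 6L, fixed_I = NULL, seed = NULL,
                         hom_threshold = 0.9) {
  if (!is.null(seed)) set.seed(seed)
  vaf <- data.table::as.data.table(vaf)
  dropped <- vaf[is.na(vaf), site]
  v <- vaf[!is.na(vaf)]
  hom <- v[vaf > hom_threshold, site]
  v <- v[vaf <= hom_threshold]
  if (nrow(v) == 0L) stop("no sites with defined VAF to cluster")
  G <- if (is.null(fixed_I)) seq_len(max_clusters) else as.integer(fixed_I)
  if (nrow(v) < max(G)) stop("fewer sites than requested clusters")
  if (stats::sd(v$vaf) < 1e-12) {
    cl <- rep(1L, nrow(v))
    means <- mean(v$vaf)
  } else {
    fit <- mclust::Mclust(v$vaf, G = G, modelNames = c("V", "E"), verbose = FALSE)
    if (is.null(fit)) stop("mixture fit failed")
    cl <- fit$classification
    means <- as.numeric(fit$parameters$mean)
  }
  ord <- order(means, decreasing = TRUE)
  relabel <- match(seq_along(means), ord)        # old label -> new label
  clone <- relabel[cl] - 1L
  means <- means[ord]
  assignments <- data.table::data.table(site = v$site, clone = clone)
  if (length(hom)) {
    assignments <- rbind(assignments,
                         data.table::data.table(site = hom, clone = 0L))
  }
  data.table::setorder(assignments, site)
  structure(list(I = length(means),
                 assignments = assignments,
                 means = means,
                 proportions = estimate_proportions(means),
                 flagged_hom = hom,
                 dropped = dropped),
            class = "clonal_structure")
}

#' Invert cluster mean VAFs into sub-clone proportions
#'
#' Under linear evolution, the VAF mode of clone i's sites is
#' `mean_i = 1/2 * sum_{k >= i} r_k`, so `r_i = 2 * (mean_i - mean_{i+1})`
#' with `mean_I = 0`. Negative components (sampling noise) are clamped to
#' zero and the vector renormalised.
#'
#' @param means Strictly decreasing cluster mean VAFs.
#' @return Numeric vector of proportions summing to 1.
#' @export
estimate_proportions <- function(means) {
  if (any(diff(means) >= 0)) stop("cluster means must be strictly decreasing")
  if (means[1] > 0.5 + 0.1) warning("largest cluster mean exceeds 0.5 markedly")
  r <- 2 * (means - c(means[-1], 0))
  r <- pmax(r, 0)
  if (sum(r) == 0) stop("degenerate proportions")
  r / sum(r)
}

#' Import a site-to-cluster table produced by an external clustering tool
#'
#' Accepts a TSV (or data.frame) mapping 1-based site positions to cluster
#' ids, e.g. exported from a variational-Bayes VAF clustering. Clusters are
#' relabelled by decreasing mean VAF and proportions re-derived, so
#' external labels need not follow the lineage order.
#'
#' @param x Path to a TSV with columns `pos` (1-based) and `cluster`, or a
#'   data.frame with those columns.
#' @param sites Site table (columns `site`, `pos`).
#' @param vaf VAF table from [compute_vaf()].
#' @return A `clonal_structure`, as from [cluster_vafs()].
#' @export
import_clusters <- function(x, sites, vaf) {
  dt <- if (is.character(x)) data.table::fread(x) else data.table::as.data.table(x)
  if (!all(c("pos", "cluster") %in% names(dt)))
    stop("cluster table needs columns pos, cluster")
  sites <- data.table::as.data.table(sites)
  dt[, pos0 := pos - 1L]
  m <- merge(dt, sites[, .(site, pos0 = pos)], by = "pos0")
  if (nrow(m) == 0L) stop("no positions in the cluster table match the site list")
  if (nrow(m) < nrow(dt))
    warning(nrow(dt) - nrow(m), " clustered position(s) absent from the site list; skipped")
  m <- merge(m, data.table::as.data.table(vaf)[, .(site, vaf)], by = "site")
  cl_means <- m[!is.na(vaf), .(mean_vaf = mean(vaf)), by = cluster]
  data.table::setorder(cl_means, -mean_vaf)
  cl_means[, clone := seq_len(.N) - 1L]
  m <- merge(m, cl_means[, .(cluster, clone)], by = "cluster")
  assignments <- m[, .(site, clone)]
  data.table::setorder(assignments, site)
  means <- cl_means$mean_vaf
  structure(list(I = nrow(cl_means),
                 assignments = assignments,
                 means = means,
                 proportions = if (length(means) > 1L) estimate_proportions(means)
                               else 1,
                 flagged_hom = integer(),
                 dropped = setdiff(sites$site, assignments$site)),
            class = "clonal_structure")
}

#' @export
print.clonal_structure <- function(x, ...) {
  cat(sprintf("Clonal structure: %d sub-clone(s)\n", x$I))
  cat("  mean VAFs:   ", paste(sprintf("%.3f", x$means), collapse = "  "), "\n")
  cat("  proportions: ", paste(sprintf("%.3f", x$proportions), collapse = "  "), "\n")
  cat(sprintf("  %d sites assigned, %d flagged homozygous, %d without VAF\n",
              nrow(x$assignments), length(x$flagged_hom), length(x$dropped)))
  invisible(x)
}
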