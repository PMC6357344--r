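#' Collapse read-pairs to variant-position extracts (VPEs)
#'
#' Each retained read-pair is reduced to the ordered allele states it
#' carries at the given variant sites: A for the reference allele, B for
#' the alternate. Pairs carrying fewer than two variant sites are discarded
#' (a single variant carries no linkage information). Bases matching
#' neither ref nor alt drop that site from the pair; mates disagreeing at a
#' shared site also drop it. Pairs whose extracts are identical (same sites
#' and states) collapse to one VPE with summed multiplicity.
#'
#' @param x A `clonehap_sim`/`sim_reads` object, an observation table with
#'   columns `pair_id`, `site`, `state`, or an alignment table from
#'   [read_alignments()] (needs `sites`).
#' @param sites Site table (required for raw alignments): columns `site`,
#'   `pos`, `ref`, `alt`.
#' @return A data.table of VPEs: `vpe_id`, `start` (smallest site index),
#'   list columns `sites` (strictly increasing 0-based indices) and
#'   `states` ("A"/"B"), `mult`, `n_sites`.
#' @export
extract_vpes <- function(x, sites = NULL) {
  obs <- .as_obs(x, sites)
  if (nrow(obs) == 0L) return(.empty_vpes())
  obs <- obs[state != "N"]
  # resolve duplicate observations of a site within a pair (overlapping or
  # double-counted mates): keep if consistent, drop the site on conflict
  obs <- unique(obs[, .(pair_id, site, state)])
  conflict <- obs[duplicated(obs, by = c("pair_id", "site")),
                  .(pair_id, site)]
  if (nrow(conflict) > 0L) obs <- obs[!conflict, on = c("pair_id", "site")]
  data.table::setorder(obs, pair_id, site)
  # collapse identical extracts: encode (site, state) pairs as integers and
  # compare pairs column-wise in wide layout (fast radix grouping)
  obs[, code := site * 2L + (state == "B")]
  obs[, slot := seq_len(.N), by = pair_id]
  nper <- obs[, .N, by = pair_id]
  keep_pairs <- nper[N >= 2L, pair_id]
  if (length(keep_pairs) == 0L) return(.empty_vpes())
  obs <- obs[pair_id %in% keep_pairs]
  wide <- data.table::dcast(obs, pair_id ~ slot, value.var = "code")
  slot_cols <- setdiff(names(wide), "pair_id")
  vpes <- wide[, .(mult = .N), by = slot_cols]
  codes <- as.matrix(vpes[, ..slot_cols])
  site_lists <- apply(codes, 1L, function(z) as.integer(z[!is.na(z)] %/% 2L),
                      simplify = FALSE)
  state_lists <- apply(codes, 1L, function(z) c("A", "B")[z[!is.na(z)] %% 2L + 1L],
                       simplify = FALSE)
  out <- data.table::data.table(
    start = vapply(site_lists, `[`, integer(1), 1L),
    sites = site_lists,
    states = state_lists,
    mult = vpes$mult,
    n_sites = vapply(site_lists, length, integer(1)))
  data.table::setorder(out, start)
  out[, vpe_id := seq_len(.N)]
  data.table::setcolorder(out, c("vpe_id", "start", "sites", "states", "mult", "n_sites"))
  out[]
}

.empty_vpes <- function() {
  data.table::data.table(vpe_id = integer(), start = integer(),
                         sites = list(), states = list(),
                         mult = integer(), n_sites = integer())
}

# Normalise the accepted inputs to an observation table (pair_id, site, state).
.as_obs <- function(x, sites = NULL) {
  if (inherits(x, "clonehap_sim")) x <- x$reads
  if (inherits(x, "sim_reads")) return(data.table::copy(x$obs))
  x <- data.table::as.data.table(x)
  if (all(c("pair_id", "site", "state") %in% names(x))) return(data.table::copy(x))
  if (all(c("qname", "pos", "seq") %in% names(x))) {
    if (is.null(sites)) stop("sites table required to interpret raw alignments")
    return(.alignments_to_obs(x, sites))
  }
  stop("cannot interpret input as read observations")
}

.alignments_to_obs <- function(aln, sites) {
  sites <- data.table::as.data.table(sites)
  pos <- sites$pos
  rl <- nchar(aln$seq)
  lo <- findInterval(aln$pos - 0.5, pos) + 1L
  hi <- findInterval(aln$pos + rl - 0.5, pos)
  cnt <- pmax(hi - lo + 1L, 0L)
  k <- cnt > 0L
  if (!any(k)) {
    return(data.table::data.table(pair_id = integer(), site = integer(),
                                  state = character()))
  }
  sidx <- sequence(cnt[k], from = lo[k])
  ridx <- rep(which(k), cnt[k])
  off <- pos[sidx] - aln$pos[ridx] + 1L
  base <- substring(aln$seq[ridx], off, off)
  st <- data.table::fifelse(base == sites$ref[sidx], "A",
        data.table::fifelse(base == sites$alt[sidx], "B", "N"))
  data.table::data.table(pair_id = match(aln$qname[ridx], unique(aln$qname)),
                         site = sites$site[sidx], state = st)
}

#' Compute per-site variant allele frequencies from the base library
#'
#' VAF is the number of reads supporting the alternate allele divided by
#' the total read depth at the site, computed on the base library only.
#' Third-allele reads count toward depth but not toward the alternate.
#' Sites with zero depth get `NA` and are excluded downstream.
#'
#' @param x A `clonehap_sim`/`sim_reads` object or an observation table
#'   (columns `pair_id`, `site`, `state`, optionally `lib`).
#' @param sites Site table; VAFs are reported for every site in it.
#' @param base_lib Library index to restrict to (when a `lib` column is
#'   present); `NULL` uses all reads.
#' @return A data.table: `site`, `depth`, `alt`, `vaf`.
#' @export
compute_vaf <- function(x, sites, base_lib = 1L) {
  obs <- .as_obs(x, sites)
  sites <- data.table::as.data.table(sites)
  if (!is.null(base_lib) && "lib" %in% names(obs)) obs <- obs[lib == base_lib]
  cov <- obs[, .(depth = .N, alt = sum(state == "B")), by = site]
  out <- cov[sites[, .(site)], on = "site"]
  out[is.na(depth), `:=`(depth = 0L, alt = 0L)]
  out[, vaf := data.table::fifelse(depth > 0L, alt / depth, NA_real_)]
  data.table::setorder(out, site)
  out[]
}
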