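#' Linearize a spanning forest into last-clone haplotype fragments
#'
#' Each tree with at least two sites becomes one fragment: its sites sorted
#' by reference position, with their tree phases forming one haplotype of
#' the last sub-clone over the fragment; the companion haplotype is the
#' sitewise complement (every placed site is heterozygous in the last
#' clone). Singleton trees carry no linkage and are not reported as
#' fragments.
#'
#' @param forest A `spanning_forest`.
#' @param sites Site table (columns `site`, `pos`).
#' @return A data.table of placed sites: `site`, `pos`, `fragment`, `state`
#'   (tracked haplotype of the last clone, "A"/"B").
#' @export
linearize_tree <- function(forest, sites) {
  asg <- data.table::copy(forest$assignment)
  sites <- data.table::as.data.table(sites)
  sz <- asg[, .N, by = tree]
  keep <- sz[N >= 2L, tree]
  asg <- asg[tree %in% keep]
  if (nrow(asg) == 0L) {
    return(data.table::data.table(site = integer(), pos = integer(),
                                  fragment = integer(), state = character()))
  }
  out <- merge(asg[, .(site = vertex, tree, state = phase)],
               sites[, .(site, pos)], by = "site")
  data.table::setorder(out, pos)
  out[, fragment := match(tree, unique(tree))]
  out[, tree := NULL]
  data.table::setcolorder(out, c("site", "pos", "fragment", "state"))
  out[]
}

#' Derive all clonal haplotypes from the last clone's haplotype
#'
#' Under linear evolution the father chain of clone i is obtained from
#' clone i+1 by reverting the mutations younger than i:
#' `h[2i, j] = A` if `h[2(i+1), j] = A`; `B` if `h[2(i+1), j] = B` and
#' `sub(j) <= i`; `A` otherwise. The companion chain is the father's
#' complement where `sub(j) <= i` (the site is heterozygous in clone i) and
#' A where `sub(j) > i` (the mutation has not arisen yet). The output
#' always satisfies the inheritance invariant.
#'
#' @param placed Data.table of placed sites with `site`, `state` (tracked
#'   haplotype of the last clone) and clone label `sub`; sites with an
#'   unknown label are excluded (with a message).
#' @param I Number of sub-clones.
#' @return A list: `matrix` (2I rows over A/B; rows `2i+1`, `2i+2` are the
#'   father and companion chains of clone i), `sites` (column site
#'   indices).
#' @export
derive_ancestors <- function(placed, I) {
  placed <- data.table::as.data.table(placed)
  drop <- is.na(placed$sub)
  if (any(drop)) {
    message(sum(drop), " placed site(s) lack a clone label; excluded")
    placed <- placed[!drop]
  }
  n <- nrow(placed)
  m <- matrix("A", nrow = 2L * I, ncol = n)
  if (n > 0L) {
    last_b <- placed$state == "B"
    for (i in (I - 1L):0L) {
      father_b <- if (i == I - 1L) last_b else m[2L * (i + 1L) + 1L, ] == "B"
      fb <- father_b & placed$sub <= i
      m[2L * i + 1L, ] <- ifelse(fb, "B", "A")
      het <- placed$sub <= i
      m[2L * i + 2L, ] <- ifelse(het, ifelse(fb, "A", "B"), "A")
    }
  }
  list(matrix = m, sites = placed$site)
}

#' Assemble the reconstructed haplotype set from an extended forest
#'
#' @param forest A `spanning_forest` (typically the extended tree).
#' @param structure A `clonal_structure` providing clone labels.
#' @param sites Site table.
#' @return A `haplotype_set`: `placed` (site, pos, fragment, state, sub),
#'   `matrix` (2I x placed sites), `fragments` (fragment spans), `I`.
#' @export
build_haplotypes <- function(forest, structure, sites) {
  placed <- linearize_tree(forest, sites)
  asg <- structure$assignments
  placed[, sub := asg$clone[match(site, asg$site)]]
  anc <- derive_ancestors(placed, structure$I)
  frags <- placed[, .(start = min(pos), end = max(pos), n_sites = .N),
                  by = fragment]
  frags[, span := end - start + 1L]
  structure(list(placed = placed, matrix = anc$matrix,
                 matrix_sites = anc$sites, fragments = frags,
                 I = structure$I),
            class = "haplotype_set")
}

#' Score a reconstruction against the simulated truth
#'
#' Recognition rate: fraction of all true variant sites placed into some
#' fragment. Accuracy rate: fraction of placed sites whose full clonal
#' assignment (clone label and haplotype side) matches the truth, after
#' choosing per fragment the global haplotype flip that maximises matches
#' (absolute phase is unobservable). Longest length: largest fragment span
#' in reference bp. Fragment count: number of multi-site fragments.
#'
#' @param recon A `haplotype_set` from [build_haplotypes()].
#' @param truth A `truth_set` from [plant_mutations()].
#' @return A `clonehap_metrics` list: `recognition_rate`, `accuracy_rate`,
#'   `longest_length`, `fragment_count`, plus supporting counts.
#' @export
score <- function(recon, truth) {
  ts <- truth$sites
  placed <- recon$placed
  if (nrow(placed) > 0L && !all(placed$pos %in% ts$pos))
    stop("reconstruction contains positions absent from the truth")
  n_total <- nrow(ts)
  n_placed <- nrow(placed)
  if (n_placed == 0L) {
    return(structure(list(recognition_rate = 0, accuracy_rate = NA_real_,
                          longest_length = 0L, fragment_count = 0L,
                          n_placed = 0L, n_total = n_total, n_matched = 0L),
                     class = "clonehap_metrics"))
  }
  tt <- ts[match(placed$pos, ts$pos)]
  cl_ok <- !is.na(placed$sub) & placed$sub == tt$sub
  is_b <- placed$state == "B"
  # flip = 0: tracked haplotype is truth side 1; flip = 1: side 0
  m0 <- cl_ok & (is_b == (tt$side == 1L))
  m1 <- cl_ok & (is_b == (tt$side == 0L))
  per_frag <- data.table::data.table(fragment = placed$fragment, m0 = m0, m1 = m1)
  agg <- per_frag[, .(matched = max(sum(m0), sum(m1))), by = fragment]
  n_matched <- sum(agg$matched)
  structure(list(recognition_rate = n_placed / n_total,
                 accuracy_rate = n_matched / n_placed,
                 longest_length = if (nrow(recon$fragments)) max(recon$fragments$span) else 0L,
                 fragment_count = nrow(recon$fragments),
                 n_placed = n_placed, n_total = n_total,
                 n_matched = n_matched),
            class = "clonehap_metrics")
}

#' @export
print.clonehap_metrics <- function(x, ...) {
  cat("Reconstruction metrics\n")
  cat(sprintf("  recognition rate: %.2f%% (%d / %d sites placed)\n",
              100 * x$recognition_rate, x$n_placed, x$n_total))
  cat(sprintf("  accuracy rate:    %.2f%% (%d / %d placed sites matched)\n",
              100 * x$accuracy_rate, x$n_matched, x$n_placed))
  cat(sprintf("  longest fragment: %d bp\n", x$longest_length))
  cat(sprintf("  fragments:        %d\n", x$fragment_count))
  invisible(x)
}

#' Write the reconstructed haplotype matrix as TSV
#' @param recon A `haplotype_set`.
#' @param path Output path.
#' @export
write_haplotype_tsv <- function(recon, path) {
  m <- recon$matrix
  dt <- data.table::as.data.table(m)
  data.table::setnames(dt, as.character(recon$matrix_sites))
  out <- cbind(data.table::data.table(haplotype = seq_len(nrow(m)) - 1L), dt)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Write fragment spans as BED (0-based half-open)
#' @param recon A `haplotype_set`.
#' @param path Output path.
#' @param contig Contig name.
#' @export
write_fragments_bed <- function(recon, path, contig = "chrS") {
  f <- recon$fragments
  writeLines(sprintf("%s\t%d\t%d\tfragment%d\t%d", contig, f$start,
                     f$end + 1L, f$fragment, f$n_sites), path)
  invisible(path)
}
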