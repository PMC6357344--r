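#' Specification of one sequencing library
#'
#' A library is defined by its insert-size distribution, read length and
#' target fold-coverage. Paired-end inserts are drawn from a normal
#' distribution truncated below at twice the read length, so mates never
#' overlap.
#'
#' @param insert_size_mean Mean outer insert size in bp.
#' @param insert_size_sd Insert-size standard deviation in bp; defaults to 5%
#'   of the mean.
#' @param read_length Length of each mate in bp.
#' @param coverage Target fold-coverage contributed by this library.
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(insert_size_mean, insert_size_sd = 0.05 * insert_size_mean,
                         read_length, coverage) {
  if (read_length < 1L) stop("read_length must be >= 1")
  if (2 * read_length > insert_size_mean)
    stop("insert_size_mean must be at least twice the read length")
  if (coverage <= 0) stop("coverage must be positive")
  structure(list(insert_size_mean = insert_size_mean,
                 insert_size_sd = insert_size_sd,
                 read_length = as.integer(read_length),
                 coverage = coverage),
            class = "library_spec")
}

#' Simulation configuration for a mixed tumor sample
#'
#' Describes a tumor sample as a mixture of `n_subclones` linearly evolving
#' sub-clones. Germline heterozygous variants are carried by every clone;
#' somatic variants arise in one clone and are inherited by all of its
#' descendants (linear evolution: clone 0 -> 1 -> ... -> I-1, no reversion,
#' each locus mutating at most once).
#'
#' @param reference_length Reference length in bases.
#' @param germline_rate Germline heterozygous mutation rate per base.
#' @param somatic_rate Somatic mutation rate per base.
#' @param n_subclones Number of sub-clones I.
#' @param proportions Mixture fractions of the sub-clones (summing to 1),
#'   ordered from the founding clone outward.
#' @param libraries List of [library_spec()] objects; the first is the base
#'   library used for variant-allele-frequency estimation.
#' @param epsilon Per-base sequencing error probability; an erroneous base is
#'   replaced by one of the three other bases uniformly.
#' @param seed Integer seed making the whole simulation reproducible.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(reference_length,
                       germline_rate = 0.001,
                       somatic_rate = 0.01,
                       n_subclones = 3L,
                       proportions = c(0.3, 0.5, 0.2),
                       libraries = list(library_spec(1000, read_length = 250, coverage = 100),
                                        library_spec(1500, read_length = 250, coverage = 50),
                                        library_spec(2000, read_length = 250, coverage = 50)),
                       epsilon = 0.01,
                       seed = 1L) {
  if (reference_length < 1) stop("reference_length must be >= 1")
  if (germline_rate < 0 || germline_rate >= 1) stop("germline_rate must be in [0, 1)")
  if (somatic_rate < 0 || somatic_rate >= 1) stop("somatic_rate must be in [0, 1)")
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  if (length(proportions) != n_subclones)
    stop("proportions must have one entry per sub-clone")
  if (any(proportions <= 0)) stop("all proportions must be positive")
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  if (!all(vapply(libraries, inherits, logical(1), "library_spec")))
    stop("libraries must be a list of library_spec objects")
  structure(list(reference_length = as.integer(reference_length),
                 germline_rate = germline_rate,
                 somatic_rate = somatic_rate,
                 n_subclones = as.integer(n_subclones),
                 proportions = proportions,
                 libraries = libraries,
                 epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

#' Generate a uniform-random reference sequence
#'
#' @param length Sequence length in bases.
#' @param seed Optional integer seed; when `NULL` the current RNG state is
#'   used (the caller is assumed to have seeded it).
#' @return A character vector of single bases over A/C/G/T.
#' @export
generate_reference <- function(length, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sample(BASES, length, replace = TRUE)
}

#' Plant germline and somatic mutations on a reference
#'
#' Germline heterozygous sites are assigned to clone label 0 on one random
#' haplotype side and inherited by every clone. Somatic sites are assigned
#' uniformly to clones `0..I-1` and one haplotype side, and propagate to all
#' descendant clones. The resulting truth matrix satisfies the inheritance
#' principle (a mutation never reverts) and the one-hit constraint (each
#' position mutates once; collisions are redrawn by sampling positions
#' without replacement).
#'
#' @param reference Character vector of single bases (from
#'   [generate_reference()]).
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A `truth_set`: `sites` (data.table with 0-based `site` index,
#'   0-based `pos`, `ref`, `alt`, clone label `sub`, haplotype `side`),
#'   `haplotypes` (2I x N character matrix over A/B; rows `2i+1`, `2i+2` are
#'   the two haplotypes of clone i), and `I`.
#' @export
plant_mutations <- function(reference, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(reference)
  I <- config$n_subclones
  n_germ <- stats::rbinom(1L, L, config$germline_rate)
  n_som <- stats::rbinom(1L, L, config$somatic_rate)
  n <- n_germ + n_som
  if (n > L) stop("more mutations than bases; lower the rates")
  pos0 <- sort(sample.int(L, n) - 1L)
  germ <- rep(FALSE, n)
  if (n > 0L) germ[sample.int(n, n_germ)] <- TRUE
  sub <- integer(n)
  if (any(!germ)) sub[!germ] <- sample.int(I, sum(!germ), replace = TRUE) - 1L
  side <- sample(0:1, n, replace = TRUE)
  ref <- reference[pos0 + 1L]
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1),
                USE.NAMES = FALSE)
  sites <- data.table::data.table(site = seq_len(n) - 1L, pos = pos0,
                                  ref = ref, alt = alt, sub = sub,
                                  side = side, germline = germ)
  hap <- matrix("A", nrow = 2L * I, ncol = n)
  if (n > 0L) {
    for (i in seq_len(I) - 1L) {
      carrier <- sites$sub <= i
      rows <- 2L * i + 1L + sites$side
      idx <- cbind(rows[carrier], which(carrier))
      hap[idx] <- "B"
    }
  }
  structure(list(sites = sites, haplotypes = hap, I = I), class = "truth_set")
}

#' Simulate aligned paired-end reads from a clonal mixture
#'
#' Read-pairs are drawn per library until the target fold-coverage is
#' reached (`pairs = length * coverage / (2 * read_length)`). Each pair
#' originates from clone i with probability `r_i` and from one of its two
#' haplotypes uniformly; the insert length is normal, truncated below at
#' twice the read length; every sequenced base is flipped to a uniformly
#' chosen different base with probability `epsilon`. Reads carry their true
#' mapping coordinates. Only the bases observed at variant sites are
#' materialised here (they determine every downstream statistic); full
#' sequences are reconstructed on demand by [write_sam()].
#'
#' @param reference Character vector of single bases.
#' @param truth A `truth_set` from [plant_mutations()].
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A `sim_reads` object: `pairs` (one row per read-pair: `pair_id`,
#'   `lib`, `clone`, `side`, 0-based mate starts `start1`/`start2`,
#'   `read_length`), `obs` (one row per read x covered variant site:
#'   `pair_id`, `lib`, `mate`, 0-based `site`, observed `base`, and `state`
#'   coded A = reference allele, B = alternate allele, N = third allele),
#'   and `base_lib = 1L`.
#' @export
simulate_reads <- function(reference, truth, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- length(reference)
  sites <- truth$sites
  max_insert <- max(vapply(config$libraries, function(l) l$insert_size_mean, numeric(1)))
  if (L < max_insert) stop("reference shorter than the largest mean insert size")
  pair_list <- vector("list", length(config$libraries))
  obs_list <- vector("list", length(config$libraries))
  next_id <- 0L
  for (li in seq_along(config$libraries)) {
    lib <- config$libraries[[li]]
    rl <- lib$read_length
    n_pairs <- as.integer(round(L * lib$coverage / (2 * rl)))
    if (n_pairs < 1L) next
    clone <- sample.int(config$n_subclones, n_pairs, replace = TRUE,
                        prob = config$proportions) - 1L
    side <- sample(0:1, n_pairs, replace = TRUE)
    ins <- as.integer(round(stats::rnorm(n_pairs, lib$insert_size_mean, lib$insert_size_sd)))
    ins <- pmax(ins, 2L * rl)
    ins <- pmin(ins, L)
    start1 <- as.integer(floor(stats::runif(n_pairs) * (L - ins + 1L)))
    start2 <- start1 + ins - rl
    ids <- next_id + seq_len(n_pairs)
    next_id <- next_id + n_pairs
    pair_list[[li]] <- data.table::data.table(
      pair_id = ids, lib = li, clone = clone, side = side,
      start1 = start1, start2 = start2, read_length = rl, insert = ins)
    if (nrow(sites) > 0L) {
      ob1 <- .sites_in_windows(ids, start1, rl, sites$pos, clone, side, truth, config$epsilon, 1L)
      ob2 <- .sites_in_windows(ids, start2, rl, sites$pos, clone, side, truth, config$epsilon, 2L)
      ob <- data.table::rbindlist(list(ob1, ob2))
      if (nrow(ob) > 0L) ob[, lib := li]
      obs_list[[li]] <- ob
    }
  }
  pairs <- data.table::rbindlist(pair_list)
  obs <- data.table::rbindlist(obs_list)
  if (nrow(obs) > 0L) {
    st <- sites[obs$site + 1L]
    obs[, base := data.table::fifelse(truth_state == "A", st$ref, st$alt)]
    err <- stats::runif(nrow(obs)) < config$epsilon
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      cur <- match(obs$base[err], BASES)
      obs$base[err] <- BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    obs[, state := data.table::fifelse(base == st$ref, "A",
                   data.table::fifelse(base == st$alt, "B", "N"))]
    obs[, truth_state := NULL]
    data.table::setorder(obs, pair_id, site)
  } else {
    obs <- data.table::data.table(pair_id = integer(), mate = integer(),
                                  site = integer(), lib = integer(),
                                  base = character(), state = character())
  }
  structure(list(pairs = pairs, obs = obs, base_lib = 1L),
            class = "sim_reads")
}

# Observations of variant sites falling inside read windows [w, w+rl).
.sites_in_windows <- function(ids, starts, rl, pos, clone, side, truth, epsilon, mate) {
  lo <- findInterval(starts - 0.5, pos) + 1L
  hi <- findInterval(starts + rl - 0.5, pos)
  cnt <- pmax(hi - lo + 1L, 0L)
  keep <- cnt > 0L
  if (!any(keep)) {
    return(data.table::data.table(pair_id = integer(), mate = integer(),
                                  site = integer(), truth_state = character()))
  }
  site_idx <- sequence(cnt[keep], from = lo[keep])           # 1-based site rank
  pid <- rep(ids[keep], cnt[keep])
  row <- rep(2L * clone[keep] + 1L + side[keep], cnt[keep])
  data.table::data.table(pair_id = pid, mate = mate, site = site_idx - 1L,
                         truth_state = truth$haplotypes[cbind(row, site_idx)])
}

#' Simulate a complete mixed tumor sample
#'
#' Convenience wrapper seeding the RNG once and running
#' [generate_reference()], [plant_mutations()] and [simulate_reads()].
#'
#' @param config A [sim_config()].
#' @return A `clonehap_sim` object with elements `reference`, `truth`,
#'   `reads` and `config`.
#' @export
simulate_tumor <- function(config) {
  set.seed(config$seed)
  reference <- generate_reference(config$reference_length)
  truth <- plant_mutations(reference, config)
  reads <- simulate_reads(reference, truth, config)
  structure(list(reference = reference, truth = truth, reads = reads,
                 config = config),
            class = "clonehap_sim")
}

#' @export
print.clonehap_sim <- function(x, ...) {
  cat("Simulated tumor sample\n")
  cat(sprintf("  reference: %d bp, %d variant sites (%d germline, %d somatic)\n",
              length(x$reference), nrow(x$truth$sites),
              sum(x$truth$sites$germline), sum(!x$truth$sites$germline)))
  cat(sprintf("  sub-clones: %d at proportions %s\n", x$config$n_subclones,
              paste(x$config$proportions, collapse = ":")))
  cat(sprintf("  read-pairs: %d across %d libraries, epsilon = %g\n",
              nrow(x$reads$pairs), length(x$config$libraries), x$config$epsilon))
  invisible(x)
}
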