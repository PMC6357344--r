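#' Partition VPEs into start-position groups
#'
#' @param vpes VPE table from [extract_vpes()].
#' @return A list of VPE tables, one per distinct start index, ordered by
#'   start.
#' @export
group_by_start <- function(vpes) {
  if (nrow(vpes) == 0L) return(list())
  starts <- sort(unique(vpes$start))
  lapply(starts, function(s) vpes[start == s])
}

# Internal chain representation: list(sites = increasing integer vector,
# states = logical (TRUE = B), supp = per-site supporting multiplicity,
# support = total supporting VPE multiplicity).
.new_chain <- function(sites, states, mult) {
  list(sites = sites, states = states,
       supp = rep(as.numeric(mult), length(sites)),
       support = as.numeric(mult))
}

# Is VPE (s, b) consistent with chain ch (equal states on all shared sites)?
# Returns the match index vector, or NULL on conflict.
.chain_match <- function(ch, s, b) {
  m <- match(s, ch$sites)
  shared <- !is.na(m)
  if (any(shared) && any(ch$states[m[shared]] != b[shared])) return(NULL)
  m
}

# Fold a VPE into a chain: extend with unseen sites, add support.
.chain_add <- function(ch, s, b, mult, m) {
  new <- is.na(m)
  if (any(new)) {
    sites <- c(ch$sites, s[new])
    states <- c(ch$states, b[new])
    supp <- c(ch$supp, rep(0, sum(new)))
    ord <- order(sites)
    ch$sites <- sites[ord]; ch$states <- states[ord]; ch$supp <- supp[ord]
  }
  at <- match(s, ch$sites)
  ch$supp[at] <- ch$supp[at] + mult
  ch$support <- ch$support + mult
  ch
}

#' Greedily build a minimal set of short chains supporting a VPE group
#'
#' All VPEs in a group share the same start index, so any two of them
#' overlap. VPEs are processed longest-first (ties: higher multiplicity,
#' then lexicographic states): a VPE contained in an existing chain only
#' adds support; a VPE consistent with an existing chain extends it (union
#' of states); otherwise it opens a new chain. Every VPE of the group is
#' supported by exactly one output chain.
#'
#' @param group A VPE table whose rows share one start index.
#' @return List of chains (each `list(sites, states, supp, support)`).
#' @export
build_short_chains <- function(group) {
  n <- nrow(group)
  if (n == 0L) return(list())
  if (length(unique(group$start)) != 1L)
    stop("build_short_chains expects VPEs sharing one start index")
  skeys <- vapply(group$states, paste, character(1), collapse = "")
  ord <- order(-group$n_sites, -group$mult, skeys)
  chains <- list()
  for (t in ord) {
    s <- group$sites[[t]]
    b <- group$states[[t]] == "B"
    mult <- group$mult[t]
    placed <- FALSE
    for (ci in seq_along(chains)) {
      m <- .chain_match(chains[[ci]], s, b)
      if (!is.null(m)) {
        chains[[ci]] <- .chain_add(chains[[ci]], s, b, mult, m)
        placed <- TRUE
        break
      }
    }
    if (!placed) chains[[length(chains) + 1L]] <- .chain_add(.new_chain(s[0], b[0], 0), s, b, mult, match(s, integer()))
  }
  chains
}

#' Arrange short-chain groups into chains spanning groups
#'
#' Groups are visited in start order. A chain from the current group is
#' merged into an earlier chain when they share at least one site and agree
#' at every shared site (the inheritance principle makes consistent local
#' patterns continuations of the same haplotype); conflicting overlaps keep
#' chains separate. At each group start the number of distinct chain
#' patterns covering that site is capped at 2I (the number of haplotypes);
#' chains beyond the cap with the lowest support are pruned.
#'
#' @param groups List of chain lists from [build_short_chains()], ordered
#'   by group start.
#' @param I Number of sub-clones (cap is 2I patterns per site).
#' @return A single list of chains.
#' @export
arrange_groups <- function(groups, I) {
  cap <- 2L * as.integer(I)
  active <- list()
  done <- list()
  for (g in groups) {
    if (length(g) == 0L) next
    gstart <- g[[1]]$sites[1]
    # retire chains that can no longer overlap any later group
    if (length(active)) {
      ends <- vapply(active, function(c) c$sites[length(c$sites)], integer(1))
      retire <- ends < gstart
      done <- c(done, active[retire])
      active <- active[!retire]
    }
    for (ch in g) {
      merged <- FALSE
      if (length(active)) {
        best <- 0L; best_shared <- 0L; best_supp <- -1
        for (ai in seq_along(active)) {
          m <- match(ch$sites, active[[ai]]$sites)
          shared <- sum(!is.na(m))
          if (shared == 0L) next
          if (any(active[[ai]]$states[m[!is.na(m)]] != ch$states[!is.na(m)])) next
          if (shared > best_shared ||
              (shared == best_shared && active[[ai]]$support > best_supp)) {
            best <- ai; best_shared <- shared; best_supp <- active[[ai]]$support
          }
        }
        if (best > 0L) {
          active[[best]] <- .merge_chains(active[[best]], ch)
          merged <- TRUE
        }
      }
      if (!merged) active[[length(active) + 1L]] <- ch
    }
    # cap the number of distinct patterns covering the group-start site
    covering <- which(vapply(active, function(c) gstart %in% c$sites, logical(1)))
    if (length(covering) > cap) {
      supp <- vapply(active[covering], function(c) c$support, numeric(1))
      drop <- covering[order(supp, decreasing = TRUE)][-seq_len(cap)]
      active <- active[-drop]
    }
  }
  c(done, active)
}

.merge_chains <- function(a, b) {
  m <- match(b$sites, a$sites)
  new <- is.na(m)
  sites <- c(a$sites, b$sites[new])
  states <- c(a$states, b$states[new])
  supp <- c(a$supp, rep(0, sum(new)))
  ord <- order(sites)
  out <- list(sites = sites[ord], states = states[ord], supp = supp[ord],
              support = a$support + b$support)
  at <- match(b$sites, out$sites)
  out$supp[at] <- out$supp[at] + b$supp
  out
}

#' Exhaustive minimal short-chain cover (test oracle)
#'
#' Finds the smallest number of pairwise-consistent chains that support a
#' set of VPEs by enumerating assignments; only usable for a handful of
#' VPEs.
#'
#' @param group A VPE table whose rows share one start index.
#' @param max_k Largest cover size tried.
#' @return The minimal number of chains.
#' @export
minimal_chain_cover <- function(group, max_k = nrow(group)) {
  n <- nrow(group)
  if (n == 0L) return(0L)
  if (n > 8L) stop("oracle limited to 8 VPEs")
  compat <- function(members) {
    st <- new.env()
    for (t in members) {
      s <- group$sites[[t]]; b <- group$states[[t]]
      for (u in seq_along(s)) {
        key <- as.character(s[u])
        prev <- st[[key]]
        if (!is.null(prev) && prev != b[u]) return(FALSE)
        st[[key]] <- b[u]
      }
    }
    TRUE
  }
  for (k in seq_len(max_k)) {
    grids <- expand.grid(rep(list(seq_len(k)), n))
    for (gi in seq_len(nrow(grids))) {
      asg <- as.integer(grids[gi, ])
      ok <- TRUE
      for (cl in seq_len(k)) {
        members <- which(asg == cl)
        if (length(members) && !compat(members)) { ok <- FALSE; break }
      }
      if (ok) return(k)
    }
  }
  max_k
}
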