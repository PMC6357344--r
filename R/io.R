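#' Load variant sites from a VCF or TSV file
#'
#' Only biallelic SNVs are kept; other records (indels, multi-allelic sites)
#' are skipped with a message. Sites are returned position-sorted and
#' indexed 0-based. A TSV must carry columns `pos` (1-based, like VCF),
#' `ref` and `alt`.
#'
#' @param path Path to a `.vcf` file or a tab-separated table.
#' @return A data.table with columns `site` (0-based rank), `pos` (0-based
#'   coordinate), `ref`, `alt`, and any clone annotation found (`sub`).
#' @export
load_sites <- function(path) {
  if (!file.exists(path)) stop("sites file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    if (nrow(fix) == 0L) stop("no records in ", path)
    dt <- data.table::data.table(pos1 = as.integer(fix$POS), ref = fix$REF,
                                 alt = fix$ALT)
    info <- fix$INFO
    sub <- suppressWarnings(as.integer(sub(".*SUB=([0-9]+).*", "\\1", info)))
    sub[!grepl("SUB=", info)] <- NA_integer_
    dt[, sub := sub]
    side <- suppressWarnings(as.integer(sub(".*SIDE=([0-9]+).*", "\\1", info)))
    side[!grepl("SIDE=", info)] <- NA_integer_
    dt[, side := side]
  } else {
    dt <- data.table::fread(path)
    if (!all(c("pos", "ref", "alt") %in% names(dt)))
      stop("TSV sites file needs columns pos, ref, alt")
    data.table::setnames(dt, "pos", "pos1")
    if (!"sub" %in% names(dt)) dt[, sub := NA_integer_]
    if (!"side" %in% names(dt)) dt[, side := NA_integer_]
  }
  if (nrow(dt) == 0L) stop("no records in ", path)
  snv <- nchar(dt$ref) == 1L & nchar(dt$alt) == 1L &
    dt$ref %in% BASES & dt$alt %in% BASES
  if (any(!snv)) message(sum(!snv), " non-SNV record(s) skipped")
  dt <- dt[snv]
  if (nrow(dt) == 0L) stop("no biallelic SNVs in ", path)
  if (anyDuplicated(dt$pos1)) stop("duplicate positions in ", path)
  data.table::setorder(dt, pos1)
  out <- data.table::data.table(site = seq_len(nrow(dt)) - 1L,
                                pos = dt$pos1 - 1L,
                                ref = dt$ref, alt = dt$alt,
                                sub = dt$sub, side = dt$side)
  out[]
}

#' Write the reference as FASTA
#'
#' @param reference Character vector of single bases.
#' @param path Output path.
#' @param name Sequence name.
#' @export
write_reference_fasta <- function(reference, path, name = "chrS") {
  seq <- Biostrings::DNAStringSet(paste(reference, collapse = ""))
  names(seq) <- name
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

#' Write simulated truth sites as a VCF
#'
#' Positions are written 1-based; the clone label and haplotype side go into
#' the INFO field as `SUB=` and `SIDE=`.
#'
#' @param truth A `truth_set`.
#' @param path Output path.
#' @param contig Contig name.
#' @export
write_truth_vcf <- function(truth, path, contig = "chrS") {
  s <- truth$sites
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", contig),
           "##INFO=<ID=SUB,Number=1,Type=Integer,Description=\"Originating sub-clone label\">",
           "##INFO=<ID=SIDE,Number=1,Type=Integer,Description=\"Haplotype side carrying the mutation\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSUB=%d;SIDE=%d",
                  contig, s$pos + 1L, s$ref, s$alt, s$sub, s$side)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write the truth haplotype matrix as TSV
#'
#' Rows are the 2I haplotypes (clone-major: rows 2i+1 and 2i+2 belong to
#' clone i), columns the variant sites; cells are A/B.
#'
#' @param truth A `truth_set`.
#' @param path Output path.
#' @export
write_truth_haplotypes <- function(truth, path) {
  m <- truth$haplotypes
  dt <- data.table::data.table(haplotype = seq_len(nrow(m)) - 1L)
  cols <- data.table::as.data.table(m)
  data.table::setnames(cols, as.character(truth$sites$pos))
  data.table::fwrite(cbind(dt, cols), path, sep = "\t")
  invisible(path)
}

#' Read the truth haplotype matrix written by [write_truth_haplotypes()]
#' @param path Input path.
#' @return A character matrix with one row per haplotype.
#' @export
read_truth_haplotypes <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses = "character")
  m <- as.matrix(dt[, -1])
  dimnames(m) <- list(NULL, colnames(m))
  m
}

#' Write simulated reads as SAM (optionally BAM)
#'
#' Sequences are rebuilt from the generating haplotype: bases at variant
#' sites reproduce exactly the observations used by the pipeline (including
#' their sequencing errors); background positions are drawn fresh at rate
#' epsilon. Reads are emitted at their true coordinates with CIGAR
#' `<read_length>M`.
#'
#' @param sim A `clonehap_sim`.
#' @param path Output `.sam` path.
#' @param bam Also convert to coordinate-sorted BAM via Rsamtools.
#' @param contig Contig name.
#' @return Path of the file written (BAM path when `bam = TRUE`).
#' @export
write_sam <- function(sim, path, bam = FALSE, contig = "chrS") {
  pr <- sim$reads$pairs
  obs <- sim$reads$obs
  ref <- sim$reference
  truth <- sim$truth
  eps <- sim$config$epsilon
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", contig, length(ref)))
  mk_seq <- function(starts, rl, rows, pids, which_mate) {
    n <- length(starts)
    offs <- sequence(rep(rl, n), from = starts + 1L)
    base <- ref[offs]
    sp <- truth$sites$pos
    lo <- findInterval(starts - 0.5, sp) + 1L
    hi <- findInterval(starts + rl - 0.5, sp)
    cnt <- pmax(hi - lo + 1L, 0L)
    err <- stats::runif(length(base)) < eps
    if (any(cnt > 0L)) {
      k <- cnt > 0L
      sidx <- sequence(cnt[k], from = lo[k])
      at <- rep((seq_len(n) - 1L)[k] * rl, cnt[k]) + (sp[sidx] - rep(starts[k], cnt[k])) + 1L
      ob <- obs[mate == which_mate][data.table::data.table(pair_id = rep(pids[k], cnt[k]),
                                                           site = sidx - 1L),
                                    on = c("pair_id", "site")]
      planted <- !is.na(ob$base)
      base[at[planted]] <- ob$base[planted]
      err[at[planted]] <- FALSE
    }
    if (any(err)) {
      shift <- sample.int(3L, sum(err), replace = TRUE)
      base[err] <- BASES[((match(base[err], BASES) - 1L + shift) %% 4L) + 1L]
    }
    apply(matrix(base, nrow = rl), 2L, paste, collapse = "")
  }
  rows <- 2L * pr$clone + 1L + pr$side
  rl <- pr$read_length[1]
  seq1 <- mk_seq(pr$start1, rl, rows, pr$pair_id, 1L)
  seq2 <- mk_seq(pr$start2, rl, rows, pr$pair_id, 2L)
  qual <- strrep("I", rl)
  qn <- sprintf("pair%08d", pr$pair_id)
  rec1 <- sprintf("%s\t99\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
                  qn, contig, pr$start1 + 1L, rl, pr$start2 + 1L, pr$insert, seq1, qual)
  rec2 <- sprintf("%s\t147\t%s\t%d\t60\t%dM\t=\t%d\t%d\t%s\t%s",
                  qn, contig, pr$start2 + 1L, rl, pr$start1 + 1L, -pr$insert, seq2, qual)
  writeLines(c(hdr, rec1, rec2), path)
  if (bam) {
    out <- Rsamtools::asBam(path, sub("\\.sam$", "", path), overwrite = TRUE)
    return(invisible(out))
  }
  invisible(path)
}

#' Read paired-end alignments from SAM or BAM
#'
#' BAM files are read with Rsamtools; SAM text is first converted with
#' `Rsamtools::asBam`. Unmapped, secondary and supplementary records are
#' dropped.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data.table with columns `qname`, `mate` (1/2, 0 when unpaired),
#'   `pos` (0-based leftmost coordinate) and `seq`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  mate <- data.table::fifelse(bitwAnd(flag, 64L) > 0L, 1L,
          data.table::fifelse(bitwAnd(flag, 128L) > 0L, 2L, 0L))
  data.table::data.table(qname = b$qname, mate = mate, pos = b$pos - 1L,
                         seq = as.character(b$seq))
}

#' Write VPEs as TSV
#' @param vpes VPE table from [extract_vpes()].
#' @param path Output path.
#' @export
write_vpe_tsv <- function(vpes, path) {
  dt <- data.table::data.table(
    start_index = vpes$start,
    site_indices = vapply(vpes$sites, paste, character(1), collapse = ","),
    states = vapply(vpes$states, paste, character(1), collapse = ","),
    multiplicity = vpes$mult)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read VPEs written by [write_vpe_tsv()]
#' @param path Input path.
#' @return A VPE table as produced by [extract_vpes()].
#' @export
read_vpe_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  out <- data.table::data.table(
    start = dt$start_index,
    sites = lapply(strsplit(dt$site_indices, ","), as.integer),
    states = strsplit(dt$states, ","),
    mult = dt$multiplicity)
  out[, n_sites := lengths(sites)]
  data.table::setorder(out, start)
  out[, vpe_id := seq_len(.N)]
  out[]
}

#' Write short chains as TSV
#' @param chains Chain list from [arrange_groups()] or [build_short_chains()].
#' @param path Output path.
#' @export
write_chain_tsv <- function(chains, path) {
  dt <- data.table::data.table(
    group_start = vapply(chains, function(c) c$sites[1], integer(1)),
    site_indices = vapply(chains, function(c) paste(c$sites, collapse = ","), character(1)),
    states = vapply(chains, function(c) paste(ifelse(c$states, "B", "A"), collapse = ","), character(1)),
    support = vapply(chains, function(c) c$support, numeric(1)))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
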