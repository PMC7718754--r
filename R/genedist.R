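# TE-upstream-of-gene proximity.  Reference mode does strand-aware
# interval arithmetic over annotations: the upstream window of a gene is
# the 5 kb 5' of its start on its own strand, and a TE hits when its
# interval overlaps the window at a gene-ward distance of 1-5000 bp
# (overlapping or abutting elements are excluded).  Reference-free mode
# classifies read pairs: a pair is evidence of TE-gene proximity when one
# mate's best mapping target is a TE contig and the other's is a gene.

#' Read-mapping parameters for pair classification
#'
#' Seed-and-extend contract mirroring short-read aligner settings: a
#' `seed_len`-base seed with at most `seed_max_mismatch` mismatches
#' anchors the read; the full read must then align within `max_edit`
#' total edits, `max_gap_open` gap openings and `max_gap_ext` gap
#' extensions.  Candidate placements are scored by
#' `mismatch_penalty * mismatches + gap_open_penalty * openings +
#' gap_ext_penalty * extensions`; the lowest-penalty target wins and reads
#' with equal-best targets of different classes are discarded as
#' ambiguous.
#'
#' @param seed_len Seed length (default 12).
#' @param seed_max_mismatch Maximum seed mismatches (default 2).
#' @param max_edit Maximum total edit distance (default 4).
#' @param max_gap_open Maximum gap openings (default 3).
#' @param max_gap_ext Maximum gap extensions (default 3).
#' @param mismatch_penalty,gap_open_penalty,gap_ext_penalty Scoring
#'   weights (defaults 2, 6, 3).
#' @return An object of class `rs_map_params`.
#' @export
map_params <- function(seed_len = 12, seed_max_mismatch = 2, max_edit = 4,
                       max_gap_open = 3, max_gap_ext = 3,
                       mismatch_penalty = 2, gap_open_penalty = 6,
                       gap_ext_penalty = 3) {
  vals <- c(seed_len, seed_max_mismatch, max_edit, max_gap_open, max_gap_ext,
            mismatch_penalty, gap_open_penalty, gap_ext_penalty)
  if (any(vals < 0)) rs_abort("map parameters must be >= 0", "invalid_argument")
  structure(list(seed_len = as.integer(seed_len),
                 seed_max_mismatch = as.integer(seed_max_mismatch),
                 max_edit = as.integer(max_edit),
                 max_gap_open = as.integer(max_gap_open),
                 max_gap_ext = as.integer(max_gap_ext),
                 mismatch_penalty = as.integer(mismatch_penalty),
                 gap_open_penalty = as.integer(gap_open_penalty),
                 gap_ext_penalty = as.integer(gap_ext_penalty)),
            class = "rs_map_params")
}

#' TE insertions in the 1-5 kb upstream windows of genes
#'
#' For a `+` strand gene the window is `[start - max_kb*1000, start)`; for
#' a `-` strand gene, `[end, end + max_kb*1000)`.  A TE hits when its
#' interval overlaps the window; the distance is the gap between the TE's
#' gene-proximal edge and the gene start, and must be at least 1 (elements
#' overlapping or abutting the gene start are excluded).  Every qualifying
#' (gene, TE) pair is reported, binned by kb (`bin_kb = ceiling(d/1000)`).
#'
#' @param genes,tes Interval data frames (`chrom`, `start`, `end`,
#'   `strand`, `feature_id`, `feature_class`; 0-based half-open).
#' @param max_kb Window size in kb (default 5).
#' @return Data frame `gene_id`, `te_id`, `te_class`, `distance_bp`,
#'   `bin_kb`, `evidence = "interval"`.
#' @export
upstream_hits <- function(genes, tes, max_kb = 5) {
  bad <- !genes$strand %in% c("+", "-")
  if (any(bad))
    rs_abort(paste0("genes with unknown strand: ",
                    paste(genes$feature_id[bad], collapse = ", ")),
             "invalid_argument")
  if (nrow(tes) == 0 || nrow(genes) == 0)
    return(empty_hits_df())
  W <- max_kb * 1000
  plus <- genes$strand == "+"
  win_start <- ifelse(plus, genes$start - W, genes$end)
  win_end <- ifelse(plus, genes$start, genes$end + W)
  win <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(start = win_start + 1L,
                                                 end = win_end))
  te_gr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(start = tes$start + 1L,
                                                   end = tes$end))
  ov <- GenomicRanges::findOverlaps(win, te_gr, ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(ov); ti <- S4Vectors::subjectHits(ov)
  d <- ifelse(plus[gi], genes$start[gi] - tes$end[ti],
              tes$start[ti] - genes$end[gi])
  keep <- d >= 1 & d <= W
  gi <- gi[keep]; ti <- ti[keep]; d <- d[keep]
  out <- data.frame(gene_id = genes$feature_id[gi],
                    te_id = tes$feature_id[ti],
                    te_class = tes$feature_class[ti],
                    distance_bp = as.integer(d),
                    bin_kb = as.integer(ceiling(d / 1000)),
                    evidence = "interval",
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$distance_bp, out$te_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits_df <- function() {
  data.frame(gene_id = character(0), te_id = character(0),
              te_class = character(0), distance_bp = integer(0),
              bin_kb = integer(0), evidence = character(0),
              stringsAsFactors = FALSE)
}

#' Retain read pairs with a TE-matching mate
#'
#' A pair is kept iff either mate has a local alignment to any TE contig
#' at `min_identity` identity or better over at least `min_len` columns;
#' mates stay synchronized.
#'
#' @param pairs List with reads data frames `mate1` and `mate2` (as from
#'   [simulate_reads()] in paired mode or [read_paired_fastq()]).
#' @param te_contigs Named character vector of TE contig sequences.
#' @param min_identity Minimum identity (default 0.80).
#' @param min_len Minimum aligned columns (default 50).
#' @return The filtered pair list (same structure, same relative order).
#' @export
prefilter_te_pairs <- function(pairs, te_contigs, min_identity = 0.80,
                               min_len = 50) {
  check_pair_sync(pairs)
  h1 <- .rs_best_hits(pairs$mate1$seq, unname(te_contigs), min_identity,
                      as.integer(min_len), 1L, -1L, -2L)
  h2 <- .rs_best_hits(pairs$mate2$seq, unname(te_contigs), min_identity,
                      as.integer(min_len), 1L, -1L, -2L)
  keep <- h1$target > 0 | h2$target > 0
  list(mate1 = pairs$mate1[keep, , drop = FALSE],
       mate2 = pairs$mate2[keep, , drop = FALSE])
}

check_pair_sync <- function(pairs) {
  b1 <- sub("/[12]$", "", pairs$mate1$read_id)
  b2 <- sub("/[12]$", "", pairs$mate2$read_id)
  if (length(b1) != length(b2) || any(b1 != b2)) {
    first <- if (length(b1) != length(b2)) {
      if (length(b1) > length(b2)) b1[length(b2) + 1L] else b2[length(b1) + 1L]
    } else b1[which(b1 != b2)[1]]
    rs_abort(sprintf("mates desynchronized at read '%s'", first),
             "desynchronized_mates")
  }
  invisible(TRUE)
}

#' Classify read pairs into TE-near-gene evidence
#'
#' Each mate is mapped against the union of TE contigs and gene sequences
#' by seed-and-extend under `params`.  A pair yields a proximity hit iff
#' one mate's best target is a TE contig and the other's best target is a
#' gene.  Mates with equal-best targets in more than one class are
#' discarded as ambiguous and counted.
#'
#' @param pairs List with reads data frames `mate1`/`mate2`.
#' @param te_contigs Named character vector of TE contig sequences; names
#'   may carry a class as `name#class` (e.g. `CL3#TE:copia`), otherwise
#'   class `TE:other` is assumed.
#' @param gene_seqs Named character vector of gene sequences.
#' @param params [map_params()].
#' @return List: `hits` (data frame `gene_id`, `pair_id`, `te_class`,
#'   `bin_kb = NA`, `evidence = "read_pair"`), `gene_counts` (data frame
#'   `gene_id`, `te_class`, `n_pairs`), `n_ambiguous`,
#'   `n_pairs_classified`.
#' @export
classify_pairs <- function(pairs, te_contigs, gene_seqs,
                           params = map_params()) {
  if (length(te_contigs) == 0 || length(gene_seqs) == 0)
    rs_abort("te_contigs and gene_seqs must be non-empty", "invalid_argument")
  check_pair_sync(pairs)
  te_names <- sub("#.*$", "", names(te_contigs))
  te_class <- ifelse(grepl("#", names(te_contigs)),
                     sub("^[^#]*#", "", names(te_contigs)), "TE:other")
  targets <- c(unname(te_contigs), unname(gene_seqs))
  classes <- c(te_class, rep("gene", length(gene_seqs)))
  target_id <- c(te_names, names(gene_seqs))
  n_te <- length(te_contigs)

  map_mate <- function(seqs) {
    hits <- .rs_map_reads(seqs, targets,
                          params$seed_len, params$seed_max_mismatch,
                          params$max_edit, params$max_gap_open,
                          params$max_gap_ext, params$mismatch_penalty,
                          params$gap_open_penalty, params$gap_ext_penalty)
    n <- length(seqs)
    best <- rep(NA_integer_, n)   # best target index, NA = unmapped
    ambig <- rep(FALSE, n)
    if (nrow(hits) > 0) {
      for (grp in split(seq_len(nrow(hits)), hits$read)) {
        r <- hits$read[grp[1]]
        tg <- unique(hits$target[grp])
        cl <- unique(classes[tg])
        if (length(cl) > 1) ambig[r] <- TRUE else best[r] <- tg[1]
      }
    }
    list(best = best, ambig = ambig)
  }
  m1 <- map_mate(pairs$mate1$seq)
  m2 <- map_mate(pairs$mate2$seq)
  n_ambiguous <- sum(m1$ambig) + sum(m2$ambig)
  pair_id <- sub("/[12]$", "", pairs$mate1$read_id)
  rows <- list()
  n_classified <- 0L
  for (i in seq_along(pair_id)) {
    if (m1$ambig[i] || m2$ambig[i]) next
    b1 <- m1$best[i]; b2 <- m2$best[i]
    if (is.na(b1) || is.na(b2)) next
    c1 <- classes[b1]; c2 <- classes[b2]
    te_first <- c1 != "gene" & c2 == "gene"
    gene_first <- c1 == "gene" & c2 != "gene"
    if (!te_first && !gene_first) next
    n_classified <- n_classified + 1L
    te_t <- if (te_first) b1 else b2
    gene_t <- if (te_first) b2 else b1
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = target_id[gene_t], pair_id = pair_id[i],
      te_class = classes[te_t], te_id = target_id[te_t],
      bin_kb = NA_integer_, evidence = "read_pair",
      stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), pair_id = character(0),
               te_class = character(0), te_id = character(0),
               bin_kb = integer(0), evidence = character(0),
               stringsAsFactors = FALSE)
  gene_counts <- if (nrow(hits)) {
    agg <- stats::aggregate(list(n_pairs = hits$pair_id),
                            by = list(gene_id = hits$gene_id,
                                      te_class = hits$te_class),
                            FUN = length)
    agg[order(agg$gene_id, agg$te_class), , drop = FALSE]
  } else {
    data.frame(gene_id = character(0), te_class = character(0),
               n_pairs = integer(0), stringsAsFactors = FALSE)
  }
  rownames(gene_counts) <- NULL
  list(hits = hits, gene_counts = gene_counts,
       n_ambiguous = n_ambiguous, n_pairs_classified = n_classified)
}
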