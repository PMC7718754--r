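# Cluster annotation against a repeat exemplar library, per-cluster
# per-species consensus assembly, and LTR extraction from consensus
# contigs.  Alignment thresholds are (identity, length) pairs rather than
# E-values so behavior is deterministic and independent of database size;
# the defaults mirror the identities used for LTR extraction (85%) and
# read matching (80%).

#' Annotate a cluster against a repeat exemplar library
#'
#' Each member read is locally aligned to every library record (both
#' strands); a read votes for its best-scoring record among those reaching
#' `min_identity` over `min_hit_len` aligned columns.  The cluster label is
#' the plurality family among voting reads, provided that family collects
#' at least `min_vote_fraction` of the cluster's reads; otherwise a
#' superfamily-level plurality is attempted with the same rule (yielding an
#' unclassified-within-superfamily call), and failing that the cluster is
#' unclassified.  Ties break by higher mean identity, then lexicographic
#' name.
#'
#' @param cluster An `rs_cluster`.
#' @param reads Reads data frame covering the cluster members.
#' @param library Library data frame from [read_repeat_library()].
#' @param min_identity Minimum alignment identity for a vote (default 0.80).
#' @param min_hit_len Minimum aligned columns for a vote (default 50).
#' @param min_vote_fraction Minimum fraction of cluster reads the winning
#'   label must collect (default 0.10).
#' @param max_votes For clusters larger than this, an evenly spaced
#'   deterministic subsample of members votes (plurality fractions are
#'   estimated from the subsample); keeps annotation cost bounded per
#'   cluster.
#' @return List with `family` (character or `NA`), `superfamily` (character
#'   or `NA`), `n_voting`, `n_members`.
#' @export
annotate_cluster <- function(cluster, reads, library,
                             min_identity = 0.80, min_hit_len = 50,
                             min_vote_fraction = 0.10, max_votes = 200) {
  if (is.null(library) || nrow(library) == 0)
    rs_abort("library must be non-empty", "invalid_argument")
  if (length(cluster$members) == 0)
    rs_abort("cluster has no members", "invalid_argument")
  idx <- match(cluster$members, reads$read_id)
  if (anyNA(idx))
    rs_abort("cluster members missing from reads", "invalid_argument")
  if (length(idx) > max_votes)
    idx <- idx[unique(round(seq(1, length(idx), length.out = max_votes)))]
  seqs <- reads$seq[idx]
  hits <- .rs_best_hits(seqs, library$seq, min_identity, min_hit_len,
                        1L, -1L, -2L)
  voting <- hits$target > 0
  n_members <- length(seqs)  # voting universe (subsample when capped)
  unclass <- list(family = NA_character_, superfamily = NA_character_,
                  n_voting = sum(voting), n_members = n_members)
  if (!any(voting)) return(unclass)
  fam_votes <- library$name[hits$target[voting]]
  sf_votes <- library$superfamily[hits$target[voting]]
  idents <- hits$identity[voting]
  pick <- function(votes) {
    tab <- tapply(idents, votes, length)
    mean_id <- tapply(idents, votes, mean)
    ord <- order(-tab, -mean_id, names(tab))
    best <- names(tab)[ord[1]]
    list(label = best, n = tab[[ord[1]]])
  }
  fam <- pick(fam_votes)
  if (fam$n >= min_vote_fraction * n_members) {
    sf <- library$superfamily[match(fam$label, library$name)]
    return(list(family = fam$label, superfamily = sf,
                n_voting = sum(voting), n_members = n_members))
  }
  sf <- pick(sf_votes)
  if (sf$n >= min_vote_fraction * n_members) {
    return(list(family = NA_character_, superfamily = sf$label,
                n_voting = sum(voting), n_members = n_members))
  }
  unclass
}

#' Annotate every significant cluster of a clustering
#'
#' @param clustering An `rs_clustering`.
#' @param library Library data frame from [read_repeat_library()].
#' @param ... Passed to [annotate_cluster()].
#' @return The clustering with `annotation`/`superfamily` filled in on each
#'   significant cluster.
#' @export
annotate_clustering <- function(clustering, library, ...) {
  clustering$clusters <- lapply(clustering$clusters, function(cl) {
    ann <- annotate_cluster(cl, clustering$reads, library, ...)
    cl$annotation <- ann$family
    cl$superfamily <- ann$superfamily
    cl
  })
  clustering
}

#' Assemble a per-species consensus contig for a cluster
#'
#' Greedy overlap-layout assembly, in rounds: the longest read seeds the
#' contig; each round aligns every pending read to the current consensus
#' and places all reads whose best local alignment spans at least
#' `min_overlap` nt at `min_identity` identity or better (highest-scoring
#' first), then the per-column majority consensus is recomputed.  Rounds
#' repeat until no pending read qualifies.  Substitution-only placement is
#' assumed: each merged read is laid onto the contig at the fixed offset
#' from its alignment, and reads overhanging either contig end extend it.
#' Majority ties go to the lexicographically smallest base.
#'
#' @param cluster An `rs_cluster`.
#' @param reads Reads data frame.
#' @param species Species code whose reads are assembled.
#' @param min_overlap Minimum merge overlap in nt (default 30).
#' @param min_identity Minimum merge identity (default 0.90).
#' @param max_reads At most this many reads are assembled (an evenly
#'   spaced subsample when the cluster is larger); 400 gives around 25x
#'   element depth for a 1.5 kb element with 100 nt reads.
#' @return An object of class `rs_consensus`: `cluster_id`, `species_code`,
#'   `seq`, `depth` (mean reads per column), `n_reads_used`.
#' @export
build_consensus <- function(cluster, reads, species,
                            min_overlap = 30, min_identity = 0.90,
                            max_reads = 400) {
  idx <- match(cluster$members, reads$read_id)
  idx <- idx[!is.na(idx)]
  idx <- idx[reads$species_code[idx] == species]
  if (length(idx) < 3)
    rs_abort(sprintf("need >= 3 reads from species '%s' (have %d)",
                     species, length(idx)), "insufficient_reads")
  seqs <- reads$seq[idx]
  ord <- order(-nchar(seqs), reads$read_id[idx])
  seqs <- seqs[ord]
  if (length(seqs) > max_reads)
    seqs <- seqs[unique(round(seq(1, length(seqs), length.out = max_reads)))]

  base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  code_of <- function(s) unname(base_codes[strsplit(s, "", fixed = TRUE)[[1]]])
  # vote matrix: 4 x L counts; grows as reads overhang the contig ends
  votes <- matrix(0L, nrow = 4, ncol = nchar(seqs[1]))
  left_grow <- 0L  # columns prepended during the current round
  add_votes <- function(codes, at) {
    L <- ncol(votes)
    lo <- min(1L, at); hi <- max(L, at + length(codes) - 1L)
    if (lo < 1L || hi > L) {
      grown <- matrix(0L, nrow = 4, ncol = hi - lo + 1L)
      grown[, (1L - lo + 1L):(1L - lo + L)] <- votes
      votes <<- grown
      left_grow <<- left_grow + (1L - lo)
      at <- at - lo + 1L
    }
    cols <- at:(at + length(codes) - 1L)
    keep <- !is.na(codes)
    votes[cbind(codes[keep], cols[keep])] <<-
      votes[cbind(codes[keep], cols[keep])] + 1L
    invisible(NULL)
  }
  consensus_of <- function() {
    paste(c("A", "C", "G", "T")[max.col(t(votes), ties.method = "first")],
          collapse = "")
  }
  add_votes(code_of(seqs[1]), 1L)
  cons <- consensus_of()
  placed <- 1L
  pending <- seqs[-1]
  repeat {
    if (length(pending) == 0) break
    hits <- .rs_best_hits(pending, cons, min_identity,
                          as.integer(min_overlap), 1L, -1L, -2L)
    ok <- hits$target > 0 & hits$identity >= min_identity
    if (!any(ok)) break
    left_grow <- 0L
    for (i in which(ok)[order(-hits$score[ok])]) {
      h <- hits[i, ]
      rd <- pending[i]
      if (h$strand < 0) {
        rd <- revcomp(rd)
        L <- nchar(rd)
        q0 <- L - h$q_end; q1 <- L - h$q_start
        h$q_start <- q0; h$q_end <- q1
      }
      # offset of read base 1 on the round-start contig, shifted by any
      # leftward growth that happened earlier in this round
      at <- (h$t_start + 1L) - h$q_start + left_grow
      add_votes(code_of(rd), at)
      placed <- placed + 1L
    }
    cons <- consensus_of()
    pending <- pending[!ok]
  }
  depth <- sum(votes) / ncol(votes)
  structure(list(cluster_id = cluster$cluster_id, species_code = species,
                 seq = cons, depth = depth, n_reads_used = placed),
            class = "rs_consensus")
}

#' Extract the LTR segment of a consensus contig
#'
#' The contig is locally aligned to every LTR exemplar (both strands); the
#' best-scoring hit reaching `min_identity` over `min_len` columns defines
#' the LTR segment, whose coordinates on the contig are returned and whose
#' sequence is extracted.  Returns `NULL` when no hit qualifies.
#'
#' @param contig An `rs_consensus` (or list with `seq`).
#' @param ltr_db Library data frame of LTR exemplars.
#' @param min_identity Minimum hit identity (default 0.85).
#' @param min_len Minimum hit length in columns (default 80).
#' @return An object of class `rs_ltr_segment` (`cluster_id`,
#'   `species_code`, `start`, `end` 0-based half-open on the contig, `seq`,
#'   `library_hit`, `identity`) or `NULL`.
#' @export
extract_ltr <- function(contig, ltr_db, min_identity = 0.85, min_len = 80) {
  if (is.null(ltr_db) || nrow(ltr_db) == 0)
    rs_abort("ltr_db must be non-empty", "invalid_argument")
  hit <- .rs_best_hits(contig$seq, ltr_db$seq, min_identity,
                       as.integer(min_len), 1L, -1L, -2L)
  if (hit$target[1] == 0) return(NULL)
  start <- hit$q_start[1]; end <- hit$q_end[1]
  structure(list(cluster_id = contig$cluster_id %||% NA_character_,
                 species_code = contig$species_code %||% NA_character_,
                 start = start, end = end,
                 seq = substr(contig$seq, start + 1L, end),
                 library_hit = ltr_db$name[hit$target[1]],
                 identity = hit$identity[1]),
            class = "rs_ltr_segment")
}
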