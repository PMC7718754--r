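# Graph-based clustering of shotgun reads into repeat families.  Reads are
# nodes; an edge connects two reads whose best local alignment reaches 90%
# identity over at least 55% of the shorter read.  Connected components of
# this graph are the repeat clusters, in both single-species and pooled
# comparative modes.

#' Clustering parameters
#'
#' @param min_identity Minimum alignment identity (matches / alignment
#'   columns, gaps counted) for an edge.  Default 0.90.
#' @param min_overlap_fraction Minimum alignment span as a fraction of the
#'   shorter read.  Default 0.55.
#' @param kmer_len k-mer length of the candidate-pair prefilter.  With the
#'   default 8, any alignment qualifying at the default identity/overlap
#'   thresholds must contain an exact match run of at least 8 nt, so the
#'   prefilter cannot lose a true edge (see the methods vignette).
#' @param min_shared_kmers Minimum shared (strand-collapsed) k-mers for a
#'   pair to be aligned.  The default 3 is still a guaranteed superset of
#'   the true edges when the shorter read is at least 100 nt (a qualifying
#'   alignment then shares at least 5 exact 8-mers in the worst case)
#'   while rejecting almost all random read pairs; set to 1 for read sets
#'   with reads shorter than 100 nt.
#' @param significant_fraction Minimum cluster size as a fraction of input
#'   reads for a cluster to be reported as significant; smaller components
#'   go to the remainder bucket.  Default 1e-4 (0.01% of input reads).
#' @param match,mismatch,gap Local-alignment scores.
#' @param max_n_fraction Reads with a larger fraction of N bases are
#'   dropped before clustering.
#' @return An object of class `rs_cluster_params`.
#' @export
cluster_params <- function(min_identity = 0.90, min_overlap_fraction = 0.55,
                           kmer_len = 8, min_shared_kmers = 3,
                           significant_fraction = 1e-4,
                           match = 1, mismatch = -1, gap = -2,
                           max_n_fraction = 0.10) {
  if (min_identity <= 0 || min_identity > 1)
    rs_abort("min_identity must be in (0, 1]", "invalid_argument")
  if (min_overlap_fraction <= 0 || min_overlap_fraction > 1)
    rs_abort("min_overlap_fraction must be in (0, 1]", "invalid_argument")
  structure(list(min_identity = min_identity,
                 min_overlap_fraction = min_overlap_fraction,
                 kmer_len = as.integer(kmer_len),
                 min_shared_kmers = as.integer(min_shared_kmers),
                 significant_fraction = significant_fraction,
                 match = as.integer(match), mismatch = as.integer(mismatch),
                 gap = as.integer(gap), max_n_fraction = max_n_fraction),
            class = "rs_cluster_params")
}

#' Candidate read pairs by shared k-mers
#'
#' Emits every unordered read pair sharing at least
#' `params$min_shared_kmers` strand-collapsed (canonical) k-mers.  With the
#' default `kmer_len = 8` this is a superset of all pairs that pass
#' [align_pair()] at the default thresholds.
#'
#' @param reads Reads data frame (`read_id`, `species_code`, `seq`).
#' @param params [cluster_params()].
#' @return Data frame with columns `a`, `b` (read ids), each pair once.
#' @export
candidate_pairs <- function(reads, params = cluster_params()) {
  m <- .rs_candidate_pairs(reads$seq, params$kmer_len, params$min_shared_kmers)
  data.frame(a = reads$read_id[m[, 1]], b = reads$read_id[m[, 2]],
             stringsAsFactors = FALSE)
}

#' Align a pair of reads and test the edge thresholds
#'
#' Best local alignment (match +1, mismatch -1, gap -2 by default), both
#' orientations, best kept.  Identity is matches over alignment columns
#' (gaps count as columns); the overlap fraction is alignment columns over
#' the shorter read length.  An edge is returned iff identity >=
#' `min_identity` and alignment columns >= `min_overlap_fraction *
#' min(len(a), len(b))`.
#'
#' @param a,b Single-row reads data frames, or lists/character scalars with
#'   the sequence.
#' @param params [cluster_params()].
#' @return A list (`a`, `b`, `identity`, `overlap_fraction`) or `NULL`.
#' @export
align_pair <- function(a, b, params = cluster_params()) {
  seq_of <- function(x) if (is.character(x)) x else x$seq
  id_of <- function(x, default) {
    if (is.character(x)) default
    else if (!is.null(x$read_id)) x$read_id else default
  }
  sa <- seq_of(a); sb <- seq_of(b)
  aln <- .rs_sw_align(sa, sb, params$match, params$mismatch, params$gap, TRUE)
  if (aln$columns == 0) return(NULL)
  identity <- aln$matches / aln$columns
  shorter <- min(nchar(sa), nchar(sb))
  if (identity >= params$min_identity &&
      aln$columns >= params$min_overlap_fraction * shorter) {
    list(a = id_of(a, "a"), b = id_of(b, "b"),
         identity = identity,
         overlap_fraction = min(1, aln$columns / shorter))
  } else NULL
}

#' Cluster reads into repeat families
#'
#' Builds the read-similarity graph over candidate pairs and partitions the
#' reads into its connected components.  Components smaller than
#' `significant_fraction` of the input are reported in the remainder
#' bucket.  Significant clusters are sorted by size (descending) and named
#' CL1, CL2, ...  Reads with more than `max_n_fraction` N bases are dropped
#' (with a message) before graph construction.
#'
#' @param reads Reads data frame.
#' @param params [cluster_params()].
#' @return A list of class `rs_clustering`: `clusters` (list of
#'   `rs_cluster`), `remainder` (list of `rs_cluster`), `edges` (data
#'   frame), `reads` (the retained reads), `n_dropped`.
#' @export
build_clusters <- function(reads, params = cluster_params()) {
  if (is.null(reads) || nrow(reads) == 0)
    rs_abort("reads must be non-empty", "invalid_argument")
  nfrac <- n_fraction(reads$seq)
  drop <- nfrac > params$max_n_fraction
  if (any(drop)) {
    message(sprintf("dropping %d read(s) with > %.0f%% N bases",
                    sum(drop), 100 * params$max_n_fraction))
    reads <- reads[!drop, , drop = FALSE]
  }
  if (nrow(reads) == 0)
    rs_abort("no reads left after N filtering", "invalid_argument")
  n <- nrow(reads)
  cand <- .rs_candidate_pairs(reads$seq, params$kmer_len,
                              params$min_shared_kmers)
  edges <- .rs_align_pairs_batch(reads$seq, cand[, 1], cand[, 2],
                                 params$min_identity,
                                 params$min_overlap_fraction,
                                 params$match, params$mismatch, params$gap)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  comp <- igraph::components(g)$membership
  min_size <- params$significant_fraction * n
  by_comp <- split(seq_len(n), comp)
  sizes <- lengths(by_comp)
  # order components by size desc, ties by smallest member index for
  # deterministic numbering
  first_member <- vapply(by_comp, min, numeric(1))
  ord <- order(-sizes, first_member)
  clusters <- list(); remainder <- list()
  ci <- 0L
  for (k in ord) {
    idx <- by_comp[[k]]
    members <- reads$read_id[idx]
    counts <- table(reads$species_code[idx])
    cl <- structure(list(cluster_id = NA_character_,
                         members = members,
                         species_counts = stats::setNames(as.integer(counts),
                                                          names(counts)),
                         annotation = NULL, superfamily = NULL),
                    class = "rs_cluster")
    if (length(idx) >= min_size) {
      ci <- ci + 1L
      cl$cluster_id <- paste0("CL", ci)
      clusters[[length(clusters) + 1L]] <- cl
    } else {
      cl$cluster_id <- paste0("RM", length(remainder) + 1L)
      remainder[[length(remainder) + 1L]] <- cl
    }
  }
  edge_df <- data.frame(a = reads$read_id[edges$i], b = reads$read_id[edges$j],
                        identity = edges$identity,
                        overlap_fraction = edges$overlap_fraction,
                        stringsAsFactors = FALSE)
  structure(list(clusters = clusters, remainder = remainder,
                 edges = edge_df, reads = reads, n_dropped = sum(drop),
                 params = params),
            class = "rs_clustering")
}

#' Pool and subsample reads across species for comparative clustering
#'
#' Takes a uniform random subsample without replacement of
#' `per_species_sample` reads from each species (all reads if fewer, with a
#' warning) and stamps the species code into each read, emulating the
#' concatenated multi-species dataset of a comparative clustering run.
#'
#' @param readsets Named list (species code -> reads data frame or
#'   FASTA/FASTQ path).
#' @param per_species_sample Reads to draw per species (>= 1).
#' @param seed Integer seed.
#' @return A pooled reads data frame.
#' @export
pool_species <- function(readsets, per_species_sample, seed) {
  if (per_species_sample < 1)
    rs_abort("per_species_sample must be >= 1", "invalid_argument")
  if (is.null(names(readsets)) || any(names(readsets) == ""))
    rs_abort("readsets must be named by species code", "invalid_argument")
  set.seed(seed)
  pooled <- list()
  for (sp in names(readsets)) {
    rd <- readsets[[sp]]
    if (is.character(rd)) rd <- read_reads(rd, species_code = sp)
    if (is.null(rd) || nrow(rd) == 0)
      rs_abort(sprintf("readset for species '%s' is empty", sp),
               "empty_readset")
    if (nrow(rd) > per_species_sample) {
      rd <- rd[sample(nrow(rd), per_species_sample), , drop = FALSE]
    } else if (nrow(rd) < per_species_sample) {
      warning(sprintf("species '%s': only %d reads available (requested %d)",
                      sp, nrow(rd), per_species_sample))
    }
    rd$species_code <- sp
    pooled[[sp]] <- rd
  }
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out
}

#' Summarize a clustering as a data frame
#'
#' @param clustering An `rs_clustering`.
#' @param include_remainder Include remainder components.
#' @return Data frame: `cluster_id`, `size`, one count column per species,
#'   `annotation`, `superfamily`.
#' @export
cluster_summary <- function(clustering, include_remainder = FALSE) {
  cls <- clustering$clusters
  if (include_remainder) cls <- c(cls, clustering$remainder)
  species <- sort(unique(clustering$reads$species_code))
  counts <- matrix(0L, nrow = length(cls), ncol = length(species),
                   dimnames = list(NULL, species))
  for (i in seq_along(cls))
    counts[i, names(cls[[i]]$species_counts)] <- cls[[i]]$species_counts
  out <- data.frame(
    cluster_id = vapply(cls, function(cl) cl$cluster_id, character(1)),
    size = vapply(cls, function(cl) length(cl$members), integer(1)),
    annotation = vapply(cls, function(cl)
      cl$annotation %||% NA_character_, character(1)),
    superfamily = vapply(cls, function(cl)
      cl$superfamily %||% NA_character_, character(1)),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(counts))
}

#' Cluster membership table
#' @param clustering An `rs_clustering`.
#' @return Data frame `read_id`, `cluster_id`, `species_code` over all
#'   reads (significant and remainder components).
#' @export
cluster_membership <- function(clustering) {
  cls <- c(clustering$clusters, clustering$remainder)
  rows <- lapply(cls, function(cl)
    data.frame(read_id = cl$members, cluster_id = cl$cluster_id,
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$species_code <- clustering$reads$species_code[
    match(df$read_id, clustering$reads$read_id)]
  df[order(match(df$read_id, clustering$reads$read_id)), , drop = FALSE]
}
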