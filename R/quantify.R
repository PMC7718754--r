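# Genome-occupancy quantification and cross-species sharing.  Cluster
# sizes (in read-length Mb) convert to Mb of genome space via
#   occupancy_mb = cluster_len_mb * genome_size_mb / denominator_mb.
# The denominator is the total length of ALL analyzed reads (clustered and
# unclustered), so that per-species occupancies over all components sum
# exactly to the genome size; repeat families then account for less than
# 100% of the genome, with the rest attributed to unclustered (low-copy)
# sequence.  The literal all-clusters denominator, which forces cluster
# occupancies to sum to the full genome, is available behind a flag.

# total length (Mb) of a cluster's member reads, optionally one species
cluster_len_mb <- function(cluster, reads, species = NULL) {
  idx <- match(cluster$members, reads$read_id)
  if (!is.null(species)) idx <- idx[reads$species_code[idx] == species]
  sum(nchar(reads$seq[idx])) / 1e6
}

#' Genome space occupied by one cluster
#'
#' `occupancy_mb = cluster_len_mb * genome_size_mb / total_input_len_mb`,
#' where the cluster length is the summed length of its member reads and
#' `total_input_len_mb` is the total length of all analyzed reads.
#'
#' @param cluster An `rs_cluster`.
#' @param reads Reads data frame.
#' @param genome_size_mb Genome size (Mb).
#' @param total_input_len_mb Total length of all analyzed reads (Mb).
#' @param species Restrict member reads to one species (pooled mode).
#' @return Occupancy in Mb.
#' @export
cluster_occupancy <- function(cluster, reads, genome_size_mb,
                              total_input_len_mb, species = NULL) {
  if (!is.numeric(total_input_len_mb) || total_input_len_mb <= 0)
    rs_abort("total_input_len_mb must be > 0", "invalid_argument")
  if (!is.numeric(genome_size_mb) || genome_size_mb <= 0)
    rs_abort("genome_size_mb must be > 0", "invalid_argument")
  cluster_len_mb(cluster, reads, species) * genome_size_mb / total_input_len_mb
}

#' Per-family, per-species composition table
#'
#' Sums cluster occupancies over clusters sharing a family label.
#' Unlabeled clusters aggregate into `Unclass.<superfamily>` rows (or
#' `Unclassified` when the superfamily is also unknown).  The attribute
#' `genome_proportion` carries, per species, the clustered fraction of the
#' genome: sum of significant-cluster occupancies over genome size.
#'
#' @param clustering An annotated `rs_clustering` (see
#'   [annotate_clustering()]).
#' @param per_species_inputs Data frame with `species_code`,
#'   `genome_size_mb` and optionally `total_input_len_mb` (defaults to the
#'   per-species total read length in the clustering input).
#' @param literal_denominator Use the summed length of clustered reads as
#'   the denominator instead of all analyzed reads.
#' @return Data frame `family`, `superfamily`, `species_code`,
#'   `occupancy_mb`, `cluster_ids`, with a `genome_proportion` attribute
#'   (named numeric, one entry per species).
#' @export
composition_table <- function(clustering, per_species_inputs,
                              literal_denominator = FALSE) {
  reads <- clustering$reads
  species <- per_species_inputs$species_code
  # per-species denominators
  denom <- numeric(length(species))
  for (si in seq_along(species)) {
    sp <- species[si]
    if (!is.null(per_species_inputs$total_input_len_mb)) {
      denom[si] <- per_species_inputs$total_input_len_mb[si]
    } else if (literal_denominator) {
      denom[si] <- sum(vapply(c(clustering$clusters, clustering$remainder),
                              cluster_len_mb, numeric(1),
                              reads = reads, species = sp))
    } else {
      denom[si] <- sum(nchar(reads$seq[reads$species_code == sp])) / 1e6
    }
  }
  names(denom) <- species
  rows <- list()
  prop <- stats::setNames(numeric(length(species)), species)
  for (si in seq_along(species)) {
    sp <- species[si]
    G <- per_species_inputs$genome_size_mb[si]
    occ <- vapply(clustering$clusters, cluster_len_mb, numeric(1),
                  reads = reads, species = sp) * G / denom[si]
    label <- vapply(clustering$clusters, function(cl) {
      if (!is.null(cl$annotation) && !is.na(cl$annotation)) cl$annotation
      else if (!is.null(cl$superfamily) && !is.na(cl$superfamily))
        paste0("Unclass.", cl$superfamily)
      else "Unclassified"
    }, character(1))
    sf <- vapply(clustering$clusters, function(cl)
      cl$superfamily %||% NA_character_, character(1))
    ids <- vapply(clustering$clusters, function(cl) cl$cluster_id, character(1))
    keep <- occ > 0
    if (any(keep)) {
      agg <- split(seq_along(occ)[keep], label[keep])
      rows[[sp]] <- do.call(rbind, lapply(names(agg), function(lb) {
        ii <- agg[[lb]]
        data.frame(family = lb,
                   superfamily = sf[ii[1]] %||% NA_character_,
                   species_code = sp,
                   occupancy_mb = sum(occ[ii]),
                   cluster_ids = paste(ids[ii], collapse = ","),
                   stringsAsFactors = FALSE)
      }))
    }
    prop[sp] <- sum(occ) / G
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$species_code, -out$occupancy_mb), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "genome_proportion") <- prop
  out
}

#' Cross-species cluster-sharing intersections
#'
#' A species is present in a cluster iff it contributes at least
#' `min_reads_per_species` reads.  Each cluster with a non-empty presence
#' set contributes to exactly one intersection row (its exact presence
#' set), so row counts partition the clusters — the long format behind an
#' UpSet plot.
#'
#' @param clustering An `rs_clustering` from pooled comparative input (or a
#'   plain list of `rs_cluster` objects).
#' @param min_reads_per_species Presence threshold (default 5), suppressing
#'   cross-species read contamination in pooled clustering.
#' @return Data frame `species_set` (codes sorted and joined with `+`),
#'   `n_species`, `n_clusters`, plus attribute `cluster_sets` (named list:
#'   cluster_id -> presence set).
#' @export
sharing_matrix <- function(clustering, min_reads_per_species = 5) {
  cls <- if (inherits(clustering, "rs_clustering")) clustering$clusters
         else clustering
  sets <- lapply(cls, function(cl) {
    present <- names(cl$species_counts)[cl$species_counts >=
                                          min_reads_per_species]
    sort(present)
  })
  names(sets) <- vapply(cls, function(cl) cl$cluster_id, character(1))
  nonempty <- lengths(sets) > 0
  keys <- vapply(sets[nonempty], paste, character(1), collapse = "+")
  tab <- table(keys)
  out <- data.frame(species_set = names(tab),
                    n_species = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    n_clusters = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_species, out$species_set), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cluster_sets") <- sets[nonempty]
  out
}
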