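# Molecular-clock dating of retrotransposon activity.  Reads are mapped
# back to their cluster's consensus LTR; the modal bin of the per-read
# identity distribution ("peak activity") converts to an age through the
# grass TE substitution rate (default 1.3e-8 per site per year).  Two
# conversion conventions exist: consensus mode (age = d / r; the consensus
# approximates the ancestral state, so each read diverges along one
# lineage) and pair mode (age = d / 2r; two sister sequences diverging
# from a common ancestor, as for the two LTRs of one element).

#' Map cluster reads to a consensus LTR
#'
#' Each read is locally aligned to the LTR on both strands; reads whose
#' best alignment spans at least `min_overlap` columns at `min_identity`
#' identity or better contribute an identity (matches over alignment
#' columns).  Others are excluded and counted.  The identity floor keeps
#' chance alignments of non-LTR reads (which plateau near 60-65% identity
#' with gaps) out of the distribution while retaining any plausibly
#' dateable divergence (80% identity is ~15 My at the default clock).
#'
#' @param reads Reads data frame.
#' @param ltr An `rs_ltr_segment` (or list with `seq`; >= 80 nt).
#' @param min_overlap Minimum aligned columns (default 50).
#' @param min_identity Minimum alignment identity (default 0.80).
#' @param bin_width Histogram bin width stored with the distribution.
#' @return An object of class `rs_identity_distribution`: `cluster_id`,
#'   `species_code`, `identities`, `matches`, `columns`, `n_excluded`,
#'   `bin_width`.
#' @export
map_reads_to_ltr <- function(reads, ltr, min_overlap = 50,
                             min_identity = 0.80, bin_width = 0.01) {
  if (nchar(ltr$seq) < 80)
    rs_abort("LTR segment must be >= 80 nt", "invalid_argument")
  hits <- .rs_best_hits(reads$seq, ltr$seq, min_identity,
                        as.integer(min_overlap), 1L, -1L, -2L)
  mapped <- hits$target > 0
  if (!any(mapped))
    rs_abort("no read maps to the LTR", "empty_distribution")
  structure(list(cluster_id = ltr$cluster_id %||% NA_character_,
                 species_code = ltr$species_code %||% NA_character_,
                 identities = hits$identity[mapped],
                 matches = hits$matches[mapped],
                 columns = hits$columns[mapped],
                 n_excluded = sum(!mapped),
                 bin_width = bin_width),
            class = "rs_identity_distribution")
}

#' Pooled identity of a distribution
#'
#' Total matches over total alignment columns across the mapped reads —
#' the maximum-likelihood divergence estimate for a family whose copies
#' arose in a single amplification burst, and, unlike the modal-bin peak,
#' continuous in age.
#'
#' @param dist An `rs_identity_distribution`.
#' @return Pooled identity in `[0, 1]`.
#' @export
pooled_identity <- function(dist) {
  if (is.null(dist$matches) || is.null(dist$columns))
    return(mean(dist$identities))
  sum(dist$matches) / sum(dist$columns)
}

#' Peak activity of an identity distribution
#'
#' Identities are histogrammed at `bin_width` (bins `[k w, (k+1) w)`, with
#' identity 1 assigned to the top bin); the peak is the midpoint of the
#' modal bin, ties broken toward higher identity (younger activity).
#'
#' @param dist An `rs_identity_distribution` (or list with `identities`
#'   and `bin_width`).
#' @return The peak identity (modal-bin midpoint).
#' @export
peak_activity <- function(dist) {
  ids <- dist$identities
  if (length(ids) < 5)
    rs_abort("need >= 5 identities for peak estimation", "insufficient_data")
  w <- dist$bin_width %||% 0.01
  bins <- pmin(floor(ids / w), ceiling(1 / w) - 1L)
  tab <- table(bins)
  top <- max(tab)
  modal <- max(as.integer(names(tab)[tab == top]))  # tie -> higher identity
  (modal + 0.5) * w
}

#' Convert an identity to an age under the molecular clock
#'
#' With divergence `d = 1 - identity`: consensus mode gives
#' `age_years = d / r`, pair mode `d / (2 r)`; ages are reported in My.
#' An optional constant `error_rate` is subtracted from d first
#' (`d' = max(0, d - error_rate)`) to discount sequencing error.
#'
#' @param peak_identity Identity in `[0, 1]`.
#' @param clock A [clock_model()]; its `divergence_mode` selects the
#'   convention.
#' @param error_rate Constant divergence attributable to sequencing error.
#' @return Age in My.
#' @export
identity_to_age <- function(peak_identity, clock, error_rate = 0) {
  if (!is.numeric(peak_identity) || any(peak_identity < 0) ||
      any(peak_identity > 1))
    rs_abort("peak_identity must be in [0, 1]", "invalid_argument")
  d <- pmax(0, (1 - peak_identity) - error_rate)
  r <- clock$rate_per_site_per_year
  years <- if (clock$divergence_mode == "pair") d / (2 * r) else d / r
  years / 1e6
}

#' Date a single element from its LTR pair
#'
#' The two LTRs of an element are identical at insertion and diverge
#' thereafter along two lineages, so pair-mode conversion is intrinsic:
#' `age = (1 - identity) / (2 r)`.  The LTRs are globally aligned
#' (Needleman-Wunsch, match +1, mismatch -1, gap -2) and identity is
#' matches over alignment columns.
#'
#' @param ltr5,ltr3 The two LTR sequences (>= 80 nt each).
#' @param clock A [clock_model()]; only the rate is used.
#' @return Age in My.
#' @export
date_element_by_ltr_pair <- function(ltr5, ltr3, clock) {
  if (nchar(ltr5) < 80 || nchar(ltr3) < 80)
    rs_abort("both LTRs must be >= 80 nt", "invalid_argument")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(ltr5, ltr3, type = "global",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  identity <- Biostrings::nmatch(pa) / cols
  if (identity < 0.5)
    rs_abort(sprintf("LTR pair identity %.2f < 0.5; not a plausible pair",
                     identity), "implausible_pair")
  identity_to_age(identity, clock_model(clock$rate_per_site_per_year, "pair"))
}

#' Date one cluster in one species
#'
#' Orchestrates consensus assembly, LTR extraction, read-to-LTR mapping
#' and clock conversion for one cluster/species.  The age point estimate
#' converts the pooled identity ([pooled_identity()]); the modal-bin peak
#' ([peak_activity()]) is reported alongside for the activity histogram.
#'
#' @param cluster An `rs_cluster`.
#' @param reads Reads data frame.
#' @param species Species code.
#' @param ltr_db LTR exemplar library data frame.
#' @param clock A [clock_model()].
#' @param error_rate Sequencing-error divergence discount (see
#'   [identity_to_age()]).
#' @param consensus Optional precomputed `rs_consensus` to reuse.
#' @param ... Passed to [build_consensus()].
#' @return An `rs_age_estimate` list (`cluster_id`, `species_code`,
#'   `peak_identity`, `pooled_identity`, `age_my`, `mode`, `n_reads`,
#'   `status`); when a stage cannot run (too few reads, no LTR hit, no
#'   mapped read) the estimate is flagged via `status` rather than
#'   dropped.
#' @export
date_cluster <- function(cluster, reads, species, ltr_db, clock,
                         error_rate = 0, consensus = NULL, ...) {
  out <- list(cluster_id = cluster$cluster_id, species_code = species,
              peak_identity = NA_real_, pooled_identity = NA_real_,
              age_my = NA_real_, mode = clock$divergence_mode,
              n_reads = NA_integer_, status = "ok")
  est <- tryCatch({
    cons <- consensus %||% build_consensus(cluster, reads, species, ...)
    ltr <- extract_ltr(cons, ltr_db)
    if (is.null(ltr)) {
      out$status <- "no_ltr_hit"
      return(structure(out, class = "rs_age_estimate"))
    }
    idx <- match(cluster$members, reads$read_id)
    idx <- idx[reads$species_code[idx] == species]
    dist <- map_reads_to_ltr(reads[idx, , drop = FALSE], ltr)
    out$peak_identity <- peak_activity(dist)
    out$pooled_identity <- pooled_identity(dist)
    out$age_my <- identity_to_age(out$pooled_identity, clock, error_rate)
    out$n_reads <- length(dist$identities)
    out
  }, repeatscape_error = function(e) {
    out$status <- sub("^repeatscape_", "", class(e)[1])
    out
  })
  structure(est, class = "rs_age_estimate")
}

#' Assemble age estimates into a long activity-timeline table
#'
#' @param estimates List of `rs_age_estimate` objects.
#' @return Data frame `cluster_id`, `species_code`, `peak_identity`,
#'   `pooled_identity`, `age_my`, `mode`, `n_reads`, `status`; estimates
#'   that could not be computed keep their row, flagged by `status`.
#' @export
activity_timeline <- function(estimates) {
  do.call(rbind, lapply(estimates, function(e)
    data.frame(cluster_id = e$cluster_id, species_code = e$species_code,
               peak_identity = e$peak_identity,
               pooled_identity = e$pooled_identity %||% NA_real_,
               age_my = e$age_my,
               mode = e$mode, n_reads = e$n_reads, status = e$status,
               stringsAsFactors = FALSE)))
}
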