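# Synthetic data generation: repeat family libraries, genomes with planted
# TE insertions of known age and placement, and shotgun read sets.  Every
# placement is recorded in a ground-truth ledger so downstream estimates
# (cluster membership, occupancy, insertion age, gene proximity) can be
# scored against what was planted.

SUPERFAMILIES <- c("gypsy", "copia", "DNA", "satellite", "other")

#' Construct a TE family specification
#'
#' A family is defined by its LTR and internal consensus sequences, the
#' amount of genome space its copies should occupy, and the mean and spread
#' of its insertion ages.  Copies are generated as LTR-internal-LTR
#' elements decayed from this consensus under a molecular clock.
#'
#' @param name Family identifier (unique within a library).
#' @param superfamily One of `"gypsy"`, `"copia"`, `"DNA"`, `"satellite"`,
#'   `"other"`.
#' @param ltr_seq LTR consensus (100-2000 nt, A/C/G/T).
#' @param internal_seq Internal-region consensus (>= 500 nt, A/C/G/T).
#' @param target_mb Genome space the family should occupy, in Mb.
#' @param age_my Mean insertion age in million years (My).
#' @param age_sd_my Standard deviation of insertion ages (My).
#' @return An object of class `rs_family`.
#' @export
te_family <- function(name, superfamily, ltr_seq, internal_seq,
                      target_mb, age_my, age_sd_my = 0) {
  superfamily <- match.arg(superfamily, SUPERFAMILIES)
  ltr_seq <- toupper(ltr_seq); internal_seq <- toupper(internal_seq)
  if (grepl("[^ACGT]", ltr_seq) || grepl("[^ACGT]", internal_seq))
    rs_abort("family sequences must contain only A/C/G/T", "invalid_argument")
  if (nchar(ltr_seq) < 100 || nchar(ltr_seq) > 2000)
    rs_abort("ltr_seq must be 100-2000 nt", "invalid_argument")
  if (nchar(internal_seq) < 500)
    rs_abort("internal_seq must be >= 500 nt", "invalid_argument")
  if (target_mb < 0 || age_my < 0 || age_sd_my < 0)
    rs_abort("target_mb, age_my and age_sd_my must be >= 0", "invalid_argument")
  structure(list(name = name, superfamily = superfamily,
                 ltr_seq = ltr_seq, internal_seq = internal_seq,
                 target_mb = target_mb, age_my = age_my,
                 age_sd_my = age_sd_my),
            class = "rs_family")
}

# Full-length element consensus: 5' LTR + internal + 3' LTR.
family_consensus <- function(fam) {
  paste0(fam$ltr_seq, fam$internal_seq, fam$ltr_seq)
}

#' Simulate a library of random TE families
#'
#' Draws `n_families` families with random LTR and internal consensus
#' sequences.  When `n_families >= 2` the library is guaranteed to contain
#' at least one gypsy and one copia family, mirroring the dominance of the
#' two LTR-retrotransposon superfamilies in plant genomes.
#'
#' @param n_families Number of families (>= 1).
#' @param seed Integer seed; output is deterministic per seed.
#' @param ltr_len_range,internal_len_range Length ranges (nt) to draw the
#'   LTR and internal consensus lengths from.
#' @param target_mb_range Range of genome occupancy targets (Mb).
#' @param age_my_range Range of mean insertion ages (My).
#' @return A list of [te_family()] objects.
#' @export
simulate_family_library <- function(n_families, seed,
                                    ltr_len_range = c(300, 600),
                                    internal_len_range = c(1000, 2000),
                                    target_mb_range = c(0.03, 0.08),
                                    age_my_range = c(0.5, 5)) {
  if (!is.numeric(n_families) || n_families < 1)
    rs_abort("n_families must be >= 1", "invalid_argument")
  n_families <- as.integer(n_families)
  set.seed(seed)
  sf <- sample(c("gypsy", "copia"), n_families, replace = TRUE)
  if (n_families >= 2) {
    # guarantee both major superfamilies are represented
    if (!"gypsy" %in% sf) sf[1] <- "gypsy"
    if (!"copia" %in% sf) sf[2] <- "copia"
  }
  lapply(seq_len(n_families), function(i) {
    ltr_len <- sample_int_range(ltr_len_range[1], ltr_len_range[2])
    int_len <- sample_int_range(internal_len_range[1], internal_len_range[2])
    age <- runif(1, age_my_range[1], age_my_range[2])
    te_family(name = sprintf("FAM%02d", i), superfamily = sf[i],
              ltr_seq = random_dna(ltr_len),
              internal_seq = random_dna(int_len),
              target_mb = runif(1, target_mb_range[1], target_mb_range[2]),
              age_my = age, age_sd_my = 0.1 * age)
  })
}

#' Construct a species profile for genome simulation
#'
#' @param species_code Short identifier (e.g. `"Zm"`).
#' @param genome_size_mb Genome size in Mb.
#' @param families List of [te_family()] objects to plant.
#' @param gene_count Number of protein-coding genes to place.
#' @param gene_len Gene length in nt.
#' @return An object of class `rs_species_profile`.
#' @export
species_profile <- function(species_code, genome_size_mb, families,
                            gene_count = 20, gene_len = 1000) {
  if (!is.numeric(genome_size_mb) || genome_size_mb <= 0)
    rs_abort("genome_size_mb must be > 0", "invalid_argument")
  if (!all(vapply(families, inherits, logical(1), "rs_family")))
    rs_abort("families must be a list of te_family objects", "invalid_argument")
  structure(list(species_code = species_code,
                 genome_size_mb = genome_size_mb,
                 families = families,
                 gene_count = as.integer(gene_count),
                 gene_len = as.integer(gene_len)),
            class = "rs_species_profile")
}

#' Construct a molecular-clock model
#'
#' The default substitution rate is the grass transposable-element rate of
#' 1.3e-8 substitutions per site per year.  `divergence_mode` states how a
#' divergence d is converted to an age: `"consensus"` treats d as having
#' accrued along a single lineage (age = d / r) and `"pair"` as having
#' accrued along two lineages since they were identical (age = d / 2r), the
#' situation of the two LTRs of one element.
#'
#' @param rate_per_site_per_year Substitution rate r (> 0).
#' @param divergence_mode `"consensus"` or `"pair"`.
#' @return An object of class `rs_clock`.
#' @export
clock_model <- function(rate_per_site_per_year = 1.3e-8,
                        divergence_mode = c("consensus", "pair")) {
  if (!is.numeric(rate_per_site_per_year) || rate_per_site_per_year <= 0)
    rs_abort("substitution rate must be > 0", "invalid_argument")
  structure(list(rate_per_site_per_year = rate_per_site_per_year,
                 divergence_mode = match.arg(divergence_mode)),
            class = "rs_clock")
}

# Draw insertion ages from Normal(age_my, age_sd_my) truncated at 0
# (negatives are redrawn).
draw_ages <- function(n, age_my, age_sd_my) {
  if (age_sd_my <= 0) return(rep(age_my, n))
  ages <- rnorm(n, age_my, age_sd_my)
  while (any(ages < 0)) {
    bad <- ages < 0
    ages[bad] <- rnorm(sum(bad), age_my, age_sd_my)
  }
  ages
}

#' Simulate a genome with planted TE insertions
#'
#' Builds one chromosome containing non-overlapping genes, TE copies and
#' random background sequence.  Each TE copy is the family consensus
#' (5'LTR-internal-3'LTR) decayed by independent per-site substitutions with
#' probability `min(r * age_years, 0.75)`; because every site mutates
#' independently, the two LTRs of one copy diverge from each other at the
#' expected rate 2 r t while the copy diverges from the consensus at r t.
#' A configurable fraction of copies is placed in the strand-aware upstream
#' window of a randomly chosen gene at a distance drawn uniformly from
#' `upstream_range`.  Every placement is recorded in the truth ledger.
#'
#' @param profile A [species_profile()].
#' @param clock A [clock_model()]; only the rate is used here.
#' @param seed Integer seed.
#' @param adjacent_fraction Fraction of TE copies placed gene-adjacent.
#' @param upstream_range Range (bp) for the upstream distance of
#'   gene-adjacent copies.
#' @param min_spacer Minimum background spacer between placed features (bp);
#'   guarantees genes without a planted adjacent copy have no TE anywhere
#'   near their upstream window.
#' @return A list of class `rs_genome_sim` with elements `genome` (named
#'   character, one chromosome), `genes` and `tes` (interval data frames,
#'   0-based half-open), `truth` (the insertion ledger), `realized_mb`
#'   (named per family), and `profile`.
#' @export
simulate_genome <- function(profile, clock, seed,
                            adjacent_fraction = 0.2,
                            upstream_range = c(1, 5000),
                            min_spacer = 6000) {
  stopifnot(inherits(profile, "rs_species_profile"), inherits(clock, "rs_clock"))
  G <- round(profile$genome_size_mb * 1e6)
  target_sum <- sum(vapply(profile$families, function(f) f$target_mb, numeric(1)))
  if (target_sum * 1e6 > G)
    rs_abort(sprintf("family target_mb sum (%.3f Mb) exceeds genome size (%.3f Mb)",
                     target_sum, profile$genome_size_mb), "infeasible_profile")
  set.seed(seed)
  r <- clock$rate_per_site_per_year
  sp <- profile$species_code

  # plan TE copies per family
  copies <- list()
  for (fam in profile$families) {
    cons <- family_consensus(fam)
    elen <- nchar(cons)
    n_copies <- max(1L, round(fam$target_mb * 1e6 / elen))
    ages <- draw_ages(n_copies, fam$age_my, fam$age_sd_my)
    for (ci in seq_len(n_copies)) {
      p_sub <- min(r * ages[ci] * 1e6, 0.75)
      copies[[length(copies) + 1L]] <- list(
        family = fam$name, superfamily = fam$superfamily,
        seq = mutate_seq(cons, p_sub), age_my = ages[ci],
        ltr_len = nchar(fam$ltr_seq), strand = sample(c("+", "-"), 1L))
    }
  }

  # genes
  n_genes <- profile$gene_count
  genes <- lapply(seq_len(n_genes), function(i) {
    list(gene_id = sprintf("%s_g%03d", sp, i),
         seq = random_dna(profile$gene_len),
         strand = sample(c("+", "-"), 1L))
  })

  # assign a subset of copies to upstream windows of distinct genes
  n_adj <- min(round(adjacent_fraction * length(copies)), n_genes)
  adj_copy_idx <- if (n_adj > 0) sample(seq_along(copies), n_adj) else integer(0)
  adj_gene_idx <- if (n_adj > 0) sample(seq_len(n_genes), n_adj) else integer(0)
  adj_dist <- if (n_adj > 0)
    sample_int_range(upstream_range[1], upstream_range[2], n_adj) else integer(0)

  # compose placement units; each unit is a list of blocks laid left to right
  units <- list()
  gene_done <- rep(FALSE, n_genes)
  copy_done <- rep(FALSE, length(copies))
  for (a in seq_len(n_adj)) {
    cp <- copies[[adj_copy_idx[a]]]
    gn <- genes[[adj_gene_idx[a]]]
    d <- adj_dist[a]
    te_seq <- if (cp$strand == "-") revcomp(cp$seq) else cp$seq
    blocks <- if (gn$strand == "+") {
      # upstream = left of gene start
      list(list(kind = "te", copy = adj_copy_idx[a], seq = te_seq),
           list(kind = "bg", seq = random_dna(d)),
           list(kind = "gene", gene = adj_gene_idx[a], seq = gn$seq))
    } else {
      # upstream = right of gene end
      list(list(kind = "gene", gene = adj_gene_idx[a], seq = gn$seq),
           list(kind = "bg", seq = random_dna(d)),
           list(kind = "te", copy = adj_copy_idx[a], seq = te_seq))
    }
    units[[length(units) + 1L]] <- list(blocks = blocks,
                                        dist = d, gene = adj_gene_idx[a],
                                        copy = adj_copy_idx[a])
    gene_done[adj_gene_idx[a]] <- TRUE
    copy_done[adj_copy_idx[a]] <- TRUE
  }
  for (i in which(!gene_done)) {
    units[[length(units) + 1L]] <- list(blocks = list(
      list(kind = "gene", gene = i, seq = genes[[i]]$seq)))
  }
  for (i in which(!copy_done)) {
    cp <- copies[[i]]
    te_seq <- if (cp$strand == "-") revcomp(cp$seq) else cp$seq
    units[[length(units) + 1L]] <- list(blocks = list(
      list(kind = "te", copy = i, seq = te_seq)))
  }
  units <- units[sample(length(units))]

  unit_len <- vapply(units, function(u)
    sum(vapply(u$blocks, function(b) nchar(b$seq), numeric(1))), numeric(1))
  n_spacer <- length(units) + 1L
  remaining <- G - sum(unit_len)
  if (remaining < n_spacer * min_spacer)
    rs_abort(sprintf(paste0("genome too small for the requested features: ",
                            "%d bp of features + %d spacers of >= %d bp ",
                            "exceed %d bp"),
                     sum(unit_len), n_spacer, min_spacer, G),
             "infeasible_profile")
  # split the remaining background into spacers, each >= min_spacer
  extra <- remaining - n_spacer * min_spacer
  w <- runif(n_spacer)
  spacer_len <- min_spacer + floor(extra * w / sum(w))
  spacer_len[1] <- spacer_len[1] + (remaining - sum(spacer_len))

  # lay out the chromosome
  chrom <- "chr1"
  seqs <- character(0)
  pos <- 0L
  gene_rows <- list(); te_rows <- list(); truth_rows <- list()
  gene_start <- integer(n_genes)
  for (ui in seq_along(units)) {
    seqs <- c(seqs, random_dna(spacer_len[ui]))
    pos <- pos + spacer_len[ui]
    u <- units[[ui]]
    te_pos <- NULL
    for (b in u$blocks) {
      blen <- nchar(b$seq)
      if (b$kind == "gene") {
        gn <- genes[[b$gene]]
        gene_rows[[length(gene_rows) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + blen, strand = gn$strand,
          feature_id = gn$gene_id, feature_class = "gene",
          stringsAsFactors = FALSE)
        gene_start[b$gene] <- pos
      } else if (b$kind == "te") {
        te_pos <- c(pos, pos + blen)
        cp <- copies[[b$copy]]
        te_id <- sprintf("%s_te%04d", sp, b$copy)
        ltr_len <- cp$ltr_len
        # LTR coordinates on the genome; for "-" strand copies the 5' LTR
        # (in element orientation) is the rightmost interval
        if (cp$strand == "+") {
          ltr5 <- c(pos, pos + ltr_len)
          ltr3 <- c(pos + blen - ltr_len, pos + blen)
        } else {
          ltr5 <- c(pos + blen - ltr_len, pos + blen)
          ltr3 <- c(pos, pos + ltr_len)
        }
        te_rows[[length(te_rows) + 1L]] <- data.frame(
          chrom = chrom, start = pos, end = pos + blen, strand = cp$strand,
          feature_id = te_id,
          feature_class = paste0("TE:", cp$superfamily),
          stringsAsFactors = FALSE)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          family = cp$family, superfamily = cp$superfamily,
          species_code = sp, chrom = chrom,
          start = pos, end = pos + blen, strand = cp$strand,
          age_my = cp$age_my,
          ltr5_start = ltr5[1], ltr5_end = ltr5[2],
          ltr3_start = ltr3[1], ltr3_end = ltr3[2],
          te_id = te_id,
          nearest_gene = NA_character_,
          upstream_distance_bp = NA_integer_,
          stringsAsFactors = FALSE)
      }
      seqs <- c(seqs, b$seq)
      pos <- pos + blen
    }
    if (!is.null(u$gene) && !is.null(u$copy)) {
      k <- length(truth_rows)
      truth_rows[[k]]$nearest_gene <- genes[[u$gene]]$gene_id
      truth_rows[[k]]$upstream_distance_bp <- u$dist
    }
  }
  seqs <- c(seqs, random_dna(spacer_len[n_spacer]))
  genome <- paste(seqs, collapse = "")
  names(genome) <- chrom
  stopifnot(nchar(genome) == G)

  truth <- do.call(rbind, truth_rows)
  realized <- tapply(truth$end - truth$start, truth$family, sum) / 1e6
  # sanity: realized occupancy must be within 5% of the requested target
  for (fam in profile$families) {
    got <- realized[[fam$name]] %||% 0
    if (fam$target_mb > 0 && abs(got - fam$target_mb) / fam$target_mb > 0.05)
      warning(sprintf("family %s realized %.4f Mb vs target %.4f Mb",
                      fam$name, got, fam$target_mb))
  }
  structure(list(genome = genome,
                 genes = do.call(rbind, gene_rows),
                 tes = do.call(rbind, te_rows),
                 truth = truth,
                 realized_mb = as.list(realized),
                 profile = profile,
                 clock = clock),
            class = "rs_genome_sim")
}

#' Simulate shotgun reads from a genome
#'
#' Uniform start positions, random strand, per-base substitution errors.
#' The total read count is `round(coverage * genome_length / read_len)`;
#' in paired mode each fragment contributes two reads.
#'
#' @param genome Named character vector of chromosome sequences (as in
#'   `rs_genome_sim$genome`), a `DNAStringSet`, or a FASTA path.
#' @param coverage Sequencing depth in read-bases per genome base (> 0).
#' @param read_len Read length (>= 50 nt).
#' @param species_code Species tag stamped into read names.
#' @param paired Generate read pairs instead of single-end reads.
#' @param insert_size Mean outer fragment length for paired mode.
#' @param insert_sd Standard deviation of the fragment length.
#' @param error_rate Per-base substitution error probability.
#' @param seed Integer seed.
#' @return Single-end: a reads data frame (`read_id`, `species_code`,
#'   `seq`).  Paired: a list with data frames `mate1` and `mate2`, mate
#'   names carrying `/1` and `/2` suffixes.
#' @export
simulate_reads <- function(genome, coverage, read_len, species_code,
                           paired = FALSE, insert_size = 500,
                           insert_sd = 25, error_rate = 0, seed = 1) {
  genome <- load_genome(genome)
  if (coverage <= 0) rs_abort("coverage must be > 0", "invalid_argument")
  if (read_len < 50) rs_abort("read_len must be >= 50", "invalid_argument")
  glen <- nchar(genome)
  if (any(read_len > glen))
    rs_abort("read_len exceeds genome length", "invalid_argument")
  set.seed(seed)
  G <- sum(glen)
  n_reads <- round(coverage * G / read_len)
  # chromosome chosen proportionally to length
  if (!paired) {
    chrom_idx <- sample.int(length(genome), n_reads, replace = TRUE,
                            prob = glen / G)
    starts <- floor(runif(n_reads) * (glen[chrom_idx] - read_len + 1)) + 1
    seqs <- substring(genome[chrom_idx], starts, starts + read_len - 1)
    flip <- runif(n_reads) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    seqs <- apply_seq_error(seqs, error_rate)
    as_reads_df(sprintf("%s_r%06d", species_code, seq_len(n_reads)),
                species_code, seqs)
  } else {
    n_pairs <- max(1L, round(n_reads / 2))
    if (insert_size < 2 * read_len)
      rs_abort("insert_size must be >= 2 * read_len", "invalid_argument")
    chrom_idx <- sample.int(length(genome), n_pairs, replace = TRUE,
                            prob = glen / G)
    ins <- pmax(2 * read_len, round(rnorm(n_pairs, insert_size, insert_sd)))
    ins <- pmin(ins, glen[chrom_idx])
    starts <- floor(runif(n_pairs) * (glen[chrom_idx] - ins + 1)) + 1
    fwd1 <- substring(genome[chrom_idx], starts, starts + read_len - 1)
    fwd2 <- substring(genome[chrom_idx], starts + ins - read_len,
                      starts + ins - 1)
    m2 <- revcomp(fwd2)
    # fragments come from either strand: swap mate roles for half
    flip <- runif(n_pairs) < 0.5
    mate1 <- ifelse(flip, revcomp(fwd2), fwd1)
    mate2 <- ifelse(flip, revcomp(fwd1), m2)
    mate1 <- apply_seq_error(mate1, error_rate)
    mate2 <- apply_seq_error(mate2, error_rate)
    ids <- sprintf("%s_p%06d", species_code, seq_len(n_pairs))
    list(mate1 = as_reads_df(paste0(ids, "/1"), species_code, mate1),
         mate2 = as_reads_df(paste0(ids, "/2"), species_code, mate2))
  }
}

#' Simulate a gene-to-term annotation table
#'
#' Random flat term assignments over a gene universe, optionally seeding
#' one or more terms with a supplied gene set so that enrichment is planted
#' by construction.
#'
#' @param gene_ids Character vector: the gene universe.
#' @param n_terms Number of terms.
#' @param seed Integer seed.
#' @param genes_per_term Expected genes per random term.
#' @param enriched_genes Optional character vector of genes to concentrate
#'   into the first term.
#' @return Data frame with columns `term_id`, `term_name`, `gene_id`.
#' @export
simulate_term_mapping <- function(gene_ids, n_terms, seed,
                                  genes_per_term = 10,
                                  enriched_genes = NULL) {
  set.seed(seed)
  rows <- list()
  for (t in seq_len(n_terms)) {
    term <- sprintf("T%04d", t)
    n <- max(2L, rbinom(1, length(gene_ids), genes_per_term / length(gene_ids)))
    gset <- sample(gene_ids, min(n, length(gene_ids)))
    if (t == 1 && !is.null(enriched_genes)) {
      gset <- unique(c(enriched_genes, sample(gene_ids, 2)))
    }
    rows[[t]] <- data.frame(term_id = term,
                            term_name = paste0("process ", term),
                            gene_id = gset, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
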