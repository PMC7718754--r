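# End-to-end orchestration: simulate -> cluster -> annotate -> quantify ->
# date -> proximity -> enrich, as a configured, logged, resumable run.
# Each stage writes plain-text outputs (TSV/JSON/FASTA/FASTQ/GFF3) plus a
# manifest entry with output checksums, and caches its in-memory state
# under <outdir>/state/ so later stages can rerun without recomputing
# upstream ones.  Outputs carry no timestamps, so a rerun with the same
# config and seed is byte-identical.

PIPELINE_STAGES <- c("simulate", "cluster", "annotate", "quantify",
                     "date", "proximity", "enrich")

CONFIG_KEYS <- c("species", "families", "cluster", "clock", "map", "sim",
                 "proximity", "enrich")

#' Demo run configuration
#'
#' Three synthetic species sharing two repeat families (one gypsy, one
#' copia) and each carrying one private family — the smallest design that
#' exercises comparative clustering, abundance recovery, cluster dating
#' and the sharing matrix.  Genomes are 0.7 Mb and repeat-rich (60% of
#' the genome in the planted families, echoing the repeat content of
#' grass genomes) with 20 genes each; single-species read sets are 0.5x
#' coverage of 100 nt reads, and the comparative stage subsamples 1500
#' reads per species.
#'
#' @return A config list accepted by [run_pipeline()].
#' @export
demo_config <- function() {
  shared <- list(
    list(name = "SHG1", superfamily = "gypsy", target_mb = 0.15,
         age_my = 1.0, age_sd_my = 0.1, species = c("Aa", "Bb", "Cc")),
    list(name = "SHC2", superfamily = "copia", target_mb = 0.15,
         age_my = 2.0, age_sd_my = 0.2, species = c("Aa", "Bb", "Cc")))
  private <- list(
    list(name = "PRA1", superfamily = "copia", target_mb = 0.12,
         age_my = 1.5, age_sd_my = 0.15, species = "Aa"),
    list(name = "PRB1", superfamily = "gypsy", target_mb = 0.12,
         age_my = 1.5, age_sd_my = 0.15, species = "Bb"),
    list(name = "PRC1", superfamily = "gypsy", target_mb = 0.12,
         age_my = 0.8, age_sd_my = 0.1, species = "Cc"))
  # sparse genome for gene-proximity work: large spacers keep TE-free
  # genes truly isolated, and upstream distances stay within mate-pair
  # reach of the insert size
  prox_fams <- list(
    list(name = "PDG1", superfamily = "gypsy", target_mb = 0.04,
         age_my = 1.0, age_sd_my = 0.1, species = "Dd"),
    list(name = "PDC2", superfamily = "copia", target_mb = 0.04,
         age_my = 1.0, age_sd_my = 0.1, species = "Dd"))
  list(
    species = list(
      list(species_code = "Aa", genome_size_mb = 0.7, gene_count = 20),
      list(species_code = "Bb", genome_size_mb = 0.7, gene_count = 20),
      list(species_code = "Cc", genome_size_mb = 0.7, gene_count = 20),
      list(species_code = "Dd", genome_size_mb = 0.7, gene_count = 25,
           comparative = FALSE, min_spacer = 6000,
           adjacent_fraction = 0.3, upstream_range = c(1, 300))),
    families = c(shared, private, prox_fams),
    sim = list(read_len = 100, coverage = 0.5, error_rate = 0.001,
               adjacent_fraction = 0.2, upstream_range = c(1, 5000),
               min_spacer = 400, ltr_len = 300, internal_len = 800),
    cluster = list(min_identity = 0.90, min_overlap_fraction = 0.55,
                   significant_fraction = 0.005, per_species_sample = 1500),
    clock = list(rate_per_site_per_year = 1.3e-8,
                 divergence_mode = "consensus"),
    map = list(),
    proximity = list(species = "Dd", coverage = 2.0, read_len = 100,
                     insert_size = 800, insert_sd = 25),
    enrich = list(n_terms = 30, min_term = 5))
}

#' Validate a run configuration
#'
#' Collects every problem before reporting, rather than failing at the
#' first; unknown top-level keys are rejected.
#'
#' @param config A config list (as from [demo_config()]) or a YAML path.
#' @return The config, invisibly, when valid; otherwise an error listing
#'   all problems.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      rs_abort(sprintf("config file '%s' not found", config), "io_error")
    config <- yaml::read_yaml(config)
  }
  errs <- character(0)
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    errs <- c(errs, paste0("unknown config keys: ",
                           paste(unknown, collapse = ", ")))
  if (is.null(config$species) || length(config$species) == 0) {
    errs <- c(errs, "species: at least one species is required")
  } else {
    codes <- vapply(config$species, function(s)
      as.character(s$species_code %||% NA), character(1))
    if (anyNA(codes)) errs <- c(errs, "species: species_code is required")
    dup <- unique(codes[duplicated(codes)])
    if (length(dup))
      errs <- c(errs, paste0("species: duplicate species_code: ",
                             paste(dup, collapse = ", ")))
    for (s in config$species) {
      g <- s$genome_size_mb %||% NA
      if (!is.numeric(g) || is.na(g) || g <= 0)
        errs <- c(errs, sprintf("species %s: genome_size_mb must be > 0",
                                s$species_code %||% "?"))
    }
  }
  if (is.null(config$families) || length(config$families) == 0) {
    errs <- c(errs, "families: at least one family is required")
  } else {
    for (f in config$families) {
      if (is.null(f$name)) errs <- c(errs, "families: name is required")
      if (!is.null(f$target_mb) && f$target_mb < 0)
        errs <- c(errs, sprintf("family %s: target_mb must be >= 0",
                                f$name %||% "?"))
      if (!is.null(f$age_my) && f$age_my < 0)
        errs <- c(errs, sprintf("family %s: age_my must be >= 0",
                                f$name %||% "?"))
      if (!is.null(f$superfamily) && !f$superfamily %in% SUPERFAMILIES)
        errs <- c(errs, sprintf("family %s: unknown superfamily '%s'",
                                f$name %||% "?", f$superfamily))
    }
  }
  rate <- config$clock$rate_per_site_per_year %||% 1.3e-8
  if (!is.numeric(rate) || rate <= 0)
    errs <- c(errs, "clock: rate_per_site_per_year must be > 0")
  if (length(errs))
    rs_abort(paste0("invalid config:\n  - ",
                    paste(errs, collapse = "\n  - ")), "invalid_config")
  invisible(config)
}

# Build the family library (with sequences) deterministically from the
# config and seed.
config_families <- function(config, seed) {
  set.seed(derive_seed(seed, 1L))
  ltr_len <- config$sim$ltr_len %||% 450
  int_len <- config$sim$internal_len %||% 1500
  fams <- lapply(config$families, function(f) {
    fam <- te_family(name = f$name, superfamily = f$superfamily %||% "other",
                     ltr_seq = random_dna(ltr_len),
                     internal_seq = random_dna(int_len),
                     target_mb = f$target_mb %||% 0.05,
                     age_my = f$age_my %||% 1,
                     age_sd_my = f$age_sd_my %||% 0)
    fam$species <- f$species %||% vapply(config$species, function(s)
      s$species_code, character(1))
    fam
  })
  names(fams) <- vapply(fams, function(f) f$name, character(1))
  fams
}

# Exemplar library data frame from the family specs: one full-element
# record and one LTR record per family, RepeatMasker-style headers.
families_to_library <- function(fams) {
  recs <- character(0)
  for (f in fams) {
    cls <- switch(f$superfamily, gypsy = "LTR/Gypsy", copia = "LTR/Copia",
                  DNA = "DNA", satellite = "Satellite", "Unknown")
    recs[paste0(f$name, "#", cls)] <- family_consensus(f)
    recs[paste0(f$name, "_LTR#", cls)] <- f$ltr_seq
  }
  read_repeat_library(recs)
}

state_path <- function(outdir, stage) file.path(outdir, "state",
                                                paste0(stage, ".rds"))

load_stage_state <- function(outdir, stage) {
  p <- state_path(outdir, stage)
  if (!file.exists(p))
    rs_abort(sprintf("missing output of stage '%s'; run it first", stage),
             "missing_stage")
  readRDS(p)
}

log_msg <- function(log_con, ...) {
  msg <- sprintf(...)
  message(msg)
  if (!is.null(log_con)) writeLines(msg, log_con)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order.  Stages not
#' requested must already have cached state under `outdir` (from an
#' earlier run); otherwise an error names the stage to run.  All outputs
#' are deterministic per (config, seed).
#'
#' @param config Config list (see [demo_config()]) or YAML path.
#' @param outdir Output directory (created if needed).
#' @param seed Integer master seed; every stage derives its own stream.
#' @param stages Subset of
#'   `c("simulate", "cluster", "annotate", "quantify", "date", "proximity",
#'   "enrich")`.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, outdir, seed = 1,
                         stages = PIPELINE_STAGES) {
  config <- validate_config(config)
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(file.path(outdir, "state"), recursive = TRUE,
             showWarnings = FALSE)
  log_con <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  manifest <- list(seed = seed, stages = list())
  out_files <- function(stage, files) {
    sums <- tools::md5sum(files)
    manifest$stages[[stage]] <<- list(
      outputs = lapply(seq_along(files), function(i)
        list(path = basename(files[i]), md5 = unname(sums[i]))))
  }
  species_codes <- vapply(config$species, function(s) s$species_code,
                          character(1))
  comparative_codes <- species_codes[vapply(config$species, function(s)
    isTRUE(s$comparative %||% TRUE), logical(1))]

  if ("simulate" %in% stages) {
    log_msg(log_con, "[simulate] %d species", length(species_codes))
    fams <- config_families(config, seed)
    clock <- clock_model(config$clock$rate_per_site_per_year %||% 1.3e-8,
                         config$clock$divergence_mode %||% "consensus")
    sims <- list(); reads <- list(); pairs <- list()
    files <- character(0)
    for (si in seq_along(config$species)) {
      sp <- config$species[[si]]
      code <- sp$species_code
      sp_fams <- Filter(function(f) code %in% f$species, fams)
      prof <- species_profile(code, sp$genome_size_mb, unname(sp_fams),
                              gene_count = sp$gene_count %||% 20)
      sim <- simulate_genome(prof, clock, derive_seed(seed, 10L + si),
                             adjacent_fraction = sp$adjacent_fraction %||%
                               config$sim$adjacent_fraction %||% 0.2,
                             upstream_range = unlist(sp$upstream_range) %||%
                               unlist(config$sim$upstream_range) %||%
                               c(1, 5000),
                             min_spacer = sp$min_spacer %||%
                               config$sim$min_spacer %||% 6000)
      rd <- simulate_reads(sim$genome,
                           coverage = config$sim$coverage %||% 0.5,
                           read_len = config$sim$read_len %||% 100,
                           species_code = code,
                           error_rate = config$sim$error_rate %||% 0,
                           seed = derive_seed(seed, 20L + si))
      sims[[code]] <- sim; reads[[code]] <- rd
      f1 <- file.path(outdir, paste0(code, "_genome.fasta"))
      f2 <- file.path(outdir, paste0(code, "_annotation.gff3"))
      f3 <- file.path(outdir, paste0(code, "_truth.tsv"))
      f4 <- file.path(outdir, paste0(code, "_reads.fastq"))
      write_fasta(sim$genome, f1)
      write_gff3(rbind(sim$genes, sim$tes), f2, truth = sim$truth)
      write_truth(sim, f3)
      write_fastq(rd, f4)
      files <- c(files, f1, f2, f3, f4)
    }
    prox_sp <- config$proximity$species %||% species_codes[1]
    pr <- simulate_reads(sims[[prox_sp]]$genome,
                         coverage = config$proximity$coverage %||% 1,
                         read_len = config$proximity$read_len %||% 100,
                         species_code = prox_sp, paired = TRUE,
                         insert_size = config$proximity$insert_size %||% 600,
                         insert_sd = config$proximity$insert_sd %||% 20,
                         error_rate = config$sim$error_rate %||% 0,
                         seed = derive_seed(seed, 30L))
    p1 <- file.path(outdir, paste0(prox_sp, "_pairs_1.fastq"))
    p2 <- file.path(outdir, paste0(prox_sp, "_pairs_2.fastq"))
    write_fastq(pr$mate1, p1); write_fastq(pr$mate2, p2)
    files <- c(files, p1, p2)
    saveRDS(list(sims = sims, reads = reads, pairs = pr,
                 prox_species = prox_sp, fams = fams, clock = clock),
            state_path(outdir, "simulate"))
    out_files("simulate", files)
  }

  if ("cluster" %in% stages) {
    st <- load_stage_state(outdir, "simulate")
    params <- do.call(cluster_params, config$cluster[
      intersect(names(config$cluster), names(formals(cluster_params)))])
    single <- list()
    files <- character(0)
    for (code in species_codes) {
      log_msg(log_con, "[cluster] single-species: %s (%d reads)", code,
              nrow(st$reads[[code]]))
      single[[code]] <- build_clusters(st$reads[[code]], params)
      f <- file.path(outdir, paste0(code, "_clusters.tsv"))
      write_tsv(cluster_summary(single[[code]], include_remainder = TRUE), f)
      fm <- file.path(outdir, paste0(code, "_membership.tsv"))
      write_tsv(cluster_membership(single[[code]]), fm)
      files <- c(files, f, fm)
    }
    pooled_reads <- pool_species(st$reads[comparative_codes],
                                 config$cluster$per_species_sample %||% 600,
                                 derive_seed(seed, 40L))
    log_msg(log_con, "[cluster] pooled comparative: %d reads",
            nrow(pooled_reads))
    pooled <- build_clusters(pooled_reads, params)
    fp <- file.path(outdir, "pooled_clusters.tsv")
    write_tsv(cluster_summary(pooled, include_remainder = TRUE), fp)
    fe <- file.path(outdir, "pooled_edges.tsv")
    write_tsv(pooled$edges, fe)
    files <- c(files, fp, fe)
    saveRDS(list(single = single, pooled = pooled),
            state_path(outdir, "cluster"))
    out_files("cluster", files)
  }

  if ("annotate" %in% stages) {
    st <- load_stage_state(outdir, "simulate")
    cl <- load_stage_state(outdir, "cluster")
    lib <- families_to_library(st$fams)
    log_msg(log_con, "[annotate] %d library records", nrow(lib))
    cl$single <- lapply(cl$single, annotate_clustering, library = lib)
    cl$pooled <- annotate_clustering(cl$pooled, library = lib)
    rows <- list()
    for (code in names(cl$single)) {
      s <- cluster_summary(cl$single[[code]])
      s$mode <- "single"; s$run <- code
      rows[[code]] <- s[, c("run", "mode", "cluster_id", "size",
                            "annotation", "superfamily")]
    }
    sp <- cluster_summary(cl$pooled)
    sp$mode <- "comparative"; sp$run <- "pooled"
    rows$pooled <- sp[, c("run", "mode", "cluster_id", "size",
                          "annotation", "superfamily")]
    f <- file.path(outdir, "cluster_annotation.tsv")
    write_tsv(do.call(rbind, rows), f)
    saveRDS(cl, state_path(outdir, "annotate"))
    out_files("annotate", f)
  }

  if ("quantify" %in% stages) {
    st <- load_stage_state(outdir, "simulate")
    cl <- load_stage_state(outdir, "annotate")
    inputs <- data.frame(
      species_code = species_codes,
      genome_size_mb = vapply(config$species, function(s)
        s$genome_size_mb, numeric(1)))
    rows <- list(); props <- list()
    for (code in species_codes) {
      comp <- composition_table(cl$single[[code]],
                                inputs[inputs$species_code == code, ])
      rows[[code]] <- comp
      props[[code]] <- attr(comp, "genome_proportion")[[code]]
    }
    comp_all <- do.call(rbind, rows)
    rownames(comp_all) <- NULL
    f1 <- file.path(outdir, "composition.tsv")
    write_tsv(comp_all, f1)
    f2 <- file.path(outdir, "genome_proportion.tsv")
    write_tsv(data.frame(species_code = names(props),
                         genome_proportion = round(unlist(props), 6)), f2)
    sharing <- sharing_matrix(cl$pooled)
    f3 <- file.path(outdir, "sharing_matrix.tsv")
    write_tsv(sharing, f3)
    f4 <- file.path(outdir, "quantify_summary.json")
    jsonlite::write_json(list(
      composition = comp_all, genome_proportion = props,
      sharing = sharing), f4, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    saveRDS(list(composition = comp_all, sharing = sharing,
                 genome_proportion = props),
            state_path(outdir, "quantify"))
    out_files("quantify", c(f1, f2, f3, f4))
  }

  if ("date" %in% stages) {
    st <- load_stage_state(outdir, "simulate")
    cl <- load_stage_state(outdir, "annotate")
    lib <- families_to_library(st$fams)
    ltr_db <- lib[lib$is_ltr_exemplar, , drop = FALSE]
    min_reads <- 15
    estimates <- list(); contigs <- list()
    for (code in species_codes) {
      clustering <- cl$single[[code]]
      for (cluster in clustering$clusters) {
        sf <- cluster$superfamily %||% NA_character_
        if (is.na(sf) || !sf %in% c("gypsy", "copia")) next
        cnt <- cluster$species_counts[code]
        if (is.na(cnt) || cnt < min_reads) next
        log_msg(log_con, "[date] %s %s (%s)", code, cluster$cluster_id,
                cluster$annotation %||% "unclassified")
        cons <- tryCatch(build_consensus(cluster, clustering$reads, code),
                         repeatscape_error = function(e) NULL)
        est <- date_cluster(cluster, clustering$reads, code, ltr_db,
                            clock_model(st$clock$rate_per_site_per_year,
                                        config$clock$divergence_mode %||%
                                          "consensus"),
                            error_rate = config$sim$error_rate %||% 0,
                            consensus = cons)
        est$annotation <- cluster$annotation
        estimates[[length(estimates) + 1L]] <- est
        if (!is.null(cons)) {
          key <- paste0(code, ":", cluster$cluster_id)
          cls <- paste0("TE:", cluster$superfamily)
          contigs[[paste0(key, "#", cls)]] <- cons$seq
        }
      }
    }
    tl <- activity_timeline(estimates)
    tl$annotation <- vapply(estimates, function(e)
      e$annotation %||% NA_character_, character(1))
    f1 <- file.path(outdir, "age_table.tsv")
    write_tsv(tl, f1)
    f2 <- file.path(outdir, "timeline.json")
    jsonlite::write_json(tl, f2, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    saveRDS(list(timeline = tl, contigs = unlist(contigs)),
            state_path(outdir, "date"))
    out_files("date", c(f1, f2))
  }

  if ("proximity" %in% stages) {
    st <- load_stage_state(outdir, "simulate")
    dt <- load_stage_state(outdir, "date")
    files <- character(0)
    ref_rows <- list()
    for (code in species_codes) {
      sim <- st$sims[[code]]
      hits <- upstream_hits(sim$genes, sim$tes)
      hits$species_code <- code
      ref_rows[[code]] <- hits
    }
    ref <- do.call(rbind, ref_rows)
    rownames(ref) <- NULL
    f1 <- file.path(outdir, "upstream_hits.tsv")
    write_tsv(ref, f1)
    files <- f1
    # read-pair mode on the designated species
    code <- st$prox_species
    sim <- st$sims[[code]]
    gseq <- substring(sim$genome[sim$genes$chrom],
                      sim$genes$start + 1L, sim$genes$end)
    names(gseq) <- sim$genes$feature_id
    te_contigs <- dt$contigs[grepl(paste0("^", code, ":"),
                                   names(dt$contigs))]
    if (length(te_contigs) > 0) {
      log_msg(log_con, "[proximity] read-pair mode: %s (%d pairs)",
              code, nrow(st$pairs$mate1))
      kept <- prefilter_te_pairs(st$pairs, te_contigs)
      log_msg(log_con, "[proximity] %d pairs after TE prefilter",
              nrow(kept$mate1))
      rp <- classify_pairs(kept, te_contigs, gseq,
                           do.call(map_params, config$map %||% list()))
      f2 <- file.path(outdir, "readpair_hits.tsv")
      write_tsv(rp$hits, f2)
      f3 <- file.path(outdir, "readpair_gene_counts.tsv")
      write_tsv(rp$gene_counts, f3)
      files <- c(files, f2, f3)
      saveRDS(list(reference = ref, readpair = rp),
              state_path(outdir, "proximity"))
    } else {
      saveRDS(list(reference = ref, readpair = NULL),
              state_path(outdir, "proximity"))
    }
    out_files("proximity", files)
  }

  if ("enrich" %in% stages) {
    st <- load_stage_state(outdir, "simulate")
    px <- load_stage_state(outdir, "proximity")
    code <- st$prox_species
    sim <- st$sims[[code]]
    background <- sim$genes$feature_id
    query <- unique(px$reference$gene_id[
      px$reference$species_code == code &
        px$reference$te_class %in% c("TE:gypsy", "TE:copia")])
    adj_genes <- sim$truth$nearest_gene[!is.na(sim$truth$nearest_gene)]
    set.seed(derive_seed(seed, 50L))
    terms <- simulate_term_mapping(background,
                                   config$enrich$n_terms %||% 30,
                                   derive_seed(seed, 51L),
                                   enriched_genes = adj_genes)
    res <- hypergeom_enrich(query, background, terms,
                            min_term = config$enrich$min_term %||% 5)
    f <- file.path(outdir, "enrichment.tsv")
    write_tsv(res, f)
    saveRDS(list(result = res, query = query, background = background),
            state_path(outdir, "enrich"))
    out_files("enrich", f)
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
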