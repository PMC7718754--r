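test_that("family library generation is seeded, unique and covers both
           LTR superfamilies", {
  lib1 <- simulate_family_library(4, seed = 1)
  lib2 <- simulate_family_library(4, seed = 1)
  expect_identical(lib1, lib2)
  nm <- vapply(lib1, function(f) f$name, character(1))
  expect_equal(anyDuplicated(nm), 0L)
  sf <- vapply(lib1, function(f) f$superfamily, character(1))
  expect_true("gypsy" %in% sf)
  expect_true("copia" %in% sf)
  one <- simulate_family_library(1, seed = 7)
  expect_length(one, 1)
  expect_identical(one, simulate_family_library(1, seed = 7))
  expect_error(simulate_family_library(0, seed = 1),
               class = "repeatscape_invalid_argument")
})

make_profile <- function(families, genome_mb = 0.3, species = "Zz",
                         genes = 5) {
  species_profile(species, genome_mb, families, gene_count = genes)
}

test_that("zero-age copies are identical to the consensus and LTR pairs
           are identical", {
  set.seed(1)
  f <- te_family("F1", "gypsy", rand_dna(150), rand_dna(600),
                 target_mb = 0.02, age_my = 0, age_sd_my = 0)
  sim <- simulate_genome(make_profile(list(f)), clock_model(), seed = 3,
                         min_spacer = 500)
  cons <- paste0(f$ltr_seq, f$internal_seq, f$ltr_seq)
  g <- unname(sim$genome)
  for (i in seq_len(nrow(sim$truth))) {
    s <- substr(g, sim$truth$start[i] + 1, sim$truth$end[i])
    if (sim$truth$strand[i] == "-") s <- rc(s)
    expect_identical(s, cons)
  }
  ltr5 <- substr(g, sim$truth$ltr5_start[1] + 1, sim$truth$ltr5_end[1])
  ltr3 <- substr(g, sim$truth$ltr3_start[1] + 1, sim$truth$ltr3_end[1])
  expect_identical(ltr5, ltr3)
})

test_that("planted decay matches the clock: copy divergence ~ r*t and
           LTR pair divergence ~ 2*r*t", {
  set.seed(2)
  f <- te_family("F1", "copia", rand_dna(200), rand_dna(600),
                 target_mb = 0.11, age_my = 1.0, age_sd_my = 0)
  sim <- simulate_genome(make_profile(list(f), genome_mb = 0.35, genes = 3),
                         clock_model(), seed = 5, min_spacer = 500)
  tr <- sim$truth
  expect_gte(nrow(tr), 100)
  cons <- paste0(f$ltr_seq, f$internal_seq, f$ltr_seq)
  g <- unname(sim$genome)
  div <- vapply(seq_len(nrow(tr)), function(i) {
    s <- substr(g, tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") s <- rc(s)
    mean(strsplit(s, "")[[1]] != strsplit(cons, "")[[1]])
  }, numeric(1))
  p <- 1.3e-8 * 1e6          # expected per-site divergence at 1 My
  n_sites <- nchar(cons) * nrow(tr)
  se <- sqrt(p * (1 - p) / n_sites)
  expect_lt(abs(mean(div) - p), 3 * se)
  # LTR-LTR divergence accrues on both copies: 2*r*t
  ltr_div <- vapply(seq_len(nrow(tr)), function(i) {
    a <- substr(g, tr$ltr5_start[i] + 1, tr$ltr5_end[i])
    b <- substr(g, tr$ltr3_start[i] + 1, tr$ltr3_end[i])
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, numeric(1))
  p2 <- 2 * p * (1 - p)  # both-mutated-to-same-base term is negligible
  se2 <- sqrt(p2 * (1 - p2) / (nchar(f$ltr_seq) * nrow(tr)))
  expect_lt(abs(mean(ltr_div) - p2), 4 * se2)
})

test_that("truth ledger conserves family occupancy exactly and realized
           Mb is within 5% of target", {
  set.seed(3)
  fams <- list(
    te_family("F1", "gypsy", rand_dna(150), rand_dna(700), 0.03, 1, 0.1),
    te_family("F2", "copia", rand_dna(180), rand_dna(600), 0.02, 2, 0.2))
  sim <- simulate_genome(make_profile(fams), clock_model(), seed = 8,
                         min_spacer = 500)
  by_fam <- tapply(sim$truth$end - sim$truth$start, sim$truth$family, sum)
  for (f in fams) {
    expect_identical(unname(by_fam[[f$name]]) / 1e6,
                     sim$realized_mb[[f$name]])
    expect_lt(abs(sim$realized_mb[[f$name]] - f$target_mb) / f$target_mb,
              0.05)
  }
  # all TE intervals are inside the genome and LTRs nested in the element
  tr <- sim$truth
  expect_true(all(tr$start < tr$end))
  expect_true(all(tr$end <= nchar(sim$genome)))
  expect_true(all(tr$ltr5_start >= tr$start & tr$ltr5_end <= tr$end))
})

test_that("infeasible profiles are rejected", {
  set.seed(4)
  f <- te_family("F1", "gypsy", rand_dna(150), rand_dna(700),
                 target_mb = 2, age_my = 1)
  expect_error(
    simulate_genome(make_profile(list(f), genome_mb = 0.5), clock_model(),
                    seed = 1),
    class = "repeatscape_infeasible_profile")
})

test_that("decay calibration: divergence regressed on planted age
           recovers the substitution rate within 10%", {
  set.seed(5)
  f <- te_family("F1", "gypsy", rand_dna(120), rand_dna(500),
                 target_mb = 0.4, age_my = 3, age_sd_my = 1.5)
  sim <- simulate_genome(
    species_profile("Zz", 1.0, list(f), gene_count = 2),
    clock_model(), seed = 11, min_spacer = 400)
  tr <- sim$truth
  expect_gte(nrow(tr), 500)
  cons <- paste0(f$ltr_seq, f$internal_seq, f$ltr_seq)
  g <- unname(sim$genome)
  div <- vapply(seq_len(nrow(tr)), function(i) {
    s <- substr(g, tr$start[i] + 1, tr$end[i])
    if (tr$strand[i] == "-") s <- rc(s)
    mean(strsplit(s, "")[[1]] != strsplit(cons, "")[[1]])
  }, numeric(1))
  fit <- stats::lm(div ~ tr$age_my)
  r_hat <- unname(stats::coef(fit)[2]) / 1e6
  expect_lt(abs(r_hat - 1.3e-8) / 1.3e-8, 0.10)
})

test_that("read simulation: count arithmetic, exact substrings at zero
           error, and determinism", {
  set.seed(6)
  genome <- c(chr1 = rand_dna(100000))
  rd <- simulate_reads(genome, coverage = 0.5, read_len = 100,
                       species_code = "Zz", seed = 2)
  expect_equal(nrow(rd), round(0.5 * 100000 / 100))
  # zero error: every read is a substring of the genome (either strand)
  rd2 <- simulate_reads(genome, coverage = 0.05, read_len = 60,
                        species_code = "Zz", seed = 3)
  both <- paste0(genome, "NNNN", rc(genome))
  expect_true(all(vapply(rd2$seq, function(s)
    grepl(s, both, fixed = TRUE), logical(1))))
  expect_identical(rd, simulate_reads(genome, coverage = 0.5,
                                      read_len = 100, species_code = "Zz",
                                      seed = 2))
  expect_error(simulate_reads(genome, 0.5, 30, "Zz"),
               class = "repeatscape_invalid_argument")
  expect_error(simulate_reads(c(chrA = rand_dna(80)), 1, 100, "Zz"),
               class = "repeatscape_invalid_argument")
})

test_that("paired reads have the requested fragment geometry (remap
           oracle) and mate naming", {
  set.seed(7)
  genome <- c(chr1 = rand_dna(60000))
  pr <- simulate_reads(genome, coverage = 0.2, read_len = 70,
                       species_code = "Zz", paired = TRUE,
                       insert_size = 400, insert_sd = 0, seed = 4)
  expect_equal(nrow(pr$mate1), nrow(pr$mate2))
  expect_true(all(grepl("/1$", pr$mate1$read_id)))
  expect_true(all(grepl("/2$", pr$mate2$read_id)))
  expect_identical(sub("/1$", "", pr$mate1$read_id),
                   sub("/2$", "", pr$mate2$read_id))
  # remap both mates to the known genome: outer distance equals the insert
  seps <- vapply(seq_len(nrow(pr$mate1)), function(i) {
    p1 <- regexpr(pr$mate1$seq[i], genome, fixed = TRUE)
    s1 <- if (p1 > 0) p1 else {
      regexpr(rc(pr$mate1$seq[i]), genome, fixed = TRUE)
    }
    p2 <- regexpr(pr$mate2$seq[i], genome, fixed = TRUE)
    s2 <- if (p2 > 0) p2 else {
      regexpr(rc(pr$mate2$seq[i]), genome, fixed = TRUE)
    }
    abs(as.integer(s2) - as.integer(s1)) + 70
  }, numeric(1))
  expect_true(all(seps == 400))
})

test_that("genome outputs are byte-identical across reruns with one
           seed", {
  set.seed(8)
  f <- te_family("F1", "gypsy", rand_dna(150), rand_dna(600), 0.02, 1, 0.1)
  write_out <- function(dir) {
    sim <- simulate_genome(make_profile(list(f)), clock_model(), seed = 9,
                           min_spacer = 500)
    rd <- simulate_reads(sim$genome, 0.1, 100, "Zz", seed = 10)
    dir.create(dir, showWarnings = FALSE)
    write_fasta(sim$genome, file.path(dir, "g.fasta"))
    write_gff3(rbind(sim$genes, sim$tes), file.path(dir, "a.gff3"),
               truth = sim$truth)
    write_truth(sim, file.path(dir, "t.tsv"))
    write_fastq(rd, file.path(dir, "r.fastq"))
    dir
  }
  d1 <- write_out(tempfile()); d2 <- write_out(tempfile())
  for (f in c("g.fasta", "a.gff3", "t.tsv", "r.fastq")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
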