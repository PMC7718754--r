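test_that("library headers parse RepeatMasker-style names and
           superfamilies", {
  set.seed(1)
  lib <- read_repeat_library(c("opie#LTR/Copia" = rand_dna(300),
                               "huck#LTR/Gypsy" = rand_dna(300),
                               "huck_LTR#LTR/Gypsy" = rand_dna(150),
                               "mudr#DNA/MULE" = rand_dna(200)))
  expect_equal(lib$name, c("opie", "huck", "huck_LTR", "mudr"))
  expect_equal(lib$superfamily, c("copia", "gypsy", "gypsy", "DNA"))
  expect_equal(lib$is_ltr_exemplar, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("cluster annotation: exact-substring reads label the cluster,
           random clusters stay unclassified, plurality wins", {
  set.seed(2)
  lib <- read_repeat_library(c("opie#LTR/Copia" = rand_dna(600),
                               "ji#LTR/Copia" = rand_dna(600),
                               "huck#LTR/Gypsy" = rand_dna(600)))
  sub_reads <- function(rec, n) vapply(seq_len(n), function(i) {
    s <- sample.int(500, 1); substr(lib$seq[lib$name == rec], s, s + 99)
  }, character(1))
  rd <- make_reads(sub_reads("opie", 10))
  cl <- list(cluster_id = "CL1", members = rd$read_id,
             species_counts = c(Xx = 10L))
  ann <- annotate_cluster(cl, rd, lib)
  expect_equal(ann$family, "opie")
  expect_equal(ann$superfamily, "copia")
  # random reads never reach 80% identity over 50 nt against the library
  rdr <- make_reads(replicate(12, rand_dna(100)))
  clr <- list(cluster_id = "CL2", members = rdr$read_id,
              species_counts = c(Xx = 12L))
  annr <- annotate_cluster(clr, rdr, lib)
  expect_true(is.na(annr$family))
  expect_true(is.na(annr$superfamily))
  # 60/40 mixture: plurality rules
  rdm <- make_reads(c(sub_reads("opie", 6), sub_reads("ji", 4)))
  clm <- list(cluster_id = "CL3", members = rdm$read_id,
              species_counts = c(Xx = 10L))
  expect_equal(annotate_cluster(clm, rdm, lib)$family, "opie")
  expect_error(annotate_cluster(clm, rdm, lib[0, ]),
               class = "repeatscape_invalid_argument")
})

test_that("superfamily-level plurality backs off before full
           unclassified", {
  set.seed(3)
  # two copia records; reads split 50/50 between them, plus noise, so no
  # single family reaches the vote fraction but the superfamily does
  lib <- read_repeat_library(c("opie#LTR/Copia" = rand_dna(600),
                               "ji#LTR/Copia" = rand_dna(600)))
  one <- substr(lib$seq[1], 1, 100)
  two <- substr(lib$seq[2], 1, 100)
  noise <- replicate(18, rand_dna(100))
  rd <- make_reads(c(one, two, noise))
  cl <- list(cluster_id = "CL1", members = rd$read_id,
             species_counts = c(Xx = 20L))
  ann <- annotate_cluster(cl, rd, lib, min_vote_fraction = 0.10)
  expect_true(is.na(ann$family))
  expect_equal(ann$superfamily, "copia")
})

test_that("greedy consensus reconstructs a tiled template exactly and
           corrects random read errors by majority vote", {
  set.seed(4)
  tpl <- rand_dna(500)
  starts <- seq(1, 401, by = 50)
  rd <- make_reads(substring(tpl, starts, starts + 99))
  cl <- list(cluster_id = "CL1", members = rd$read_id,
             species_counts = c(Xx = nrow(rd)))
  cons <- build_consensus(cl, rd, "Xx")
  expect_identical(cons$seq, tpl)
  expect_lte(nchar(cons$seq), sum(nchar(rd$seq)))
  # depth 10 with 1% errors: consensus within >= 99% of the template
  starts2 <- sample.int(401, 50, replace = TRUE)
  noisy <- vapply(starts2, function(s) {
    r <- substr(tpl, s, s + 99)
    nm <- rbinom(1, 100, 0.01)
    if (nm > 0) r <- mutate_at(r, sample.int(100, nm))
    r
  }, character(1))
  rd2 <- make_reads(noisy)
  cl2 <- list(cluster_id = "CL2", members = rd2$read_id,
              species_counts = c(Xx = nrow(rd2)))
  cons2 <- build_consensus(cl2, rd2, "Xx")
  o <- pwa_local(cons2$seq, tpl)
  expect_gte(o$matches / o$columns, 0.99)
  # fewer than three reads is an error
  cl3 <- list(cluster_id = "CL3", members = rd$read_id[1:2],
              species_counts = c(Xx = 2L))
  expect_error(build_consensus(cl3, rd, "Xx"),
               class = "repeatscape_insufficient_reads")
})

test_that("LTR extraction returns exact coordinates for planted
           exemplars, honors the best-hit rule, and rejects random
           contigs", {
  set.seed(5)
  ltr <- rand_dna(200)
  other <- rand_dna(120)
  contig <- list(cluster_id = "CL1", species_code = "Xx",
                 seq = paste0(rand_dna(150), ltr, rand_dna(250)))
  db <- read_repeat_library(c("fam_LTR#LTR/Gypsy" = ltr,
                              "short_LTR#LTR/Copia" = other))
  seg <- extract_ltr(contig, db)
  expect_s3_class(seg, "rs_ltr_segment")
  expect_equal(c(seg$start, seg$end), c(150, 350))
  expect_equal(seg$identity, 1.0)
  expect_equal(seg$library_hit, "fam_LTR")
  # extracted sequence equals the contig slice
  expect_identical(seg$seq, substr(contig$seq, seg$start + 1, seg$end))
  # random contig: no qualifying hit
  rnd <- list(cluster_id = "CL2", species_code = "Xx", seq = rand_dna(600))
  expect_null(extract_ltr(rnd, db))
  expect_error(extract_ltr(contig, db[0, ]),
               class = "repeatscape_invalid_argument")
})
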