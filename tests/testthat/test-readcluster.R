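test_that("align_pair: identity, strand symmetry and the 90% threshold
           around constructed substitutions", {
  set.seed(1)
  a <- rand_dna(100)
  e <- align_pair(a, a)
  expect_equal(e$identity, 1.0)
  expect_equal(e$overlap_fraction, 1.0)
  # reverse complement aligns perfectly
  e2 <- align_pair(a, rc(a))
  expect_equal(e2$identity, 1.0)
  # 8 evenly spaced substitutions: identity 0.92 -> edge
  b8 <- mutate_at(a, c(7, 19, 31, 43, 55, 67, 79, 91))
  e3 <- align_pair(a, b8)
  expect_equal(e3$identity, 0.92)
  # 12 substitutions: identity 0.88 -> no edge
  b12 <- mutate_at(a, seq(5, 93, by = 8))
  expect_null(align_pair(a, b12))
  # agreement with the plain-R alignment oracle
  o <- sw_oracle(a, b8)
  expect_equal(e3$identity, o$matches / o$columns)
  expect_equal(e3$overlap_fraction, o$columns / 100)
})

test_that("align_pair is symmetric in its arguments", {
  set.seed(2)
  for (i in 1:20) {
    a <- rand_dna(sample(60:120, 1))
    b <- if (runif(1) < 0.5) mutate_at(a, sample.int(nchar(a), 5))
         else rand_dna(sample(60:120, 1))
    eab <- align_pair(a, b); eba <- align_pair(b, a)
    expect_equal(is.null(eab), is.null(eba))
    if (!is.null(eab)) {
      expect_equal(eab$identity, eba$identity)
      expect_equal(eab$overlap_fraction, eba$overlap_fraction)
    }
  }
})

test_that("candidate prefilter: identical reads pair, disjoint reads do
           not, and the emitted set is a superset of true edges", {
  set.seed(3)
  a <- rand_dna(100)
  rd <- make_reads(c(a, a))
  cand <- candidate_pairs(rd, cluster_params(kmer_len = 17,
                                             min_shared_kmers = 1))
  expect_equal(nrow(cand), 1)
  # reads with no shared 17-mers are not emitted
  rd2 <- make_reads(c(rand_dna(100), rand_dna(100)))
  cand2 <- candidate_pairs(rd2, cluster_params(kmer_len = 17,
                                               min_shared_kmers = 1))
  expect_equal(nrow(cand2), 0)
  # superset property at defaults on 200 mixed reads
  reads <- planted_readset(n_per_family = 40, n_background = 120, seed = 4)
  cand3 <- candidate_pairs(reads)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  emitted <- key(match(cand3$a, reads$read_id),
                 match(cand3$b, reads$read_id))
  # reference route: align EVERY pair with no prefilter; the candidate
  # set must contain every pair that forms an edge
  ij <- t(utils::combn(nrow(reads), 2))
  edges <- repeatscape:::.rs_align_pairs_batch(reads$seq, ij[, 1], ij[, 2],
                                               0.90, 0.55, 1L, -1L, -2L)
  truth <- key(edges$i, edges$j)
  expect_gt(length(truth), 10)
  expect_true(all(truth %in% emitted))
})

test_that("build_clusters equals brute-force transitive closure on a
           constructed fixture and respects the partition property", {
  set.seed(5)
  elemA <- rand_dna(100); elemB <- rand_dna(100)
  seqs <- c(mutate_at(elemA, sample.int(100, 3)),
            mutate_at(elemA, sample.int(100, 4)),
            mutate_at(elemA, sample.int(100, 2)),
            mutate_at(elemB, sample.int(100, 3)),
            mutate_at(elemB, sample.int(100, 3)),
            rc(mutate_at(elemB, sample.int(100, 4))),
            replicate(4, rand_dna(100)))
  rd <- make_reads(seqs)
  cl <- build_clusters(rd, cluster_params(significant_fraction = 0))
  sizes <- sort(vapply(cl$clusters, function(x) length(x$members),
                       integer(1)), decreasing = TRUE)
  expect_equal(sizes, c(3L, 3L, 1L, 1L, 1L, 1L))
  expect_length(cl$remainder, 0)
  # members partition the input
  all_members <- unlist(lapply(cl$clusters, function(x) x$members))
  expect_setequal(all_members, rd$read_id)
  expect_equal(anyDuplicated(all_members), 0L)
  # numbering follows size
  expect_equal(cl$clusters[[1]]$cluster_id, "CL1")
  expect_length(cl$clusters[[1]]$members, 3)
})

test_that("clustering matches an independently aligned exhaustive
           oracle on a mixed read set", {
  reads <- planted_readset(n_per_family = 16, n_background = 24,
                           divergence = 0.03, seed = 6)
  n <- nrow(reads)
  cl <- build_clusters(reads, cluster_params(significant_fraction = 0))
  # oracle: align every pair, transitive closure
  ij <- t(utils::combn(n, 2))
  pass <- edge_oracle_batch(reads$seq, ij[, 1], ij[, 2])
  comp <- components_oracle(n, ij[pass, 1], ij[pass, 2])
  oracle_parts <- unname(split(reads$read_id, comp))
  got_parts <- lapply(cl$clusters, function(x) sort(x$members))
  expect_setequal(lapply(oracle_parts, sort), got_parts)
})

test_that("all reads identical collapse to one cluster and species
           bookkeeping is conserved in pooled mode", {
  set.seed(7)
  a <- rand_dna(100)
  rd <- rbind(make_reads(rep(a, 5), species = "Aa"),
              make_reads(rep(a, 3), species = "Bb"))
  cl <- build_clusters(rd, cluster_params(significant_fraction = 0))
  expect_length(cl$clusters, 1)
  expect_equal(sort(unname(cl$clusters[[1]]$species_counts)), c(3L, 5L))
  expect_equal(sum(cl$clusters[[1]]$species_counts),
               length(cl$clusters[[1]]$members))
})

test_that("reads with more than 10% N are dropped and N never matches", {
  set.seed(8)
  a <- rand_dna(100)
  noisy <- paste0(strrep("N", 15), substr(a, 16, 100))
  rd <- make_reads(c(a, a, noisy))
  expect_message(cl <- build_clusters(rd,
                                      cluster_params(significant_fraction = 0)),
                 "dropping 1")
  expect_equal(cl$n_dropped, 1L)
  expect_equal(sum(vapply(cl$clusters, function(x) length(x$members),
                          integer(1))), 2L)
  # N-vs-N columns are not matches
  n100 <- strrep("N", 100)
  expect_null(align_pair(n100, n100))
})

test_that("pool_species subsamples per species deterministically, clamps
           and reports empty readsets", {
  set.seed(9)
  rs <- list(Aa = make_reads(replicate(100, rand_dna(60)), "Aa"),
             Bb = make_reads(replicate(100, rand_dna(60)), "Bb"))
  pooled <- pool_species(rs, 50, seed = 1)
  expect_equal(nrow(pooled), 100)
  expect_equal(unname(table(pooled$species_code)[c("Aa", "Bb")]),
               array(c(50L, 50L)))
  expect_identical(pooled, pool_species(rs, 50, seed = 1))
  ws <- capture_warnings(big <- pool_species(rs, 150, seed = 1))
  expect_match(ws, "only 100", all = TRUE)
  expect_equal(nrow(big), 200)
  rs$Cc <- rs$Aa[0, ]
  expect_error(pool_species(rs, 10, seed = 1),
               class = "repeatscape_empty_readset")
  expect_error(suppressWarnings(pool_species(rs["Aa"], 0, seed = 1)),
               class = "repeatscape_invalid_argument")
})
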