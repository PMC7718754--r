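test_that("upstream hits: strand-aware distances and kb bins on
           constructed intervals", {
  genes <- data.frame(chrom = "chr1", start = c(10000, 30000),
                      end = c(12000, 32000), strand = c("+", "-"),
                      feature_id = c("g1", "g2"), feature_class = "gene",
                      stringsAsFactors = FALSE)
  tes <- data.frame(chrom = "chr1",
                    start = c(9400, 32300, 11000, 2000),
                    end = c(9500, 32400, 11100, 2100),
                    strand = "+",
                    feature_id = c("t1", "t2", "t3", "t4"),
                    feature_class = "TE:gypsy", stringsAsFactors = FALSE)
  hits <- upstream_hits(genes, tes)
  # + strand: TE [9400,9500) sits 500 bp upstream of gene start 10000
  h1 <- hits[hits$te_id == "t1", ]
  expect_equal(h1$gene_id, "g1")
  expect_equal(h1$distance_bp, 500L)
  expect_equal(h1$bin_kb, 1L)
  # - strand mirror: TE [32300,32400) is 300 bp upstream of gene end 32000
  h2 <- hits[hits$te_id == "t2", ]
  expect_equal(h2$gene_id, "g2")
  expect_equal(h2$distance_bp, 300L)
  expect_equal(h2$bin_kb, 1L)
  # t3 overlaps the gene body (distance < 1) and t4 is out of range
  expect_false("t3" %in% hits$te_id)
  expect_false("t4" %in% hits$te_id)
  bad <- genes; bad$strand[1] <- "*"
  expect_error(upstream_hits(bad, tes), "g1")
})

test_that("upstream hits equal the brute-force all-pairs scan on random
           fixtures", {
  set.seed(21)
  for (rep in 1:25) {
    fx <- random_intervals(sample(20:60, 1), sample(40:120, 1))
    got <- upstream_hits(fx$genes, fx$tes)
    want <- upstream_oracle(fx$genes, fx$tes)
    expect_equal(got[, c("gene_id", "te_id", "distance_bp", "bin_kb")],
                 want, ignore_attr = TRUE)
  }
})

test_that("reflecting coordinates and flipping strands preserves the
           hit multiset", {
  set.seed(22)
  fx <- random_intervals(30, 60, glen = 50000)
  L <- 50000
  reflect <- function(df) {
    out <- df
    out$start <- L - df$end
    out$end <- L - df$start
    out$strand <- ifelse(df$strand == "+", "-", "+")
    out
  }
  h1 <- upstream_hits(fx$genes, fx$tes)
  h2 <- upstream_hits(reflect(fx$genes), reflect(fx$tes))
  k1 <- sort(paste(h1$gene_id, h1$te_id, h1$distance_bp))
  k2 <- sort(paste(h2$gene_id, h2$te_id, h2$distance_bp))
  expect_identical(k1, k2)
})

test_that("pair prefilter keeps TE-matching pairs, drops random pairs
           and preserves mate synchronization", {
  set.seed(23)
  te <- rand_dna(1500)
  pairs <- list(
    mate1 = make_reads(c(substr(te, 101, 200), rand_dna(100),
                         rand_dna(100)), prefix = "p"),
    mate2 = make_reads(c(rand_dna(100), substr(te, 901, 1000),
                         rand_dna(100)), prefix = "p"))
  pairs$mate1$read_id <- paste0(pairs$mate1$read_id, "/1")
  pairs$mate2$read_id <- paste0(pairs$mate2$read_id, "/2")
  kept <- prefilter_te_pairs(pairs, c(fam = te))
  expect_equal(nrow(kept$mate1), 2)
  expect_equal(nrow(kept$mate2), 2)
  expect_identical(sub("/1$", "", kept$mate1$read_id),
                   sub("/2$", "", kept$mate2$read_id))
  # desynchronized input is rejected with the offending name
  bad <- pairs
  bad$mate2 <- bad$mate2[c(2, 1, 3), ]
  expect_error(prefilter_te_pairs(bad, c(fam = te)),
               class = "repeatscape_desynchronized_mates")
})

test_that("pair classification links a TE mate with a gene mate and
           ignores gene-gene or unmapped pairs", {
  set.seed(24)
  te <- rand_dna(1400)
  genes <- c(gA = rand_dna(1000), gB = rand_dna(1000))
  p <- function(s1, s2, id) list(
    mate1 = data.frame(read_id = paste0(id, "/1"), species_code = "Xx",
                       seq = s1, stringsAsFactors = FALSE),
    mate2 = data.frame(read_id = paste0(id, "/2"), species_code = "Xx",
                       seq = s2, stringsAsFactors = FALSE))
  cat2 <- function(a, b) list(mate1 = rbind(a$mate1, b$mate1),
                              mate2 = rbind(a$mate2, b$mate2))
  pairs <- Reduce(cat2, list(
    p(substr(te, 1, 100), rc(substr(genes["gA"], 201, 300)), "x1"),
    p(substr(genes["gA"], 1, 100), substr(genes["gB"], 1, 100), "x2"),
    p(substr(te, 201, 300), rand_dna(100), "x3")))
  res <- classify_pairs(pairs, c("fam#TE:copia" = te), genes)
  expect_equal(nrow(res$hits), 1)
  expect_equal(res$hits$gene_id, "gA")
  expect_equal(res$hits$te_class, "TE:copia")
  expect_equal(res$hits$pair_id, "x1")
  expect_equal(res$n_pairs_classified, 1L)
  expect_equal(res$gene_counts$n_pairs, 1L)
  # reported genes always come from the gene library
  expect_true(all(res$hits$gene_id %in% names(genes)))
})

test_that("mates matching two different target classes equally well are
           discarded as ambiguous", {
  set.seed(25)
  shared <- rand_dna(100)
  te <- paste0(rand_dna(300), shared, rand_dna(300))
  gene <- paste0(rand_dna(200), shared, rand_dna(200))
  other_gene <- rand_dna(600)
  pairs <- list(
    mate1 = data.frame(read_id = "a1/1", species_code = "Xx",
                       seq = shared, stringsAsFactors = FALSE),
    mate2 = data.frame(read_id = "a1/2", species_code = "Xx",
                       seq = substr(other_gene, 1, 100),
                       stringsAsFactors = FALSE))
  res <- classify_pairs(pairs, c("fam#TE:gypsy" = te),
                        c(g1 = gene, g2 = other_gene))
  expect_equal(nrow(res$hits), 0)
  expect_equal(res$n_ambiguous, 1L)
})

test_that("map parameter validation rejects negatives", {
  expect_error(map_params(seed_len = -1),
               class = "repeatscape_invalid_argument")
  mp <- map_params()
  expect_equal(mp$seed_len, 12L)
  expect_equal(mp$max_edit, 4L)
})
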