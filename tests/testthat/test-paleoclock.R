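test_that("read-to-LTR mapping: exact reads give identity 1, counted
           substitutions give exact fractions, unmappable reads are
           excluded", {
  set.seed(1)
  ltr <- list(cluster_id = "CL1", species_code = "Xx", seq = rand_dna(300))
  exact <- vapply(1:6, function(i) {
    s <- sample.int(200, 1); substr(ltr$seq, s, s + 99)
  }, character(1))
  dist <- map_reads_to_ltr(make_reads(exact), ltr)
  expect_true(all(dist$identities == 1))
  # exactly 2 substitutions in a fully-contained 100 nt read -> 0.98
  rd2 <- mutate_at(substr(ltr$seq, 50, 149), c(30, 60))
  d2 <- map_reads_to_ltr(make_reads(rd2), ltr)
  expect_equal(d2$identities, 0.98)
  # unrelated reads are excluded, and all-unrelated input errors out
  mixed <- map_reads_to_ltr(make_reads(c(exact, rand_dna(100))), ltr)
  expect_equal(mixed$n_excluded, 1L)
  expect_error(map_reads_to_ltr(make_reads(replicate(5, rand_dna(100))),
                                ltr),
               class = "repeatscape_empty_distribution")
  short <- list(seq = rand_dna(60))
  expect_error(map_reads_to_ltr(make_reads(exact), short),
               class = "repeatscape_invalid_argument")
})

test_that("peak activity is the modal bin midpoint with ties toward
           younger (higher identity)", {
  d <- function(ids) list(identities = ids, bin_width = 0.01)
  expect_equal(peak_activity(d(rep(0.98, 7))), 0.985)
  # bimodal: 20 reads at 0.99 dominate 10 at 0.95
  expect_equal(peak_activity(d(c(rep(0.99, 20), rep(0.95, 10)))), 0.995)
  # exact tie: higher-identity bin wins
  expect_equal(peak_activity(d(c(rep(0.95, 6), rep(0.98, 6)))), 0.985)
  expect_error(peak_activity(d(rep(0.99, 4))),
               class = "repeatscape_insufficient_data")
})

test_that("identity converts to age by d/r (consensus) and d/2r (pair),
           exactly and monotonically", {
  clk_c <- clock_model(1.3e-8, "consensus")
  clk_p <- clock_model(1.3e-8, "pair")
  expect_equal(identity_to_age(1.0, clk_c), 0)
  expect_equal(identity_to_age(1.0, clk_p), 0)
  expect_equal(identity_to_age(0.974, clk_p), 0.026 / (2 * 1.3e-8) / 1e6)
  expect_equal(identity_to_age(0.974, clk_c), 0.026 / 1.3e-8 / 1e6)
  expect_equal(identity_to_age(0.974, clk_p), 1.0)
  expect_equal(identity_to_age(0.974, clk_c), 2.0)
  # pair age is exactly half the consensus age; ages decrease in identity
  ids <- seq(0.90, 1.0, by = 0.005)
  ages_c <- identity_to_age(ids, clk_c)
  ages_p <- identity_to_age(ids, clk_p)
  expect_equal(ages_p, ages_c / 2)
  expect_true(all(diff(ages_c) < 0 | ids[-1] == 1))
  # sequencing-error discount
  expect_equal(identity_to_age(0.974, clk_c, error_rate = 0.013), 1.0)
  expect_error(identity_to_age(1.2, clk_c),
               class = "repeatscape_invalid_argument")
})

test_that("LTR-pair element dating: identical pairs date to zero, 26
           mismatches over 1000 nt date to 1 My, implausible pairs are
           rejected", {
  set.seed(2)
  clk <- clock_model()
  ltr <- rand_dna(1000)
  expect_equal(date_element_by_ltr_pair(ltr, ltr, clk), 0)
  mut <- mutate_at(ltr, sample.int(1000, 26))
  expect_equal(date_element_by_ltr_pair(ltr, mut, clk),
               0.026 / (2 * 1.3e-8) / 1e6)
  expect_error(date_element_by_ltr_pair(strrep("A", 1000),
                                        strrep("C", 1000), clk),
               class = "repeatscape_implausible_pair")
  expect_error(date_element_by_ltr_pair(rand_dna(50), ltr, clk),
               class = "repeatscape_invalid_argument")
})

test_that("round-trip dating on simulated families: zero sequencing
           error, substitution-only decay recovers planted ages within
           0.25 My median error", {
  set.seed(3)
  clk <- clock_model(1.3e-8, "consensus")
  ages <- c(1, 2, 3)
  ests <- numeric(0)
  for (k in seq_along(ages)) {
    f <- te_family(sprintf("F%d", k), "gypsy", rand_dna(250),
                   rand_dna(700), target_mb = 0.05, age_my = ages[k],
                   age_sd_my = 0)
    prof <- species_profile("Xx", 0.25, list(f), gene_count = 2)
    sim <- simulate_genome(prof, clk, seed = 30 + k, min_spacer = 500)
    rd <- simulate_reads(sim$genome, 0.6, 100, "Xx", error_rate = 0,
                         seed = 40 + k)
    cl <- build_clusters(rd, cluster_params(significant_fraction = 0.02))
    cluster <- cl$clusters[[1]]
    ltr_db <- read_repeat_library(
      stats::setNames(f$ltr_seq, sprintf("F%d_LTR#LTR/Gypsy", k)))
    est <- date_cluster(cluster, cl$reads, "Xx", ltr_db, clk)
    expect_equal(est$status, "ok")
    expect_gte(est$n_reads, 10)
    ests <- c(ests, est$age_my)
  }
  expect_lte(median(abs(ests - ages)), 0.25)
})

test_that("the activity timeline keeps failed estimates as flagged
           rows", {
  set.seed(4)
  clk <- clock_model()
  rd <- make_reads(replicate(4, rand_dna(100)))
  small <- structure(list(cluster_id = "CL9", members = rd$read_id[1:2],
                          species_counts = c(Xx = 2L)),
                     class = "rs_cluster")
  db <- read_repeat_library(c("x_LTR#LTR/Gypsy" = rand_dna(200)))
  est <- date_cluster(small, rd, "Xx", db, clk)
  expect_equal(est$status, "insufficient_reads")
  tl <- activity_timeline(list(est))
  expect_equal(nrow(tl), 1)
  expect_true(is.na(tl$age_my))
  expect_equal(tl$status, "insufficient_reads")
})
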