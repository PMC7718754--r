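# Shared fixtures and independent oracles.  The oracles here are
# deliberately naive (dynamic programming in plain R, exhaustive scans,
# full enumeration) so they stay independent of the package's optimized
# code paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc <- function(x) repeatscape::revcomp(x)

make_reads <- function(seqs, species = "Xx", prefix = "r") {
  data.frame(read_id = sprintf("%s_%s%04d", species, prefix,
                               seq_along(seqs)),
             species_code = species, seq = seqs, stringsAsFactors = FALSE)
}

# mutate a sequence at exactly the given 1-based positions (guaranteed
# substitutions)
mutate_at <- function(seq, pos) {
  ch <- strsplit(seq, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

# plain-R Smith-Waterman oracle: best local alignment score, matches and
# columns under match/mismatch/gap scoring.  O(nm) with full traceback;
# used on short sequences only.
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  TB <- matrix(0L, n + 1, m + 1)
  best <- 0; bi <- 0; bj <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- if (av[i] %in% c("A", "C", "G", "T") && av[i] == bv[j])
        match else mismatch
      cand <- c(H[i, j] + sub, H[i, j + 1] + gap, H[i + 1, j] + gap, 0)
      k <- which.max(cand)
      H[i + 1, j + 1] <- cand[k]
      TB[i + 1, j + 1] <- if (cand[k] <= 0) 0L else k
      if (cand[k] > best) { best <- cand[k]; bi <- i + 1; bj <- j + 1 }
    }
  }
  matches <- 0; columns <- 0
  i <- bi; j <- bj
  while (i > 1 && j > 1 && TB[i, j] != 0L) {
    t <- TB[i, j]
    columns <- columns + 1
    if (t == 1L) {
      if (av[i - 1] == bv[j - 1]) matches <- matches + 1
      i <- i - 1; j <- j - 1
    } else if (t == 2L) i <- i - 1 else j <- j - 1
  }
  list(score = best, matches = matches, columns = columns)
}

# oracle edge test via Biostrings (an independent local-alignment
# implementation): best orientation by score, thresholds as in the edge
# definition
pwa_local <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 0, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
  list(score = Biostrings::score(pa),
       matches = Biostrings::nmatch(pa), columns = cols)
}

edge_oracle <- function(sa, sb, min_identity = 0.90,
                        min_overlap_fraction = 0.55) {
  f <- pwa_local(sa, sb)
  r <- pwa_local(rc(sa), sb)
  b <- if (r$score > f$score) r else f
  if (b$columns == 0 || b$score <= 0) return(FALSE)
  ident <- b$matches / b$columns
  ident >= min_identity &&
    b$columns >= min_overlap_fraction * min(nchar(sa), nchar(sb))
}

# vectorized oracle over many (i, j) pairs: for each subject j, all its
# partner reads are aligned in one pairwiseAlignment call (both
# orientations), which keeps the independent-oracle runs fast enough for
# full all-vs-all sweeps
edge_oracle_batch <- function(seqs, ii, jj, min_identity = 0.90,
                              min_overlap_fraction = 0.55) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  out <- logical(length(ii))
  fw <- Biostrings::DNAStringSet(seqs)
  rv <- Biostrings::reverseComplement(fw)
  for (j in unique(jj)) {
    rows <- which(jj == j)
    pat_idx <- ii[rows]
    res <- lapply(list(fw[pat_idx], rv[pat_idx]), function(pat) {
      pa <- Biostrings::pairwiseAlignment(pat, fw[[j]], type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 0, gapExtension = 2)
      list(score = Biostrings::score(pa),
           matches = Biostrings::nmatch(pa),
           columns = BiocGenerics::width(Biostrings::alignedPattern(pa)))
    })
    use_rc <- res[[2]]$score > res[[1]]$score
    sc <- ifelse(use_rc, res[[2]]$score, res[[1]]$score)
    m <- ifelse(use_rc, res[[2]]$matches, res[[1]]$matches)
    cols <- ifelse(use_rc, res[[2]]$columns, res[[1]]$columns)
    shorter <- pmin(nchar(seqs[pat_idx]), nchar(seqs[j]))
    out[rows] <- sc > 0 & cols > 0 & (m / cols) >= min_identity &
      cols >= min_overlap_fraction * shorter
  }
  out
}

# connected components by transitive closure over an edge list (union-find)
components_oracle <- function(n, edges_i, edges_j) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(edges_i)) {
    a <- find(edges_i[k]); b <- find(edges_j[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

# exhaustive upstream-window scan (all gene x TE pairs)
upstream_oracle <- function(genes, tes, max_kb = 5) {
  W <- max_kb * 1000
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    for (t in seq_len(nrow(tes))) {
      if (genes$chrom[g] != tes$chrom[t]) next
      d <- if (genes$strand[g] == "+") genes$start[g] - tes$end[t]
           else tes$start[t] - genes$end[g]
      # TE must overlap the half-open window: gap strictly less than W
      if (d >= 1 && d < W) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = genes$feature_id[g], te_id = tes$feature_id[t],
          distance_bp = as.integer(d),
          bin_kb = as.integer(ceiling(d / 1000)),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), te_id = character(0),
                      distance_bp = integer(0), bin_kb = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$gene_id, out$distance_bp, out$te_id), , drop = FALSE]
}

# exact upper-tail hypergeometric by enumerating all C(N, n) draws
hyper_enum_oracle <- function(k, K, n, N) {
  pop <- c(rep(1, K), rep(0, N - K))
  draws <- utils::combn(N, n)
  hits <- colSums(matrix(pop[draws], nrow = n))
  mean(hits >= k)
}

# random interval fixture on a small genome
random_intervals <- function(n_genes, n_tes, glen = 100000) {
  gs <- sort(sample.int(glen - 2000, n_genes))
  genes <- data.frame(chrom = "chr1", start = gs, end = gs + 1000,
                      strand = sample(c("+", "-"), n_genes, TRUE),
                      feature_id = sprintf("g%03d", seq_len(n_genes)),
                      feature_class = "gene", stringsAsFactors = FALSE)
  ts <- sample.int(glen - 3000, n_tes)
  tes <- data.frame(chrom = "chr1", start = ts,
                    end = ts + sample(200:2000, n_tes, TRUE),
                    strand = sample(c("+", "-"), n_tes, TRUE),
                    feature_id = sprintf("te%03d", seq_len(n_tes)),
                    feature_class = sample(c("TE:gypsy", "TE:copia"),
                                           n_tes, TRUE),
                    stringsAsFactors = FALSE)
  list(genes = genes, tes = tes)
}

# a small planted-family read set: n_fam families of identical-length
# elements, plus background reads
planted_readset <- function(n_per_family = 25, elem_len = 600,
                            n_background = 30, divergence = 0.02,
                            read_len = 100, species = "Xx", seed = 1) {
  set.seed(seed)
  elems <- replicate(2, rand_dna(elem_len))
  seqs <- character(0); fam <- integer(0)
  for (e in seq_along(elems)) {
    for (i in seq_len(n_per_family)) {
      s <- sample.int(elem_len - read_len + 1, 1)
      rd <- substr(elems[e], s, s + read_len - 1)
      nmut <- rbinom(1, read_len, divergence)
      if (nmut > 0) rd <- mutate_at(rd, sample.int(read_len, nmut))
      if (runif(1) < 0.5) rd <- rc(rd)
      seqs <- c(seqs, rd); fam <- c(fam, e)
    }
  }
  seqs <- c(seqs, replicate(n_background, rand_dna(read_len)))
  fam <- c(fam, rep(0L, n_background))
  reads <- make_reads(seqs, species)
  reads$family <- fam
  reads
}
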