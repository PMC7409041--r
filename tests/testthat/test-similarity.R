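test_that("select_unassigned keeps only phylum-unassigned contigs", {
  cat <- tiny_catalog()
  # c1: one phylum-assigned gene -> excluded; c2: empty lineage -> included;
  # c3: viral with phylum -> excluded; c9 has no predicted genes -> included
  got <- select_unassigned(cat, c("c1", "c2", "c3", "c9"))
  expect_setequal(got, c("c2", "c9"))

  # domain-only gene (phylum = unclassified_phylum) counts as unassigned
  cat$lineage[2] <- pad_lineage("Bacteria")
  cat$lineage[1] <- ""
  got2 <- select_unassigned(cat, c("c1", "c2", "c3"))
  expect_true("c1" %in% got2)
})

test_that("kmer_set enumerates sliding windows and handles edge cases", {
  expect_equal(sort(kmer_set("ACGTT", k = 3, canonical = FALSE)),
               sort(c("ACG", "CGT", "GTT")))
  # shorter than k -> empty
  expect_length(kmer_set(strrep("A", 30), k = 31), 0L)
  # windows containing N are dropped
  expect_equal(as.character(kmer_set("ACGNACG", k = 3, canonical = FALSE)),
               "ACG")
  expect_error(kmer_set("ACGT", k = 4), "odd")
})

test_that("canonicalisation makes k-mer sets strand-independent", {
  set.seed(31)
  for (i in 1:10) {
    s <- random_dna(120)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_setequal(kmer_set(s, k = 7), kmer_set(rc, k = 7))
    # and matches the independent oracle
    expect_setequal(kmer_set(s, k = 7), oracle_kmers(s, 7))
    expect_setequal(kmer_set(s, k = 7, canonical = FALSE),
                    oracle_kmers(s, 7, canonical = FALSE))
  }
})

test_that("jaccard matches brute-force set arithmetic", {
  a <- kmer_set("ACGTT", k = 3, canonical = FALSE)
  b <- kmer_set("CGTTA", k = 3, canonical = FALSE)
  expect_equal(jaccard(a, b), 0.5)  # {ACG,CGT,GTT} vs {CGT,GTT,TTA}
  expect_equal(jaccard(a, a), 1.0)
  expect_equal(jaccard(a, kmer_set("AAAAA", k = 3, canonical = FALSE)), 0)
  # both empty -> 0 by convention
  e <- kmer_set("AC", k = 3)
  expect_equal(jaccard(e, e), 0)
  expect_error(jaccard(kmer_set("ACGTACG", k = 3), kmer_set("ACGTACG", k = 5)),
               "mismatched k")
})

test_that("the sparse engine equals the nested-loop oracle on random instances", {
  set.seed(123)
  for (rep in 1:6) {
    k <- sample(c(5L, 7L), 1)
    na <- sample(3:12, 1); nb <- sample(3:12, 1)
    # mix of related and unrelated contigs to get nontrivial Jaccard values
    base <- random_dna(80)
    mk <- function(n) setNames(vapply(seq_len(n), function(i) {
      if (runif(1) < 0.5) random_dna(sample(20:90, 1)) else {
        ch <- strsplit(base, "")[[1]]
        hit <- runif(80) < 0.05
        ch[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
        paste(ch, collapse = "")
      }
    }, ""), paste0("s", seq_len(n)))
    a <- mk(na); names(a) <- paste0("a", seq_len(na))
    b <- mk(nb); names(b) <- paste0("b", seq_len(nb))
    got <- shared_fraction(a, b, k = k, threshold = 0.1)
    want <- oracle_shared_fraction(a, b, k = k, threshold = 0.1)
    expect_equal(matrix(got$pairs$jaccard, na, nb), want$jaccard,
                 tolerance = 1e-12)
    expect_setequal(got$shared_ids, c(want$shared_a, want$shared_b))
    expect_equal(got$shared_fraction, want$overall)
    expect_equal(got$shared_fraction_a, want$frac_a)
    expect_equal(got$shared_fraction_b, want$frac_b)
  }
})

test_that("shared_fraction honours forced outcomes and the strict threshold", {
  seqs <- setNames(vapply(1:4, function(i) random_dna(100), ""),
                   paste0("c", 1:4))
  # identical pools -> everything shared
  r1 <- shared_fraction(seqs, setNames(seqs, paste0("d", 1:4)), k = 31)
  expect_equal(r1$shared_fraction, 1.0)
  # unrelated pools -> nothing shared
  set.seed(5)
  other <- setNames(vapply(1:4, function(i) random_dna(100), ""),
                    paste0("e", 1:4))
  r0 <- shared_fraction(seqs, other, k = 31)
  expect_equal(r0$shared_fraction, 0.0)
  # strict inequality at the threshold: J == threshold is not similar
  a <- kmer_set("ACGTT", k = 3, canonical = FALSE)
  b <- kmer_set("CGTTA", k = 3, canonical = FALSE)
  stopifnot(jaccard(a, b) == 0.5)
  r <- shared_fraction(c(x = "ACGTT"), c(y = "CGTTA"), k = 3,
                       threshold = 0.5, canonical = FALSE)
  expect_equal(r$n_shared, 0L)
  expect_error(shared_fraction(character(0), seqs), "at least one")
})

test_that("site swap symmetry and threshold monotonicity hold", {
  pools <- generate_contig_pools(8, 0.5, 2, 400, 0.01, seed = 77)
  r_ab <- shared_fraction(pools$site_a, pools$site_b)
  r_ba <- shared_fraction(pools$site_b, pools$site_a)
  expect_equal(r_ab$shared_fraction, r_ba$shared_fraction)
  expect_equal(r_ab$shared_fraction_a, r_ba$shared_fraction_b)
  expect_equal(r_ab$shared_fraction_b, r_ba$shared_fraction_a)

  fracs <- vapply(c(0.05, 0.1, 0.3, 0.6, 0.9), function(th) {
    shared_fraction(pools$site_a, pools$site_b, threshold = th,
                    keep_pairs = FALSE)$shared_fraction
  }, 0)
  expect_true(all(diff(fracs) <= 0))
})

test_that("contigs shorter than k stay in the denominator and are never shared", {
  a <- c(long = random_dna(100), short = "ACGTAC")
  b <- c(long2 = a[["long"]])
  expect_message(r <- shared_fraction(a, b, k = 31), "empty k-mer")
  expect_equal(r$n_unassigned_a, 2L)
  expect_false("short" %in% r$shared_ids)
  expect_equal(r$shared_fraction, 2 / 3)
})

test_that("recovered sharing matches truth labels on synthetic pools", {
  pools <- generate_contig_pools(12, 0.25, 3, 1000, 0.005, seed = 13)
  r <- shared_fraction(pools$site_a, pools$site_b, k = 31, threshold = 0.1)
  truth_prop <- mean(pools$truth$shared)
  n <- nrow(pools$truth)
  se <- sqrt(truth_prop * (1 - truth_prop) / n)
  expect_lt(abs(r$shared_fraction - truth_prop), max(3 * se, 1e-9) + 1e-12)
  # and the brute-force oracle agrees exactly
  want <- oracle_shared_fraction(pools$site_a, pools$site_b, 31, 0.1)
  expect_equal(r$shared_fraction, want$overall)
})
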