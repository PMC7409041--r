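test_that("generate_taxa yields distinct, well-formed, seed-deterministic lineages", {
  one <- generate_taxa(1, seed = 5)
  expect_length(one, 1L)
  expect_length(strsplit(one, ";")[[1]], 7L)

  a <- generate_taxa(50, seed = 1)
  b <- generate_taxa(50, seed = 1)
  expect_identical(a, b)
  expect_false(anyDuplicated(a) > 0)
  expect_true(all(lengths(strsplit(a, ";")) == 7L))

  c2 <- generate_taxa(50, seed = 2)
  expect_true(any(a != c2))

  expect_error(generate_taxa(0, seed = 1), "positive")
})

test_that("generate_community proportions follow the symmetric Dirichlet", {
  # degenerate single taxon
  t1 <- generate_taxa(1, seed = 3)
  com1 <- generate_community(t1, n_orfs = 5, seed = 4)
  expect_equal(unname(com1$proportions), 1.0)

  # concentration -> Inf limit is the uniform community
  t10 <- generate_taxa(10, seed = 3)
  com <- generate_community(t10, concentration = 1e6, n_orfs = 30, seed = 4)
  expect_true(all(abs(com$proportions - 0.1) < 0.001))
  expect_equal(sum(com$proportions), 1, tolerance = 1e-9)

  # every taxon owns at least one ORF
  expect_setequal(unique(com$catalog$lineage), t10)
  expect_error(generate_community(t10, n_orfs = 9, seed = 1), ">=")
})

test_that("community catalogs are valid ORF tables", {
  com <- generate_community(generate_taxa(6, seed = 2), n_orfs = 40, seed = 9)
  cat <- com$catalog
  expect_true(all(cat$length_bp == cat$end - cat$start + 1L))
  expect_true(all(cat$length_bp >= 200 & cat$length_bp <= 3000))
  expect_false(anyDuplicated(cat$orf_id) > 0)
  # a contig carries genes of a single taxon
  expect_true(all(tapply(cat$lineage, cat$contig_id,
                         function(x) length(unique(x))) == 1L))
})

test_that("simulate_read_counts is multinomial with length-weighted probabilities", {
  cat1 <- data.frame(orf_id = "a", contig_id = "c", start = 1L, end = 900L,
                     strand = "+", length_bp = 900L, lineage = "x",
                     function_label = "", viral_flag = FALSE)
  counts <- simulate_read_counts(cat1, c(x = 1), 1000, seed = 1)
  expect_equal(unname(counts), 1000L)

  # closure: counts always sum to library size
  ds <- generate_community(generate_taxa(5, seed = 1), n_orfs = 25, seed = 2)
  for (s in 1:5) {
    cts <- simulate_read_counts(ds$catalog, ds$proportions, 12345, seed = s)
    expect_equal(sum(cts), 12345L)
  }

  # two equal-proportion taxa, lengths 1000 vs 2000 -> count ratio ~ 1:2
  cat2 <- data.frame(orf_id = c("a", "b"), contig_id = c("c1", "c2"),
                     start = 1L, end = c(1000L, 2000L), strand = "+",
                     length_bp = c(1000L, 2000L),
                     lineage = c("t1", "t2"), function_label = "",
                     viral_flag = FALSE)
  cts <- simulate_read_counts(cat2, c(t1 = 0.5, t2 = 0.5), 1e6, seed = 3)
  p <- 1 / 3  # expected share of ORF a
  se <- sqrt(p * (1 - p) / 1e6)
  expect_lt(abs(cts[["a"]] / 1e6 - p), 3 * se)

  expect_error(simulate_read_counts(cat2[0, ], c(t1 = 1), 10, seed = 1),
               "non-empty")
})

test_that("contig pools realise the requested shared-population structure", {
  # no sharing
  p0 <- generate_contig_pools(6, 0, 2, 300, 0.01, seed = 11)
  pops_a <- unique(p0$truth$population[p0$truth$site == "A"])
  pops_b <- unique(p0$truth$population[p0$truth$site == "B"])
  expect_length(intersect(pops_a, pops_b), 0L)
  expect_false(any(p0$truth$shared))

  # full sharing
  p1 <- generate_contig_pools(6, 1, 2, 300, 0.01, seed = 11)
  pops_a <- unique(p1$truth$population[p1$truth$site == "A"])
  pops_b <- unique(p1$truth$population[p1$truth$site == "B"])
  expect_setequal(pops_a, 1:6)
  expect_setequal(pops_b, 1:6)

  # zero mutation: same-population contigs are identical strings
  pz <- generate_contig_pools(4, 0.5, 3, 250, 0, seed = 2)
  seqs <- c(pz$site_a, pz$site_b)
  by_pop <- split(pz$truth$contig_id, pz$truth$population)
  for (ids in by_pop) {
    expect_length(unique(unname(seqs[ids])), 1L)
  }
  expect_true(all(pz$truth$assignment_status == "unassigned"))

  expect_error(generate_contig_pools(4, 0.5, 2, 300, 0.5, seed = 1),
               "mutation_rate")
  expect_error(generate_contig_pools(4, 0.5, 2, 100, 0.01, seed = 1), "200")
  expect_error(generate_contig_pools(4, 1.5, 2, 300, 0.01, seed = 1),
               "\\[0, 1\\]")
})

test_that("mutated copies diverge at roughly the requested rate", {
  mu <- 0.05
  p <- generate_contig_pools(2, 1, 2, 2000, mu, seed = 21)
  seqs <- c(p$site_a, p$site_b)
  for (ids in split(p$truth$contig_id, p$truth$population)) {
    grp <- unname(seqs[ids])
    d <- mapply(function(x, y) {
      mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
    }, grp[1], grp[-1])
    # two independently mutated copies differ at ~ 2*mu*(1 - mu/0.75...)
    expect_gt(mean(d), mu)
    expect_lt(mean(d), 3 * mu)
  }
})

test_that("the dataset wrapper is deterministic and internally consistent", {
  args <- list(n_taxa = 6, n_orfs = 30, library_size = 2e4, n_populations = 8,
               shared_population_fraction = 0.25, contigs_per_population = 2,
               contig_length = 300, seed = 42)
  d1 <- do.call(simulate_two_site_dataset, args)
  d2 <- do.call(simulate_two_site_dataset, args)
  expect_identical(d1[names(d1) != "truth"], d2[names(d2) != "truth"])

  expect_true(all(names(d1$counts$A) %in% d1$catalog$orf_id))
  expect_equal(sum(d1$counts$A), 2e4)
  expect_equal(sum(d1$counts$B), 2e4)
  expect_equal(sum(d1$proportions$A), 1, tolerance = 1e-9)
  expect_equal(sum(d1$proportions$B), 1, tolerance = 1e-9)
  expect_output(print(d1), "Synthetic two-site")
})
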