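# Synthetic two-site communities with known ground truth.
#
# The generator emulates what the upstream wet-lab/assembly/annotation stack
# produces: an ORF catalog with lineages and function labels, per-ORF mapped
# read counts, and per-site pools of taxonomically unassigned contigs with a
# controlled fraction of shared underlying populations.

#' Generate distinct seven-rank lineage strings
#'
#' Draws `n_taxa` distinct semicolon-delimited lineage strings of exactly
#' `ranks` fields. Domains are sampled from Bacteria/Archaea/Eukaryota/Viruses;
#' intermediate ranks are drawn from small per-domain pools so taxa share
#' higher ranks the way a real community does; the species field is unique by
#' construction.
#'
#' @param n_taxa Number of taxa (>= 1).
#' @param ranks Number of lineage fields; the package convention is 7.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return Character vector of `n_taxa` distinct lineage strings.
#' @export
#' @examples
#' generate_taxa(5, seed = 1)
generate_taxa <- function(n_taxa, ranks = 7L, seed) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 1) {
    stop_invalid("`n_taxa` must be a positive count")
  }
  n_taxa <- as.integer(n_taxa)
  ranks <- as.integer(ranks)
  if (ranks < 1L) stop_invalid("`ranks` must be >= 1")
  with_seed(seed, {
    domains <- sample(c("Bacteria", "Archaea", "Eukaryota", "Viruses"),
                      n_taxa, replace = TRUE,
                      prob = c(0.5, 0.1, 0.1, 0.3))
    n_pool <- max(2L, ceiling(sqrt(n_taxa)))
    rank_names <- if (ranks == 7L) lineage_ranks() else paste0("rank", seq_len(ranks))
    fields <- matrix("", nrow = n_taxa, ncol = ranks)
    fields[, 1L] <- domains
    if (ranks >= 2L) {
      for (j in 2L:ranks) {
        grp <- sample.int(n_pool, n_taxa, replace = TRUE)
        # embed the parent field so same-name groups in different parents stay
        # distinct lineages (hierarchical consistency)
        fields[, j] <- paste0(substr(fields[, j - 1L], 1L, 12L), "_",
                              rank_names[j], grp)
      }
      # species (last field) unique per taxon
      fields[, ranks] <- sprintf("species_%04d", seq_len(n_taxa))
    }
    apply(fields, 1L, paste, collapse = ";")
  })
}

#' Generate a community: ORF catalog plus taxon proportions
#'
#' Taxon relative abundances are drawn from a symmetric Dirichlet with the
#' given concentration (large concentration -> near-uniform community; small
#' -> dominated by few taxa). Each taxon owns at least one ORF; remaining ORFs
#' are assigned to taxa proportionally to abundance. ORF lengths are uniform
#' on `orf_length_range`; ORFs are grouped onto contigs of 1--4 genes with
#' 1-based inclusive coordinates. Viral taxa get `viral_flag = TRUE` and some
#' of their genes carry `"AMG:"`-prefixed function labels, emulating auxiliary
#' metabolic genes.
#'
#' @param taxa Character vector of lineage strings (see [generate_taxa()]).
#' @param concentration Symmetric Dirichlet concentration parameter (> 0).
#' @param n_orfs Total number of ORFs (>= number of taxa).
#' @param orf_length_range Length-2 bp interval within \[100, 50000\].
#' @param seed Integer seed.
#' @return List with `catalog` (a data.frame of ORF records: orf_id,
#'   contig_id, start, end, strand, length_bp, lineage, function_label,
#'   viral_flag, taxon) and `proportions` (named numeric summing to 1).
#' @export
#' @examples
#' com <- generate_community(generate_taxa(4, seed = 1), n_orfs = 20, seed = 2)
#' sum(com$proportions)
generate_community <- function(taxa, concentration = 1, n_orfs,
                               orf_length_range = c(200L, 3000L), seed) {
  n_taxa <- length(taxa)
  if (n_taxa < 1L) stop_invalid("`taxa` must be non-empty")
  if (anyDuplicated(taxa)) stop_invalid("`taxa` must be distinct")
  if (!is.numeric(concentration) || concentration <= 0) {
    stop_invalid("`concentration` must be a positive real")
  }
  if (n_orfs < n_taxa) {
    stop_invalid("`n_orfs` (", n_orfs, ") must be >= number of taxa (",
                 n_taxa, ")")
  }
  if (length(orf_length_range) != 2L || orf_length_range[1L] < 100 ||
      orf_length_range[2L] > 50000 ||
      orf_length_range[1L] > orf_length_range[2L]) {
    stop_invalid("`orf_length_range` must be an increasing interval within [100, 50000] bp")
  }
  n_orfs <- as.integer(n_orfs)
  with_seed(seed, {
    # symmetric Dirichlet via normalised gammas; degenerate at one taxon
    g <- rgamma(n_taxa, shape = concentration, rate = 1)
    while (sum(g) == 0) g <- rgamma(n_taxa, shape = concentration, rate = 1)
    props <- setNames(g / sum(g), taxa)

    # every taxon owns >= 1 ORF; the rest follow abundance
    owner <- c(seq_len(n_taxa),
               sample.int(n_taxa, n_orfs - n_taxa, replace = TRUE,
                          prob = props))
    owner <- owner[sample.int(n_orfs)]
    lengths_bp <- as.integer(round(runif(n_orfs, orf_length_range[1L],
                                         orf_length_range[2L])))

    # pack consecutive ORFs of the same taxon onto contigs of 1-4 genes
    contig_of <- integer(n_orfs)
    start <- integer(n_orfs)
    contig <- 0L
    i <- 1L
    while (i <= n_orfs) {
      contig <- contig + 1L
      size <- sample.int(4L, 1L)
      last <- i
      while (last - i + 1L < size && last < n_orfs &&
             owner[last + 1L] == owner[i]) {
        last <- last + 1L  # a contig holds one taxon's genes
      }
      pos <- 1L
      for (j in i:last) {
        contig_of[j] <- contig
        start[j] <- pos
        pos <- pos + lengths_bp[j] + sample(20:200, 1L)  # intergenic gap
      }
      i <- last + 1L
    }
    domain <- lineage_matrix(taxa)[, "domain"][owner]
    viral <- domain == "Viruses"
    fun_pool <- c("terminase", "portal protein", "major capsid protein",
                  "tail fiber protein", "integrase", "recombinase XerD",
                  "DNA primase", "hypothetical protein")
    amg_pool <- c("AMG:psbA photosystem II D1", "AMG:cobS cobalamin synthase",
                  "AMG:phoH phosphate starvation", "AMG:mazG pyrophosphatase")
    fun <- sample(fun_pool, n_orfs, replace = TRUE)
    is_amg <- viral & runif(n_orfs) < 0.25
    fun[is_amg] <- sample(amg_pool, sum(is_amg), replace = TRUE)
    catalog <- data.frame(
      orf_id = sprintf("orf_%05d", seq_len(n_orfs)),
      contig_id = sprintf("ctg_%05d", contig_of),
      start = start,
      end = start + lengths_bp - 1L,
      strand = sample(c("+", "-"), n_orfs, replace = TRUE),
      length_bp = lengths_bp,
      lineage = taxa[owner],
      function_label = fun,
      viral_flag = viral,
      stringsAsFactors = FALSE
    )
    list(catalog = catalog, proportions = props)
  })
}

#' Simulate mapped-read counts over an ORF catalog
#'
#' Reads are drawn multinomially with per-ORF probability proportional to
#' (taxon proportion / number of the taxon's ORFs) x ORF length. The taxon's
#' abundance is its share of length-normalised sequencing effort, split evenly
#' over its genes; length-proportional sampling within a gene makes TPM
#' (which divides by length) the unbiased recovery estimator for the taxon
#' proportions.
#'
#' @param catalog ORF catalog data.frame (needs `orf_id`, `length_bp`,
#'   `lineage`).
#' @param proportions Named numeric taxon proportions (names are lineage
#'   strings covering every lineage in the catalog).
#' @param library_size Total reads to draw (>= 1).
#' @param seed Integer seed.
#' @return Named integer vector of counts summing to `library_size`.
#' @export
simulate_read_counts <- function(catalog, proportions, library_size, seed) {
  if (is.null(catalog) || nrow(catalog) == 0L) {
    stop_invalid("`catalog` must be non-empty")
  }
  if (library_size < 1) stop_invalid("`library_size` must be >= 1")
  p_taxon <- proportions[catalog$lineage]
  if (anyNA(p_taxon)) {
    stop_invalid("every catalog lineage needs an entry in `proportions`")
  }
  n_per_taxon <- table(catalog$lineage)[catalog$lineage]
  w <- as.numeric(p_taxon) / as.numeric(n_per_taxon) * catalog$length_bp
  counts <- with_seed(seed,
    as.integer(rmultinom(1L, size = as.integer(library_size), prob = w)))
  setNames(counts, catalog$orf_id)
}

#' Delta-method standard error of TPM-based proportion recovery
#'
#' Standard error of the estimator "grouped TPM / 1e6" for the true grouped
#' proportion, under the sampling model of [simulate_read_counts()] at the
#' given library size. For equal ORF lengths this reduces to the binomial
#' `sqrt(p (1 - p) / library_size)`.
#'
#' @param catalog ORF catalog data.frame.
#' @param proportions Named numeric taxon proportions.
#' @param library_size Read count of the simulated library.
#' @param rank Rank at which groups are formed (default `"phylum"`), or
#'   `"lineage"` for full lineage strings.
#' @return Named numeric vector: per-group true proportion standard errors.
#' @export
tpm_recovery_se <- function(catalog, proportions, library_size,
                            rank = "phylum") {
  p_taxon <- as.numeric(proportions[catalog$lineage])
  n_per_taxon <- as.numeric(table(catalog$lineage)[catalog$lineage])
  w_len <- p_taxon / n_per_taxon * catalog$length_bp
  pi_i <- w_len / sum(w_len)               # multinomial cell probabilities
  w <- 1 / catalog$length_bp               # TPM weight (rate per base)
  group <- if (identical(rank, "lineage")) catalog$lineage else
    lineage_matrix(catalog$lineage)[, rank]
  mu <- sum(pi_i * w)
  p_g <- vapply(split(pi_i * w, group), sum, 0) / mu
  se <- vapply(names(p_g), function(g) {
    ind <- as.numeric(group == g)
    sqrt(sum(pi_i * w^2 * (ind - p_g[[g]])^2) / library_size) / mu
  }, 0)
  setNames(se, names(p_g))
}

#' Generate per-site pools of unassigned contigs with known shared populations
#'
#' Draws `n_populations` random ancestor sequences. A fraction
#' `shared_population_fraction` of populations seed contigs in both sites; the
#' rest in exactly one site (balanced between sites). Each contig is an
#' independently mutated copy (per-base substitution at `mutation_rate`) of
#' its population's ancestor. All contigs are flagged "unassigned"; the truth
#' table records each contig's population and shared status.
#'
#' @param n_populations Number of underlying populations (>= 1).
#' @param shared_population_fraction Fraction of populations present in both
#'   sites, in \[0, 1\].
#' @param contigs_per_population Contigs drawn per population in each site
#'   where it occurs.
#' @param contig_length Contig length in bp (>= 200).
#' @param mutation_rate Per-base substitution probability, in \[0, 0.5).
#' @param seed Integer seed.
#' @return List with `site_a`, `site_b` (named character vectors of contig
#'   sequences) and `truth` (data.frame: contig_id, site, population, shared,
#'   assignment_status).
#' @export
generate_contig_pools <- function(n_populations, shared_population_fraction,
                                  contigs_per_population = 5L,
                                  contig_length = 2000L,
                                  mutation_rate = 0.005, seed) {
  if (n_populations < 1) stop_invalid("`n_populations` must be >= 1")
  if (shared_population_fraction < 0 || shared_population_fraction > 1) {
    stop_invalid("`shared_population_fraction` must be in [0, 1]")
  }
  if (contig_length < 200) stop_invalid("`contig_length` must be >= 200 bp")
  if (contigs_per_population < 1) {
    stop_invalid("`contigs_per_population` must be >= 1")
  }
  if (mutation_rate < 0 || mutation_rate >= 0.5) {
    stop_invalid("`mutation_rate` must be in [0, 0.5): at 0.5 and beyond the k-mer signal is destroyed")
  }
  n_populations <- as.integer(n_populations)
  contig_length <- as.integer(contig_length)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ancestors <- replicate(n_populations,
      sample(bases, contig_length, replace = TRUE), simplify = FALSE)
    n_shared <- as.integer(round(shared_population_fraction * n_populations))
    shared <- seq_len(n_populations) <= n_shared
    # unshared populations split evenly between the sites
    home <- character(n_populations)
    unshared_idx <- which(!shared)
    if (length(unshared_idx)) {
      half <- ceiling(length(unshared_idx) / 2)
      home[unshared_idx] <- rep(c("A", "B"), c(half, length(unshared_idx) - half))
    }
    mutate <- function(anc) {
      hit <- runif(length(anc)) < mutation_rate
      if (any(hit)) {
        # substitute to a uniformly chosen *different* base
        anc[hit] <- vapply(anc[hit],
                           function(b) sample(setdiff(bases, b), 1L), "")
      }
      paste(anc, collapse = "")
    }
    rows <- list()
    seqs <- list(A = character(), B = character())
    for (p in seq_len(n_populations)) {
      sites <- if (shared[p]) c("A", "B") else home[p]
      for (s in sites) {
        ids <- sprintf("pop%03d_%s_c%02d", p, s, seq_len(contigs_per_population))
        seqs[[s]] <- c(seqs[[s]], setNames(
          vapply(seq_len(contigs_per_population),
                 function(i) mutate(ancestors[[p]]), ""),
          ids))
        rows[[length(rows) + 1L]] <- data.frame(
          contig_id = ids, site = s, population = p, shared = shared[p],
          assignment_status = "unassigned", stringsAsFactors = FALSE)
      }
    }
    list(site_a = seqs$A, site_b = seqs$B, truth = do.call(rbind, rows))
  })
}

#' Simulate a complete two-site dataset with ground truth
#'
#' Convenience wrapper combining [generate_taxa()], [generate_community()]
#' (one shared ORF catalog, independent per-site taxon proportions),
#' [simulate_read_counts()] per site, and [generate_contig_pools()]. The
#' single seed is fanned out into per-stage child seeds, so each stage is
#' reproducible on its own.
#'
#' @param n_taxa,n_orfs,concentration,orf_length_range Passed to the taxon and
#'   community generators.
#' @param library_size Reads per site.
#' @param n_populations,shared_population_fraction,contigs_per_population,contig_length,mutation_rate
#'   Passed to [generate_contig_pools()].
#' @param seed Integer master seed.
#' @return Object of class `"synthetic_dataset"`: list with `catalog`,
#'   `proportions` (per site), `counts` (per site), `contigs` (per site),
#'   `contig_truth`, and `truth` (the generating parameters).
#' @export
#' @examples
#' ds <- simulate_two_site_dataset(n_taxa = 5, n_orfs = 30,
#'                                 library_size = 1e4, seed = 1)
#' sapply(ds$counts, sum)
simulate_two_site_dataset <- function(n_taxa = 30L, n_orfs = 400L,
                                      concentration = 1,
                                      orf_length_range = c(200L, 3000L),
                                      library_size = 1e6,
                                      n_populations = 40L,
                                      shared_population_fraction = 0.25,
                                      contigs_per_population = 5L,
                                      contig_length = 2000L,
                                      mutation_rate = 0.005,
                                      seed) {
  seeds <- child_seeds(seed, c("taxa", "community_a", "community_b",
                               "counts_a", "counts_b", "pools"))
  taxa <- generate_taxa(n_taxa, seed = seeds[["taxa"]])
  com_a <- generate_community(taxa, concentration, n_orfs, orf_length_range,
                              seed = seeds[["community_a"]])
  # both sites share the ORF catalog (same underlying gene pool) but have
  # independent Dirichlet community compositions
  props_b <- with_seed(seeds[["community_b"]], {
    g <- rgamma(length(taxa), shape = concentration, rate = 1)
    setNames(g / sum(g), taxa)
  })
  counts <- list(
    A = simulate_read_counts(com_a$catalog, com_a$proportions, library_size,
                             seed = seeds[["counts_a"]]),
    B = simulate_read_counts(com_a$catalog, props_b, library_size,
                             seed = seeds[["counts_b"]])
  )
  pools <- generate_contig_pools(n_populations, shared_population_fraction,
                                 contigs_per_population, contig_length,
                                 mutation_rate, seed = seeds[["pools"]])
  structure(list(
    catalog = com_a$catalog,
    proportions = list(A = com_a$proportions, B = props_b),
    counts = counts,
    contigs = list(A = pools$site_a, B = pools$site_b),
    contig_truth = pools$truth,
    truth = list(n_taxa = n_taxa, n_orfs = n_orfs,
                 concentration = concentration,
                 library_size = library_size,
                 n_populations = n_populations,
                 shared_population_fraction = shared_population_fraction,
                 contigs_per_population = contigs_per_population,
                 contig_length = contig_length,
                 mutation_rate = mutation_rate, seed = seed)
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic two-site virome dataset\n")
  cat("  taxa:", x$truth$n_taxa, " ORFs:", nrow(x$catalog),
      " reads/site:", format(x$truth$library_size, big.mark = ","), "\n")
  cat("  unassigned contigs: ", length(x$contigs$A), " (site A) + ",
      length(x$contigs$B), " (site B), shared population fraction ",
      x$truth$shared_population_fraction, "\n", sep = "")
  invisible(x)
}
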