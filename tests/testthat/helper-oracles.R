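# Independent oracles and small fixture builders. The oracle code shares no
# primitives with the package's engine: reverse complements go through
# Biostrings, sets through %in%, and the pairwise comparison is a literal
# nested loop.

oracle_kmers <- function(seq, k, canonical = TRUE) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  out <- character(0)
  for (i in seq_len(n - k + 1)) {
    km <- substr(seq, i, i + k - 1)
    if (grepl("N", km, fixed = TRUE)) next
    out <- c(out, km)
  }
  if (canonical && length(out)) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(out)))
    out <- ifelse(out <= rc, out, rc)
  }
  unique(out)
}

oracle_jaccard <- function(a, b) {
  if (!length(a) && !length(b)) return(0)
  sum(a %in% b) / length(unique(c(a, b)))
}

# literal nested-loop reference for the whole shared-fraction procedure
oracle_shared_fraction <- function(site_a, site_b, k, threshold,
                                   canonical = TRUE) {
  sa <- lapply(site_a, oracle_kmers, k = k, canonical = canonical)
  sb <- lapply(site_b, oracle_kmers, k = k, canonical = canonical)
  sim_a <- logical(length(sa))
  sim_b <- logical(length(sb))
  jac <- matrix(0, length(sa), length(sb))
  for (i in seq_along(sa)) {
    for (j in seq_along(sb)) {
      jac[i, j] <- oracle_jaccard(sa[[i]], sb[[j]])
      if (jac[i, j] > threshold) {
        sim_a[i] <- TRUE
        sim_b[j] <- TRUE
      }
    }
  }
  list(jaccard = jac,
       shared_a = names(site_a)[sim_a],
       shared_b = names(site_b)[sim_b],
       overall = (sum(sim_a) + sum(sim_b)) / (length(sa) + length(sb)),
       frac_a = mean(sim_a), frac_b = mean(sim_b))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimal hand-built catalog for IO and aggregation tests
tiny_catalog <- function() {
  data.frame(
    orf_id = c("o1", "o2", "o3", "o4"),
    contig_id = c("c1", "c1", "c2", "c3"),
    start = c(1L, 1201L, 1L, 1L),
    end = c(1000L, 2200L, 2000L, 500L),
    strand = c("+", "-", "+", "+"),
    length_bp = c(1000L, 1000L, 2000L, 500L),
    lineage = c(pad_lineage(c("Bacteria", "Proteobacteria", "Gamma", "Alteromonadales",
                              "Alteromonadaceae", "Alteromonas", "sp1")),
                pad_lineage("Bacteria"),
                "",
                pad_lineage(c("Viruses", "Uroviricota", "Caudoviricetes",
                              "Caudovirales", "Siphoviridae", "unclassified_genus",
                              "phage1"))),
    function_label = c("hypothetical protein", "", "terminase", "AMG:psbA"),
    viral_flag = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}
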