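# Pairwise k-mer Jaccard comparison of taxonomically unassigned contigs
# across two metagenomes, and the shared-contig fraction statistic.
#
# The engine computes exact k-mer sets (no sketching): a sliding window of k
# bases at step 1 along each contig, optionally collapsed to canonical form
# (lexicographic minimum of a k-mer and its reverse complement) so that
# comparisons are independent of assembly strand. All-pairs intersection
# sizes come from one sparse contig-by-k-mer membership matrix cross-product,
# which is exactly equivalent to nested-loop set intersection.

#' Select phylum-unassigned contigs
#'
#' A contig is taxonomically unassigned when none of its genes carries a
#' phylum-level assignment: every ORF has an empty lineage or a lineage whose
#' phylum field is `unclassified_phylum` (only the domain known), and contigs
#' with no predicted genes at all are included (no classification at all).
#'
#' @param catalog ORF catalog data.frame (`contig_id`, `lineage`).
#' @param contig_ids Character vector of all contig ids under consideration.
#' @return Subset of `contig_ids` that is phylum-unassigned.
#' @export
select_unassigned <- function(catalog, contig_ids) {
  assigned <- unique(catalog$contig_id[!is_phylum_unassigned(catalog$lineage)])
  setdiff(contig_ids, assigned)
}

#' k-mer set of a contig
#'
#' All length-`k` windows at step 1 along the sequence; windows containing N
#' are dropped. With `canonical = TRUE` each k-mer is replaced by the
#' lexicographic minimum of itself and its reverse complement.
#'
#' @param sequence Uppercase DNA string.
#' @param k Odd word size >= 3 (default 31; odd so no k-mer equals its own
#'   reverse complement).
#' @param canonical Collapse strands? Default TRUE.
#' @return Character vector of distinct k-mers with attributes `k` and
#'   `canonical`; empty when the sequence is shorter than `k`.
#' @export
#' @examples
#' kmer_set("ACGTT", k = 3, canonical = FALSE)
kmer_set <- function(sequence, k = 31L, canonical = TRUE) {
  k <- as.integer(k)
  if (k < 3L || k %% 2L == 0L) stop_invalid("`k` must be odd and >= 3")
  n <- nchar(sequence)
  if (n < k) {
    return(structure(character(0), k = k, canonical = canonical))
  }
  kmers <- substring(sequence, 1:(n - k + 1L), k:n)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (canonical && length(kmers)) {
    kmers <- pmin(kmers, revcomp_fixed(kmers, k))
  }
  structure(unique(kmers), k = k, canonical = canonical)
}

#' Jaccard similarity of two k-mer sets
#'
#' J = |A intersect B| / |A union B|; defined as 0 when both sets are empty.
#'
#' @param a,b k-mer sets from [kmer_set()] with the same `k`.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  ka <- attr(a, "k"); kb <- attr(b, "k")
  if (!is.null(ka) && !is.null(kb) && ka != kb) {
    stop_invalid("mismatched k: ", ka, " vs ", kb)
  }
  if (length(a) == 0L && length(b) == 0L) return(0)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Fraction of unassigned contigs shared between two metagenomes
#'
#' Computes the Jaccard index in k-mer space for every cross-site contig
#' pair. A contig counts as *shared* when it has at least one partner in the
#' other site with J strictly greater than `threshold` (two such contigs are
#' assumed to come from the same or a related population). The overall shared
#' fraction is shared contigs over all contigs, both sites pooled; per-site
#' fractions are reported as well. Contigs shorter than `k` have empty k-mer
#' sets, can never be shared, and stay in the denominator.
#'
#' @param site_a,site_b Named character vectors of contig sequences (the
#'   phylum-unassigned pool of each site); both non-empty.
#' @param k Word size (default 31).
#' @param threshold Similarity cutoff; a pair is similar iff J > threshold
#'   (strict; default 0.1).
#' @param canonical Use canonical k-mers (default TRUE).
#' @param keep_pairs Keep the full cross-site pair table (default TRUE; set
#'   FALSE to save memory on large pools).
#' @return A `contig_similarity` list: `pairs` (data.frame contig_a,
#'   contig_b, jaccard, similar), `shared_ids`, `shared_fraction`
#'   (overall), `shared_fraction_a`, `shared_fraction_b`, `n_unassigned_a`,
#'   `n_unassigned_b`, `n_shared`, `k`, `threshold`, `canonical`.
#' @export
shared_fraction <- function(site_a, site_b, k = 31L, threshold = 0.1,
                            canonical = TRUE, keep_pairs = TRUE) {
  if (length(site_a) == 0L || length(site_b) == 0L) {
    stop_invalid("both sites must contribute at least one contig")
  }
  if (is.null(names(site_a)) || is.null(names(site_b))) {
    stop_invalid("contig vectors must be named by contig id")
  }
  sets <- lapply(c(site_a, site_b), kmer_set, k = k, canonical = canonical)
  ids_a <- names(site_a); ids_b <- names(site_b)
  na <- length(ids_a); nb <- length(ids_b)
  sizes <- lengths(sets)
  if (any(sizes == 0L)) {
    message(sum(sizes == 0L), " contig(s) shorter than k = ", k,
            " have empty k-mer sets and cannot be shared")
  }

  # sparse contig x k-mer membership matrix; cross-product gives all
  # pairwise intersection sizes at once
  universe <- unique(unlist(sets, use.names = FALSE))
  j_idx <- match(unlist(sets, use.names = FALSE), universe)
  i_idx <- rep.int(seq_along(sets), sizes)
  inter <- if (length(universe)) {
    m <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = 1,
                              dims = c(na + nb, length(universe)))
    as.matrix(Matrix::tcrossprod(m[seq_len(na), , drop = FALSE],
                                 m[na + seq_len(nb), , drop = FALSE]))
  } else {
    matrix(0, na, nb)
  }
  union_sz <- outer(sizes[seq_len(na)], sizes[na + seq_len(nb)], "+") - inter
  jac <- ifelse(union_sz > 0, inter / union_sz, 0)
  similar <- jac > threshold

  shared_a <- ids_a[rowSums(similar) > 0]
  shared_b <- ids_b[colSums(similar) > 0]
  pairs <- NULL
  if (keep_pairs) {
    pairs <- data.frame(contig_a = rep(ids_a, times = nb),
                        contig_b = rep(ids_b, each = na),
                        jaccard = as.numeric(jac),
                        similar = as.logical(similar),
                        stringsAsFactors = FALSE)
  }
  structure(list(
    pairs = pairs,
    shared_ids = c(shared_a, shared_b),
    n_unassigned_a = na,
    n_unassigned_b = nb,
    n_shared = length(shared_a) + length(shared_b),
    shared_fraction = (length(shared_a) + length(shared_b)) / (na + nb),
    shared_fraction_a = length(shared_a) / na,
    shared_fraction_b = length(shared_b) / nb,
    k = as.integer(k),
    threshold = threshold,
    canonical = canonical
  ), class = "contig_similarity")
}

#' @export
print.contig_similarity <- function(x, ...) {
  cat("Cross-site contig similarity (k = ", x$k, ", Jaccard > ", x$threshold,
      if (x$canonical) ", canonical k-mers", ")\n", sep = "")
  cat(sprintf("  unassigned contigs: %d (A) + %d (B); shared: %d (%.1f%%)\n",
              x$n_unassigned_a, x$n_unassigned_b, x$n_shared,
              100 * x$shared_fraction))
  cat(sprintf("  per-site shared fraction: A %.3f, B %.3f\n",
              x$shared_fraction_a, x$shared_fraction_b))
  invisible(x)
}

#' Write the pairwise Jaccard table and sharing summary
#'
#' @param result A `contig_similarity`.
#' @param pairs_path,summary_path Output TSV paths (either may be NULL to
#'   skip).
#' @return Invisibly, the summary data.frame.
#' @export
write_similarity <- function(result, pairs_path = NULL, summary_path = NULL) {
  if (!is.null(pairs_path)) {
    if (is.null(result$pairs)) {
      stop_invalid("result was computed with keep_pairs = FALSE")
    }
    write_tsv_commented(result$pairs, pairs_path, "cross-site contig Jaccard")
  }
  summary_df <- data.frame(
    n_unassigned_a = result$n_unassigned_a,
    n_unassigned_b = result$n_unassigned_b,
    n_shared = result$n_shared,
    shared_fraction_overall = result$shared_fraction,
    shared_fraction_a = result$shared_fraction_a,
    shared_fraction_b = result$shared_fraction_b,
    k = result$k, threshold = result$threshold,
    canonical = result$canonical)
  if (!is.null(summary_path)) {
    write_tsv_commented(summary_df, summary_path, "contig sharing summary")
  }
  invisible(summary_df)
}
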