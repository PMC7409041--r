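# Per-ORF TPM abundance and library summary statistics.

#' Per-ORF abundance by the transcripts-per-million (TPM) calculation
#'
#' For each ORF i with mapped-read count r_i and length L_i (kbp), the
#' length-normalised rate is r_i / L_i and
#' \deqn{TPM_i = \frac{r_i / L_i}{\sum_j r_j / L_j} \times 10^6.}
#' The double normalisation — by predicted ORF length in kilobase-pairs and
#' by library size — makes abundances comparable between ORFs of different
#' length and between libraries of different depth. TPM is invariant to
#' uniform rescaling of the counts, so whether reads were counted as mates or
#' as fragments does not change the result.
#'
#' ORFs present in the catalog but absent from `counts` are retained with
#' zero reads and zero TPM.
#'
#' @param counts Named vector of non-negative mapped-read counts (names are
#'   orf_ids); at least one must be positive.
#' @param catalog ORF catalog data.frame with `orf_id` and `length_bp`; every
#'   counted orf_id must have a catalog length.
#' @param site_id Optional site label attached to the result.
#' @return An `abundance_table`: data.frame with columns `orf_id`,
#'   `mapped_reads`, `length_kbp`, `rate`, `tpm`; TPM sums to 1e6.
#' @export
#' @examples
#' cat <- data.frame(orf_id = c("a", "b"), length_bp = c(1000L, 2000L))
#' compute_tpm(c(a = 10, b = 10), cat)
compute_tpm <- function(counts, catalog, site_id = NA_character_) {
  if (is.null(names(counts)) && length(counts) > 0L) {
    stop_invalid("`counts` must be named by orf_id")
  }
  unknown <- setdiff(names(counts), catalog$orf_id)
  if (length(unknown)) {
    stop_invalid("missing length: orf_id(s) without a catalog entry: ",
                 paste(utils::head(unknown, 3L), collapse = ", "))
  }
  if (any(counts < 0)) stop_invalid("counts must be non-negative")
  r <- setNames(numeric(nrow(catalog)), catalog$orf_id)
  r[names(counts)] <- as.numeric(counts)
  if (sum(r) <= 0) {
    stop_invalid("empty library: all counts are zero")
  }
  length_kbp <- catalog$length_bp / 1000
  rate <- r / length_kbp
  tpm <- rate / sum(rate) * 1e6
  structure(
    data.frame(orf_id = catalog$orf_id,
               mapped_reads = as.numeric(r),
               length_kbp = length_kbp,
               rate = rate,
               tpm = tpm,
               row.names = NULL),
    site_id = site_id,
    class = c("abundance_table", "data.frame")
  )
}

#' @export
print.abundance_table <- function(x, ...) {
  site <- attr(x, "site_id")
  cat("TPM abundance table", if (!is.na(site)) paste0("(site ", site, ")"),
      "\n")
  cat("  ", nrow(x), " ORFs, ", sum(x$mapped_reads > 0), " with reads; ",
      "sum(tpm) = ", format(sum(x$tpm)), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("  ... ", nrow(x) - 5L, " more rows\n")
  invisible(x)
}

#' Sequencing library summary
#'
#' @param n_reads Number of reads (>= 1).
#' @param total_bp Total base pairs sequenced.
#' @return List with `n_reads`, `total_bp` and `mean_read_length` (bp,
#'   rounded to the nearest integer).
#' @export
#' @examples
#' library_summary(11614382, 2558493699)$mean_read_length  # 220
library_summary <- function(n_reads, total_bp) {
  if (n_reads < 1) stop_invalid("`n_reads` must be >= 1")
  if (total_bp < 0) stop_invalid("`total_bp` must be non-negative")
  list(n_reads = n_reads, total_bp = total_bp,
       mean_read_length = as.integer(round(total_bp / n_reads)))
}
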