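# Aggregate per-ORF TPM into taxonomy and function profiles — the surrogate
# OTU table used for diversity estimation and the heatmap-ready matrices.

#' Sum ORF TPM by unique taxonomic lineage string
#'
#' Gene TPM values are summed by their full seven-rank lineage identifier
#' (domain;phylum;class;order;family;genus;species), producing the table that
#' stands in for an OTU table downstream. ORFs with an empty lineage
#' accumulate under the all-`unclassified_<rank>` lineage. Total TPM is
#' conserved.
#'
#' @param abundance An `abundance_table` from [compute_tpm()].
#' @param catalog ORF catalog with `orf_id` and `lineage`.
#' @return A `taxon_profile`: data.frame with columns `lineage`, `tpm`,
#'   ordered by decreasing TPM, with the site id carried as an attribute.
#' @export
aggregate_by_lineage <- function(abundance, catalog) {
  lin <- setNames(catalog$lineage, catalog$orf_id)[abundance$orf_id]
  if (anyNA(lin)) stop_invalid("catalog is missing ORFs present in `abundance`")
  lin[!nzchar(lin)] <- pad_lineage(character(0))  # fully unclassified bin
  tpm <- vapply(split(abundance$tpm, lin), sum, 0)
  out <- data.frame(lineage = names(tpm), tpm = as.numeric(tpm),
                    row.names = NULL)
  out <- out[order(-out$tpm, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, site_id = attr(abundance, "site_id"),
            class = c("taxon_profile", "data.frame"))
}

#' @export
print.taxon_profile <- function(x, ...) {
  site <- attr(x, "site_id")
  cat("Taxon profile", if (!is.null(site) && !is.na(site))
    paste0("(site ", site, ")"), "- ", nrow(x), "lineages, total TPM",
    format(sum(x$tpm)), "\n")
  print.data.frame(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("  ... ", nrow(x) - 5L, " more rows\n")
  invisible(x)
}

#' Roll a taxon profile up to one rank
#'
#' Groups lineages by the named rank field and reports summed TPM and
#' relative abundance (percent of total).
#'
#' @param profile A `taxon_profile`.
#' @param rank One of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @return Data.frame with columns `name`, `tpm`, `percent` (summing to 100),
#'   ordered by decreasing TPM.
#' @export
rollup <- function(profile, rank) {
  ranks <- lineage_ranks()
  if (length(rank) != 1L || !rank %in% ranks) {
    stop_invalid("`rank` must be one of: ", paste(ranks, collapse = ", "))
  }
  name <- lineage_matrix(profile$lineage)[, rank]
  tpm <- vapply(split(profile$tpm, name), sum, 0)
  out <- data.frame(name = names(tpm), tpm = as.numeric(tpm),
                    percent = 100 * as.numeric(tpm) / sum(tpm),
                    row.names = NULL)
  out <- out[order(-out$tpm, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sum ORF TPM by function label
#'
#' Scope `"all"` uses every ORF with a non-empty function label; `"viral"`
#' restricts to viral-flagged ORFs (genes identified as viral in origin);
#' `"amg"` restricts further to auxiliary metabolic genes, identified by
#' membership in `amg_labels` or, by default, by an `"AMG:"` label prefix
#' (the convention of the synthetic generator).
#'
#' @param abundance An `abundance_table`.
#' @param catalog ORF catalog with `orf_id`, `function_label`, `viral_flag`.
#' @param scope One of `"viral"`, `"amg"`, `"all"`.
#' @param amg_labels Optional character vector naming AMG function labels.
#' @return A `function_profile`: data.frame with columns `function_label`,
#'   `tpm`; may have zero rows when nothing matches the scope.
#' @export
aggregate_by_function <- function(abundance, catalog,
                                  scope = c("viral", "amg", "all"),
                                  amg_labels = NULL) {
  scope <- match.arg(scope)
  idx <- match(abundance$orf_id, catalog$orf_id)
  if (anyNA(idx)) stop_invalid("catalog is missing ORFs present in `abundance`")
  label <- catalog$function_label[idx]
  viral <- if ("viral_flag" %in% names(catalog)) {
    isTRUE_v <- catalog$viral_flag[idx]
    !is.na(isTRUE_v) & isTRUE_v
  } else rep(FALSE, length(idx))
  keep <- nzchar(label) & !is.na(label)
  if (scope %in% c("viral", "amg")) keep <- keep & viral
  if (scope == "amg") {
    is_amg <- if (is.null(amg_labels)) startsWith(label, "AMG:")
              else label %in% amg_labels
    keep <- keep & is_amg
  }
  tpm <- vapply(split(abundance$tpm[keep], label[keep]), sum, 0)
  out <- data.frame(function_label = names(tpm), tpm = as.numeric(tpm),
                    row.names = NULL)
  out <- out[order(-out$tpm, out$function_label), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, site_id = attr(abundance, "site_id"), scope = scope,
            class = c("function_profile", "data.frame"))
}

#' Joint two-site matrix over the union of keys
#'
#' Combines per-site profiles (taxon or function) into a wide, heatmap-ready
#' matrix whose rows are the union of keys across sites, with explicit zeros
#' where a key is absent from a site — so a gene recovered in one site but
#' not the other shows as 0, not as a missing row.
#'
#' @param profiles Named list of profiles (one per site); each a data.frame
#'   whose first column is the key and which has a `tpm` column.
#' @return Numeric matrix, keys x sites.
#' @export
profile_matrix <- function(profiles) {
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop_invalid("`profiles` must be a named list (names = site ids)")
  }
  keys <- sort(unique(unlist(lapply(profiles, function(p) p[[1L]]))))
  out <- sapply(profiles, function(p) {
    v <- setNames(p$tpm, p[[1L]])[keys]
    v[is.na(v)] <- 0
    as.numeric(v)
  })
  out <- matrix(out, nrow = length(keys),
                dimnames = list(keys, names(profiles)))
  out
}

#' Write a profile as long-form TSV
#'
#' Columns: site, key, tpm, percent.
#'
#' @param profile A `taxon_profile` or `function_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  site <- attr(profile, "site_id")
  df <- data.frame(site = if (is.null(site)) NA_character_ else site,
                   key = profile[[1L]],
                   tpm = profile$tpm,
                   percent = 100 * profile$tpm / sum(profile$tpm))
  write_tsv_commented(df, path, "abundance profile (long form)")
}
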