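# Virus/picoplankton summary statistics and cross-site report assembly.

#' Virus-to-picoplankton ratio (VPR)
#'
#' Dimensionless ratio of virus-like-particle concentration to picoplankton
#' cell concentration, both per mL.
#'
#' @param vlp_per_ml VLP concentration (> 0).
#' @param cells_per_ml Picoplankton concentration (> 0).
#' @return vlp_per_ml / cells_per_ml.
#' @export
#' @examples
#' vpr(2.5e6, 2.1e5)
vpr <- function(vlp_per_ml, cells_per_ml) {
  if (any(!is.finite(vlp_per_ml)) || any(vlp_per_ml <= 0) ||
      any(!is.finite(cells_per_ml)) || any(cells_per_ml <= 0)) {
    stop_invalid("`vlp_per_ml` and `cells_per_ml` must be positive")
  }
  vlp_per_ml / cells_per_ml
}

#' Assemble a cross-site report
#'
#' Combines site metadata (with derived VPR and mean read length), taxon
#' rollups, alpha diversity and the contig-sharing summary into one
#' structured report. A missing component is recorded as absent rather than
#' failing.
#'
#' @param sites Site metadata data.frame (see [read_sites()]), or NULL.
#' @param profiles Named list of `taxon_profile`s (names = site ids), or NULL.
#' @param diversity Data.frame of stacked `diversity_result` rows, or NULL.
#' @param similarity A `contig_similarity`, or NULL.
#' @param rank Rank for the taxon rollup excerpt (default `"phylum"`).
#' @return A `virome_report` list with sections `sites`, `taxa`, `diversity`,
#'   `similarity`; absent sections are NULL and listed in the `absent`
#'   attribute.
#' @export
build_report <- function(sites = NULL, profiles = NULL, diversity = NULL,
                         similarity = NULL, rank = "phylum") {
  site_section <- NULL
  if (!is.null(sites)) {
    site_section <- sites
    if (all(c("vlp_per_ml", "cells_per_ml") %in% names(sites))) {
      site_section$vpr <- vpr(sites$vlp_per_ml, sites$cells_per_ml)
    }
    if (all(c("n_reads", "total_bp") %in% names(sites))) {
      site_section$mean_read_length <-
        as.integer(round(sites$total_bp / sites$n_reads))
    }
  }
  taxa_section <- NULL
  if (!is.null(profiles)) {
    taxa_section <- do.call(rbind, lapply(names(profiles), function(s) {
      r <- rollup(profiles[[s]], rank)
      data.frame(site_id = s, rank = rank, r, stringsAsFactors = FALSE)
    }))
  }
  sim_section <- if (!is.null(similarity)) write_similarity(similarity)
  div_section <- NULL
  if (!is.null(diversity)) {
    div_section <- as.data.frame(diversity)
    rownames(div_section) <- NULL
  }
  sections <- list(sites = site_section, taxa = taxa_section,
                   diversity = div_section, similarity = sim_section)
  structure(sections,
            absent = names(sections)[vapply(sections, is.null, TRUE)],
            class = "virome_report")
}

#' @export
print.virome_report <- function(x, ...) {
  cat("Two-site virome report\n")
  for (s in names(x)) {
    if (is.null(x[[s]])) {
      cat("  ", s, ": absent\n", sep = "")
    } else {
      cat("  ", s, ": ", nrow(x[[s]]), " row(s)\n", sep = "")
    }
  }
  invisible(x)
}

#' Write a report to a directory of TSV sections plus a JSON summary
#'
#' Each present section becomes `<dir>/<section>.tsv`; `report.json` records
#' the section inventory and headline numbers.
#'
#' @param report A `virome_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(report)) {
    if (!is.null(report[[s]])) {
      write_tsv_commented(report[[s]], file.path(dir, paste0(s, ".tsv")),
                          paste("report section:", s))
    }
  }
  summary <- list(
    sections_present = setdiff(names(report), attr(report, "absent")),
    sections_absent = attr(report, "absent"))
  if (!is.null(report$similarity)) {
    summary$shared_fraction <- report$similarity$shared_fraction_overall
  }
  if (!is.null(report$sites) && "vpr" %in% names(report$sites)) {
    summary$vpr <- setNames(as.list(report$sites$vpr), report$sites$site_id)
  }
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a report directory back
#'
#' @param dir Directory written by [write_report()].
#' @return A `virome_report` with the sections found on disk.
#' @export
read_report <- function(dir) {
  sections <- c("sites", "taxa", "diversity", "similarity")
  out <- setNames(vector("list", length(sections)), sections)
  for (s in sections) {
    p <- file.path(dir, paste0(s, ".tsv"))
    if (file.exists(p)) out[[s]] <- read_tsv_commented(p)
  }
  structure(out, absent = sections[vapply(out, is.null, TRUE)],
            class = "virome_report")
}

#' Run the full synthetic two-site study
#'
#' Orchestrates synthetic data generation, TPM abundance, taxonomy profiles,
#' alpha diversity, cross-site contig sharing, and report assembly, all from
#' one seed. Intended both as the end-to-end example and as the integration
#' surface the command-line wrapper calls.
#'
#' @param seed Integer master seed.
#' @param sites Optional site metadata data.frame (two rows with site_id
#'   matching `"A"`, `"B"`); defaults to plausible wetland values.
#' @param k,threshold Contig-sharing parameters.
#' @param ... Passed to [simulate_two_site_dataset()].
#' @return List: `dataset`, `abundance` (per site), `profiles` (per site),
#'   `diversity`, `similarity`, `report`.
#' @export
run_pipeline <- function(seed, sites = NULL, k = 31L, threshold = 0.1, ...) {
  ds <- simulate_two_site_dataset(seed = seed, ...)
  abundance <- lapply(setNames(names(ds$counts), names(ds$counts)),
                      function(s) compute_tpm(ds$counts[[s]], ds$catalog,
                                              site_id = s))
  profiles <- lapply(abundance, aggregate_by_lineage, catalog = ds$catalog)
  diversity <- do.call(rbind, lapply(profiles, alpha_diversity))
  similarity <- shared_fraction(ds$contigs$A, ds$contigs$B, k = k,
                                threshold = threshold, keep_pairs = FALSE)
  if (is.null(sites)) {
    sites <- data.frame(site_id = c("A", "B"),
                        vlp_per_ml = c(2.0e6, 1.5e6),
                        cells_per_ml = c(2.5e5, 4.0e5),
                        n_reads = rep(ds$truth$library_size, 2L),
                        total_bp = round(rep(ds$truth$library_size, 2L) * 220))
  }
  report <- build_report(sites = sites, profiles = profiles,
                         diversity = diversity, similarity = similarity)
  list(dataset = ds, abundance = abundance, profiles = profiles,
       diversity = diversity, similarity = similarity, report = report)
}
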