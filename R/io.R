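# Readers/writers for the formats the pipeline touches, with strict
# validation. FASTA goes through Biostrings; tables are TSV with a header and
# an optional leading "#" comment line recording tool version and parameters.

orf_required_cols <- c("orf_id", "contig_id", "start", "end", "strand",
                       "length_bp", "lineage", "function_label")

write_tsv_commented <- function(df, path, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# viromics %s | %s | written %s", viromics_version(),
                     what, format(Sys.time(), "%Y-%m-%d")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

check_columns <- function(df, required, optional = character(), path) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_invalid("format error in ", path, ": missing required column(s) ",
                 paste(missing, collapse = ", "))
  }
  unknown <- setdiff(names(df), c(required, optional))
  if (length(unknown)) {
    warning("ignoring unknown column(s) in ", basename(path), ": ",
            paste(unknown, collapse = ", "), call. = FALSE)
    df <- df[c(required, intersect(optional, names(df)))]
  }
  df
}

#' Read a DNA FASTA file
#'
#' Wraps [Biostrings::readDNAStringSet()] and validates the result: ids must
#' be unique, sequences non-empty and over the alphabet A/C/G/T/N
#' (case-insensitive; output is uppercased). Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))  # id = first whitespace token
  if (anyDuplicated(ids)) {
    stop_invalid("format error in ", path, ": duplicate sequence id '",
                 ids[duplicated(ids)][1L], "'")
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop_invalid("format error in ", path, ": empty sequence for id '",
                 ids[!nzchar(seqs)][1L], "'")
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop_invalid("format error in ", path, ": sequence '", ids[bad][1L],
                 "' contains characters outside A/C/G/T/N")
  }
  setNames(seqs, ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop_invalid("`seqs` must be a named character vector")
  }
  set <- Biostrings::DNAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

validate_orf_table <- function(df, path = "<orf table>") {
  df$start <- suppressWarnings(as.integer(df$start))
  df$end <- suppressWarnings(as.integer(df$end))
  df$length_bp <- suppressWarnings(as.integer(df$length_bp))
  if (!"viral_flag" %in% names(df)) df$viral_flag <- FALSE
  df$viral_flag <- as.logical(df$viral_flag)
  df$lineage[is.na(df$lineage)] <- ""
  df$function_label[is.na(df$function_label)] <- ""
  if (anyDuplicated(df$orf_id)) {
    stop_invalid("format error in ", path, ": duplicate orf_id '",
                 df$orf_id[duplicated(df$orf_id)][1L], "'")
  }
  has_coord <- !is.na(df$start) & !is.na(df$end)
  if (any(has_coord & df$end < df$start)) {
    bad <- which(has_coord & df$end < df$start)[1L]
    stop_invalid("format error in ", path, ": end < start for orf '",
                 df$orf_id[bad], "' (row ", bad, ")")
  }
  if (any(has_coord & df$length_bp != df$end - df$start + 1L)) {
    bad <- which(has_coord & df$length_bp != df$end - df$start + 1L)[1L]
    stop_invalid("format error in ", path, ": length_bp != end - start + 1 ",
                 "for orf '", df$orf_id[bad], "' (coordinates are 1-based inclusive)")
  }
  if (any(df$length_bp < 3L, na.rm = TRUE)) {
    stop_invalid("format error in ", path, ": length_bp < 3")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop_invalid("format error in ", path, ": strand must be '+' or '-'")
  }
  nonempty <- nzchar(df$lineage)
  if (any(nonempty)) {
    nf <- lengths(strsplit(df$lineage[nonempty], ";", fixed = TRUE))
    if (any(nf != 7L)) {
      bad <- which(nonempty)[nf != 7L][1L]
      stop_invalid("format error in ", path, ": lineage must have exactly 7 ",
                   "fields, found ", nf[nf != 7L][1L], " for orf '",
                   df$orf_id[bad], "' (row ", bad, ")")
    }
  }
  df
}

#' Read an ORF catalog table
#'
#' Tab-separated with header columns `orf_id`, `contig_id`, `start`, `end`,
#' `strand`, `length_bp`, `lineage`, `function_label` (optional
#' `viral_flag`). Coordinates are 1-based inclusive; `length_bp` must equal
#' `end - start + 1`; non-empty lineages must have exactly 7 fields. Unknown
#' columns are dropped with a warning.
#'
#' @param path Path to the TSV file.
#' @return Validated data.frame of ORF records.
#' @export
read_orf_table <- function(path) {
  df <- read_tsv_commented(path)
  df <- check_columns(df, orf_required_cols, optional = "viral_flag", path)
  validate_orf_table(df, path)
}

#' Write an ORF catalog table
#' @param catalog ORF catalog data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orf_table <- function(catalog, path) {
  cols <- c(orf_required_cols, "viral_flag")
  catalog <- validate_orf_table(catalog)
  write_tsv_commented(catalog[intersect(cols, names(catalog))], path,
                      "ORF catalog")
}

#' Read a per-ORF mapped-read count table
#'
#' TSV with header columns `orf_id` and `count`; counts must be non-negative
#' integers.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector of counts.
#' @export
read_counts <- function(path) {
  df <- read_tsv_commented(path)
  df <- check_columns(df, c("orf_id", "count"), path = path)
  counts <- suppressWarnings(as.numeric(df$count))
  if (anyNA(counts)) {
    stop_invalid("format error in ", path, ": non-numeric count for orf '",
                 df$orf_id[is.na(counts)][1L], "'")
  }
  if (any(counts < 0)) {
    stop_invalid("format error in ", path, ": negative count for orf '",
                 df$orf_id[counts < 0][1L], "'")
  }
  if (any(counts != round(counts))) {
    stop_invalid("format error in ", path, ": counts must be integers ",
                 "(TPM values are reals and never share a column with counts)")
  }
  if (anyDuplicated(df$orf_id)) {
    stop_invalid("format error in ", path, ": duplicate orf_id")
  }
  setNames(as.integer(counts), df$orf_id)
}

#' Write a per-ORF count table
#' @param counts Named integer vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  write_tsv_commented(data.frame(orf_id = names(counts),
                                 count = as.integer(counts)),
                      path, "mapped-read counts")
}

site_numeric_cols <- c("vlp_per_ml", "cells_per_ml", "conductivity",
                       "temperature", "ph", "oxygen", "phosphate",
                       "n_reads", "total_bp")

#' Read a site metadata table
#'
#' TSV with header; requires `site_id`, accepts the numeric columns
#' `vlp_per_ml`, `cells_per_ml` (virus-like particles and picoplankton cells
#' per mL), `conductivity` (uS/cm), `temperature` (C), `ph`, `oxygen` (mg/L),
#' `phosphate` (mg/L), `n_reads`, `total_bp`. VLP and cell concentrations
#' must be positive when present.
#'
#' @param path Path to the TSV file.
#' @return Data.frame of site records.
#' @export
read_sites <- function(path) {
  df <- read_tsv_commented(path)
  df <- check_columns(df, "site_id", optional = site_numeric_cols, path)
  for (col in intersect(site_numeric_cols, names(df))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  for (col in intersect(c("vlp_per_ml", "cells_per_ml"), names(df))) {
    if (any(df[[col]] <= 0, na.rm = TRUE)) {
      stop_invalid("format error in ", path, ": ", col, " must be > 0")
    }
  }
  df
}

#' Write a site metadata table
#' @param sites Data.frame of site records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  write_tsv_commented(sites, path, "site metadata")
}
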