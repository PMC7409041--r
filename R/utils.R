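# Internal helpers: seeded RNG scoping, lineage strings, reverse complement.

#' @noRd
stop_invalid <- function(...) stop(..., call. = FALSE)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop_invalid("`seed` must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Fan one user-facing seed out into named per-stage child seeds so each
# pipeline stage is independently reproducible.
child_seeds <- function(seed, stages) {
  with_seed(seed, setNames(sample.int(.Machine$integer.max, length(stages)),
                           stages))
}

#' Taxonomic rank names used throughout the package
#'
#' Lineage strings are semicolon-delimited with exactly seven fields, in this
#' order: domain, phylum, class, order, family, genus, species.
#'
#' @return Character vector of the seven rank names.
#' @export
#' @examples
#' lineage_ranks()
lineage_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Pad a partial lineage to seven ranks
#'
#' Unknown ranks are filled with `"unclassified_<rank>"`, so that e.g. a
#' domain-only assignment survives a domain rollup yet counts as unassigned
#' at phylum.
#'
#' @param fields Character vector of known rank names, outermost first
#'   (at most seven).
#' @return A seven-field semicolon-delimited lineage string.
#' @export
#' @examples
#' pad_lineage("Bacteria")
pad_lineage <- function(fields) {
  ranks <- lineage_ranks()
  if (length(fields) > length(ranks)) {
    stop_invalid("a lineage has at most ", length(ranks), " ranks")
  }
  full <- paste0("unclassified_", ranks)
  full[seq_along(fields)] <- fields
  paste(full, collapse = ";")
}

# Split lineage strings into an n x 7 character matrix; empty lineages
# become all-"unclassified_<rank>" rows.
lineage_matrix <- function(lineages) {
  ranks <- lineage_ranks()
  out <- matrix(rep(paste0("unclassified_", ranks), each = length(lineages)),
                nrow = length(lineages), ncol = length(ranks),
                dimnames = list(NULL, ranks))
  nonempty <- !is.na(lineages) & nzchar(lineages)
  if (any(nonempty)) {
    parts <- strsplit(lineages[nonempty], ";", fixed = TRUE)
    bad <- lengths(parts) != length(ranks)
    if (any(bad)) {
      stop_invalid("lineage must have exactly ", length(ranks),
                   " ';'-delimited fields (offending value: '",
                   lineages[nonempty][bad][1L], "')")
    }
    out[nonempty, ] <- do.call(rbind, parts)
  }
  out
}

# TRUE for lineages with no phylum-level assignment (empty, or phylum field
# "unclassified_phylum").
is_phylum_unassigned <- function(lineages) {
  empty <- is.na(lineages) | !nzchar(lineages)
  phylum <- rep("unclassified_phylum", length(lineages))
  if (any(!empty)) phylum[!empty] <- lineage_matrix(lineages[!empty])[, "phylum"]
  empty | phylum == "unclassified_phylum" | phylum == ""
}

# Vectorised reverse complement of fixed-width uppercase DNA strings.
revcomp_fixed <- function(x, k) {
  comp <- chartr("ACGTN", "TGCAN", x)
  do.call(paste0, lapply(rev(seq_len(k)), function(j) substr(comp, j, j)))
}
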