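# Richness and alpha diversity on the TPM-derived surrogate count table.
#
# The lineage-summed TPM table stands in for an OTU count table. Chao1 needs
# integer counts, so TPM values are rounded, with lineages that would round
# to zero floored to 1 (observed richness then equals the number of lineages
# with positive abundance).

#' Integerise a taxon profile into a surrogate count table
#'
#' @param profile A `taxon_profile` (lineage, tpm) or any data.frame with a
#'   `tpm` column and a key in the first column.
#' @return Named integer vector; lineages with zero TPM are excluded, and
#'   positive TPM below 0.5 is floored to a count of 1.
#' @export
#' @examples
#' surrogate_counts(data.frame(lineage = c("A", "B"), tpm = c(2.6, 0.2)))
surrogate_counts <- function(profile) {
  if (nrow(profile) == 0L) stop_invalid("`profile` must be non-empty")
  tpm <- profile$tpm
  keep <- tpm > 0
  counts <- as.integer(pmax(1L, round(tpm[keep])))
  setNames(counts, profile[[1L]][keep])
}

#' Shannon diversity index
#'
#' H = -sum p_i log(p_i) with p_i the relative abundances, computed through
#' the standard community-ecology toolkit (natural log by default).
#'
#' @param counts Numeric vector of non-negative abundances, at least one
#'   positive.
#' @param base Logarithm base (default natural log, giving H in nats).
#' @return Shannon index H.
#' @export
#' @examples
#' shannon(rep(5, 4))  # log(4)
shannon <- function(counts, base = exp(1)) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) {
    stop_invalid("`counts` must contain at least one positive value")
  }
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' Chao1 richness estimator
#'
#' Nonparametric richness from singleton (F1) and doubleton (F2) counts:
#' classic form S + F1^2 / (2 F2); bias-corrected form (the default)
#' S + F1 (F1 - 1) / (2 (F2 + 1)). When F2 = 0 the classic form is undefined
#' and falls back to the bias-corrected form with a warning.
#'
#' @param counts Integer abundance vector.
#' @param variant `"bias-corrected"` (default) or `"classic"`.
#' @return Estimated richness (>= observed richness).
#' @export
#' @examples
#' chao1(c(1, 1, 2, 3, 3))                      # 5.5
#' chao1(c(1, 1, 2, 3, 3), variant = "classic") # 7
chao1 <- function(counts, variant = c("bias-corrected", "classic")) {
  variant <- match.arg(variant)
  counts <- counts[counts > 0]
  if (any(counts != round(counts))) {
    stop_invalid("chao1 requires integer counts; integerise TPM with surrogate_counts()")
  }
  s <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (variant == "classic") {
    if (f2 > 0) return(s + f1^2 / (2 * f2))
    warning("F2 = 0: classic Chao1 undefined, falling back to bias-corrected",
            call. = FALSE)
  }
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Evenness as Shannon index over observed richness
#'
#' E = H / S. This is the evenness definition consistent with the package's
#' reference tables; it differs from Pielou's J = H / ln(S), which
#' [alpha_diversity()] reports alongside.
#'
#' @param h Shannon index.
#' @param s Observed richness (>= 1).
#' @return E = H / S.
#' @export
#' @examples
#' signif(evenness(4.381, 2209), 3)  # 0.00198
evenness <- function(h, s) {
  if (any(s < 1)) stop_invalid("`s` must be >= 1")
  h / s
}

#' Pielou's evenness J = H / ln(S)
#' @param h Shannon index (nats).
#' @param s Observed richness (>= 1).
#' @return J, or 0 when S = 1.
#' @export
pielou <- function(h, s) {
  if (any(s < 1)) stop_invalid("`s` must be >= 1")
  ifelse(s == 1, 0, h / log(s))
}

#' Alpha diversity of a taxon profile
#'
#' Builds the surrogate count table with [surrogate_counts()] and reports
#' observed richness, Shannon (nats), Chao1, evenness (H/S) and Pielou's J.
#'
#' @param profile A `taxon_profile`.
#' @param chao1_variant Passed to [chao1()].
#' @return A `diversity_result`: one-row data.frame with columns `site_id`,
#'   `observed`, `shannon`, `chao1`, `evenness`, `pielou`, `chao1_variant`.
#' @export
alpha_diversity <- function(profile,
                            chao1_variant = c("bias-corrected", "classic")) {
  chao1_variant <- match.arg(chao1_variant)
  counts <- surrogate_counts(profile)
  s <- length(counts)
  h <- if (s == 1L) 0 else shannon(counts)
  site <- attr(profile, "site_id")
  structure(
    data.frame(site_id = if (is.null(site)) NA_character_ else site,
               observed = s,
               shannon = h,
               chao1 = chao1(counts, chao1_variant),
               evenness = evenness(h, s),
               pielou = pielou(h, s),
               chao1_variant = chao1_variant,
               stringsAsFactors = FALSE),
    class = c("diversity_result", "data.frame")
  )
}

#' @export
print.diversity_result <- function(x, ...) {
  cat("Alpha diversity (TPM surrogate count table; chao1:",
      x$chao1_variant[1L], ")\n")
  print.data.frame(as.data.frame(x)[
    c("site_id", "observed", "shannon", "chao1", "evenness", "pielou")])
  invisible(x)
}
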