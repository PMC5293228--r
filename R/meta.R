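#' Sample-size-weighted z-score meta-analysis
#'
#' Combines per-study z-scores for one SNP with weights proportional to the
#' square root of the sample size, the sample-size-based scheme of METAL:
#' \deqn{z_{meta} = \sum_i w_i z_i / \sqrt{\sum_i w_i^2}, \quad w_i = \sqrt{N_i}.}
#' With `weight = "effective"` the effective case-control sample size
#' \eqn{4 / (1/n_{case} + 1/n_{control})} replaces the total N. Alleles
#' must already be harmonized to a common effect allele (see
#' [harmonize()]); a mismatch is an error, never silently dropped.
#'
#' @param records [sumstats]-style data.frame, one row per study, all rows
#'   the same SNP.
#' @param weight `"total"` (default) or `"effective"`.
#' @return one-row data.frame `snp_id`, `z_meta`, `p_meta`, `n_studies`,
#'   plus the weights used in attribute `"weights"`.
#' @export
meta_combine <- function(records, weight = c("total", "effective")) {
  weight <- match.arg(weight)
  if (nrow(records) < 1) stop("meta_combine: need at least one study")
  if (length(unique(records$snp_id)) != 1)
    stop("meta_combine: records must all describe the same SNP")
  if (length(unique(records$allele1)) != 1 ||
      length(unique(records$allele2)) != 1)
    stop("meta_combine: alleles not harmonized for ", records$snp_id[1],
         "; run harmonize() first")
  n <- if (weight == "total") records$n_case + records$n_control
       else 4 / (1 / records$n_case + 1 / records$n_control)
  if (any(is.na(n) | n <= 0))
    stop("meta_combine: missing or non-positive sample sizes")
  w <- sqrt(n)
  z <- sum(w * records$z) / sqrt(sum(w^2))
  out <- data.frame(snp_id = records$snp_id[1], z_meta = z,
                    p_meta = 2 * stats::pnorm(-abs(z)),
                    n_studies = nrow(records), stringsAsFactors = FALSE)
  attr(out, "weights") <- w
  out
}

#' Meta-analyze two (or more) studies across all SNPs
#'
#' Harmonizes each shared SNP to the first study's effect allele, then
#' applies [meta_combine()]. SNPs present in a single study are carried
#' through as that study unless `require_all = TRUE`, which restricts to
#' the intersection.
#'
#' @param studies list of [sumstats] tables.
#' @param weight see [meta_combine()].
#' @param require_all keep only SNPs present in every study.
#' @param drop_ambiguous drop strand-ambiguous SNPs before combining.
#' @return [sumstats] table of meta-analysis results (alleles of the first
#'   study supplying each SNP; `n_case`/`n_control` summed over studies).
#' @export
meta_analyze <- function(studies, weight = "total", require_all = FALSE,
                         drop_ambiguous = FALSE) {
  stopifnot(length(studies) >= 1)
  ids <- unique(unlist(lapply(studies, `[[`, "snp_id")))
  if (require_all)
    ids <- Reduce(intersect, lapply(studies, `[[`, "snp_id"))
  rows <- lapply(ids, function(id) {
    recs <- lapply(studies, function(s) s[s$snp_id == id, , drop = FALSE])
    recs <- recs[vapply(recs, nrow, integer(1)) == 1]
    ref <- recs[[1]]
    if (drop_ambiguous && is_strand_ambiguous(ref$allele1, ref$allele2))
      return(NULL)
    aligned <- lapply(recs, function(r) harmonize(ref, r)$b)
    stacked <- do.call(rbind, aligned)
    m <- meta_combine(stacked, weight = weight)
    data.frame(snp_id = id, chrom = ref$chrom, pos = ref$pos,
               allele1 = ref$allele1, allele2 = ref$allele2,
               z = m$z_meta, p = m$p_meta,
               n_case = sum(stacked$n_case), n_control = sum(stacked$n_control),
               accuracy = min(stacked$accuracy),
               n_studies = m$n_studies, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  validate_sumstats(out)
}
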