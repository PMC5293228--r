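#' Map index SNPs into a target study
#'
#' Filters an index-SNP list to variants that can be looked up in a target
#' study: X-chromosomal variants are excluded (cannot be imputed by the
#' autosomal pipeline), then insertions/deletions (any allele longer than
#' one base, or a symbolic allele such as `I`, `D`, `<DEL>`), and the
#' remainder is intersected with the target study's SNP ids. The tally of
#' each exclusion class is returned alongside.
#'
#' @param index_list [sumstats] table of index SNPs.
#' @param target_study [sumstats] table (or any data.frame with `snp_id`)
#'   to intersect with; `NULL` skips the intersection.
#' @return list with `mapped` (surviving rows) and `tally` (named counts:
#'   `n_input`, `n_excluded_x`, `n_excluded_indel`, `n_mapped`,
#'   `n_absent`, `n_tested`).
#' @export
map_snps <- function(index_list, target_study = NULL) {
  n_input <- nrow(index_list)
  on_x <- toupper(index_list$chrom) %in% c("X", "23")
  x <- index_list[!on_x, , drop = FALSE]
  is_indel <- nchar(x$allele1) > 1 | nchar(x$allele2) > 1 |
    !(x$allele1 %in% names(DNA_COMPLEMENT)) |
    !(x$allele2 %in% names(DNA_COMPLEMENT))
  mapped <- x[!is_indel, , drop = FALSE]
  n_mapped <- nrow(mapped)
  n_absent <- 0L
  if (!is.null(target_study)) {
    present <- mapped$snp_id %in% target_study$snp_id
    n_absent <- sum(!present)
    mapped <- mapped[present, , drop = FALSE]
  }
  class(mapped) <- class(index_list)
  list(mapped = mapped,
       tally = c(n_input = n_input, n_excluded_x = sum(on_x),
                 n_excluded_indel = sum(is_indel), n_mapped = n_mapped,
                 n_absent = n_absent, n_tested = nrow(mapped)))
}

#' Count nominally significant p-values
#'
#' Strict inequality: p-values exactly at `alpha` do not count.
#'
#' @param p p-values in \[0, 1\].
#' @param alpha nominal significance level in (0, 1), default 0.05.
#' @return integer count of `p < alpha`.
#' @export
count_nominal <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  sum(p < alpha, na.rm = TRUE)
}

#' Binomial enrichment test for shared loci
#'
#' Upper-tail probability that at least `k` of `n` independent index SNPs
#' reach nominal significance when each does so with probability `p0`
#' under the null: `P(X >= k)`, `X ~ Binomial(n, p0)`, computed exactly.
#'
#' @param k observed count of nominal hits.
#' @param n number of SNPs tested.
#' @param p0 null per-SNP hit probability (the nominal alpha).
#' @return upper-tail p-value.
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (k < 0 || k > n) stop("need 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' `min(1, m * p)`, monotone in both arguments. Display layers render
#' values above 0.9999 as `">0.9999"`; see [format_bonferroni()].
#'
#' @param p nominal p-value(s).
#' @param m number of tests (>= 1).
#' @export
bonferroni <- function(p, m) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}

#' @rdname bonferroni
#' @param digits decimal places for display.
#' @export
format_bonferroni <- function(p, digits = 4) {
  ifelse(p > 0.9999, ">0.9999", formatC(p, digits = digits, format = "f"))
}

#' Direction concordance between two harmonized z-score sets
#'
#' Fraction of SNP pairs whose z-scores agree in sign. A zero z-score in
#' either study counts as discordant and is flagged.
#'
#' @param z1,z2 harmonized z-score vectors of equal length.
#' @return list with `fraction`, per-SNP logical `concordant`, and
#'   logical `zero_flag`.
#' @export
direction_concordance <- function(z1, z2) {
  stopifnot(length(z1) == length(z2))
  zero <- z1 == 0 | z2 == 0
  conc <- sign(z1) == sign(z2) & !zero
  list(fraction = mean(conc), concordant = conc, zero_flag = zero)
}

#' Build a shared-locus report
#'
#' Assembles the per-SNP table and summary counts of the shared-locus
#' analysis: each index SNP's corrected p-value in the target study, its
#' Bonferroni-corrected value at `m` tests, optional nearby-gene
#' annotation, the nominal and Bonferroni hit counts, and the binomial
#' enrichment p-value of the nominal count. Rows are sorted by ascending
#' corrected p, ties broken by chromosome then position. The nominal-only
#' subset (`table_nominal`) mirrors a headline hits table; `table_full`
#' keeps every tested SNP.
#'
#' @param mapped [sumstats] rows for the tested index SNPs.
#' @param p_corrected corrected p-values aligned with `mapped`.
#' @param p_source p-values of the same SNPs in the source (discovery)
#'   study, optional.
#' @param m Bonferroni test count (includes both lookup directions when
#'   the analysis is run both ways).
#' @param alpha nominal level for hit counting.
#' @param tally exclusion tally from [map_snps()], optional.
#' @param genes optional gene annotation data.frame (`gene_id`, `chrom`,
#'   `start`, `end`) used to label each SNP with the nearest overlapping
#'   or flanking gene.
#' @param gene_flank_bp flank for the nearby-gene join, default 50000.
#' @return object of class `shared_locus_report`.
#' @export
build_report <- function(mapped, p_corrected, p_source = NULL, m,
                         alpha = 0.05, tally = NULL, genes = NULL,
                         gene_flank_bp = 50000) {
  stopifnot(nrow(mapped) == length(p_corrected))
  rows <- data.frame(
    snp_id = mapped$snp_id, chrom = mapped$chrom, pos = mapped$pos,
    allele1 = mapped$allele1, allele2 = mapped$allele2,
    p_corrected = p_corrected,
    p_bonferroni = bonferroni(p_corrected, m),
    p_source_study = if (is.null(p_source)) NA_real_ else p_source,
    stringsAsFactors = FALSE)
  rows$nearby_gene <- NA_character_
  if (!is.null(genes) && nrow(rows) > 0) {
    gr_snp <- GenomicRanges::GRanges(
      rows$chrom, IRanges::IRanges(rows$pos, rows$pos))
    gr_gene <- GenomicRanges::GRanges(
      sub("^chr", "", genes$chrom),
      IRanges::IRanges(pmax(1, genes$start - gene_flank_bp),
                       genes$end + gene_flank_bp))
    hits <- GenomicRanges::findOverlaps(gr_snp, gr_gene)
    for (i in unique(S4Vectors::queryHits(hits))) {
      g <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
      rows$nearby_gene[i] <- paste(genes$gene_id[g], collapse = ",")
    }
  }
  ord <- order(rows$p_corrected, rows$chrom, rows$pos)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  n_tested <- nrow(rows)
  n_nominal <- count_nominal(rows$p_corrected, alpha)
  counts <- c(
    if (!is.null(tally)) tally[c("n_input", "n_excluded_x",
                                 "n_excluded_indel", "n_mapped")]
    else c(n_input = n_tested, n_excluded_x = 0L,
           n_excluded_indel = 0L, n_mapped = n_tested),
    n_tested = n_tested, n_nominal = n_nominal,
    n_bonferroni = count_nominal(rows$p_bonferroni, alpha))
  structure(list(
    table_full = rows,
    table_nominal = rows[rows$p_corrected < alpha, , drop = FALSE],
    counts = counts, m = m, alpha = alpha,
    enrichment_p = binomial_enrichment(n_nominal, n_tested, alpha)),
    class = "shared_locus_report")
}

#' @export
print.shared_locus_report <- function(x, ...) {
  cat("Shared-locus report\n")
  cat(sprintf("  %d input, %d on X, %d indels -> %d mappable, %d tested\n",
              x$counts["n_input"], x$counts["n_excluded_x"],
              x$counts["n_excluded_indel"], x$counts["n_mapped"],
              x$counts["n_tested"]))
  cat(sprintf("  %d of %d nominal at alpha = %g (binomial p = %.3g)\n",
              x$counts["n_nominal"], x$counts["n_tested"], x$alpha,
              x$enrichment_p))
  cat(sprintf("  %d survive Bonferroni at m = %d\n",
              x$counts["n_bonferroni"], x$m))
  invisible(x)
}

#' Write a shared-locus report to a directory
#'
#' Emits `shared_loci_full.tsv`, `shared_loci_nominal.tsv` (with
#' display-formatted Bonferroni column) and `summary.json`.
#'
#' @param report a `shared_locus_report`.
#' @param dir output directory, created if needed.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(tab) {
    tab$p_bonferroni_display <- format_bonferroni(tab$p_bonferroni)
    tab
  }
  utils::write.table(fmt(report$table_full),
                     file.path(dir, "shared_loci_full.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(report$table_nominal),
                     file.path(dir, "shared_loci_nominal.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(as.list(report$counts),
      list(m = report$m, alpha = report$alpha,
           enrichment_p = report$enrichment_p)),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
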