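#' LD block: SNP metadata plus a pairwise correlation matrix
#'
#' The reference-panel unit: an ordered set of SNPs with their allelic
#' correlation matrix r. The matrix must be symmetric with unit diagonal;
#' if it is not positive semi-definite within tolerance it is repaired by
#' clipping negative eigenvalues at zero and restoring the unit diagonal.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `allele1`, `allele2`.
#' @param corr square numeric matrix of correlations, dimension `nrow(snps)`.
#' @param tol eigenvalue tolerance below which repair is triggered.
#' @return an `ld_block` object.
#' @export
ld_block <- function(snps, corr, tol = 1e-8) {
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || nrow(corr) != nrow(snps))
    stop("ld_block: correlation matrix dimensions must match SNP count")
  if (max(abs(corr - t(corr))) > 1e-8)
    stop("ld_block: correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    stop("ld_block: correlation matrix must have unit diagonal")
  if (any(abs(corr) > 1 + 1e-8))
    stop("ld_block: correlations must lie in [-1, 1]")
  ev <- eigen(corr, symmetric = TRUE)
  if (min(ev$values) < -tol) {
    vals <- pmax(ev$values, 0)
    corr <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(corr))
    corr <- corr / tcrossprod(d)
    diag(corr) <- 1
    corr <- (corr + t(corr)) / 2
  }
  dimnames(corr) <- list(snps$snp_id, snps$snp_id)
  structure(list(snps = as.data.frame(snps), corr = corr),
            class = "ld_block")
}

#' @export
print.ld_block <- function(x, ...) {
  cat(sprintf("LD block: %d SNPs on chr%s, %d-%d\n", nrow(x$snps),
              x$snps$chrom[1], min(x$snps$pos), max(x$snps$pos)))
  invisible(x)
}

block_index <- function(block, snp_id) {
  i <- match(snp_id, block$snps$snp_id)
  if (any(is.na(i)))
    stop("SNP(s) not in block: ", paste(snp_id[is.na(i)], collapse = ", "))
  i
}

#' Pairwise r-squared between two SNPs of one block
#'
#' @param block an [ld_block].
#' @param id_a,id_b SNP ids present in the block.
#' @return squared correlation in \[0, 1\].
#' @export
pairwise_r2 <- function(block, id_a, id_b) {
  i <- block_index(block, id_a)
  j <- block_index(block, id_b)
  unname(block$corr[i, j]^2)
}

#' Read / write an LD panel directory
#'
#' A panel directory holds one whitespace-delimited dense matrix file per
#' block (`block_<k>.corr`) and one metadata table per block
#' (`block_<k>.snps` with columns snp_id, chrom, pos, allele1, allele2).
#'
#' @param dir directory path.
#' @return list of [ld_block] objects.
#' @export
read_ld_panel <- function(dir) {
  metas <- sort(list.files(dir, pattern = "\\.snps$", full.names = TRUE))
  if (length(metas) == 0) stop("no *.snps files found in ", dir)
  lapply(metas, function(m) {
    cf <- sub("\\.snps$", ".corr", m)
    if (!file.exists(cf)) stop("missing matrix file ", cf)
    snps <- utils::read.table(m, header = TRUE, stringsAsFactors = FALSE,
                              colClasses = c(chrom = "character"))
    corr <- as.matrix(utils::read.table(cf, header = FALSE))
    ld_block(snps, corr)
  })
}

#' @rdname read_ld_panel
#' @param blocks list of [ld_block] objects.
#' @export
write_ld_panel <- function(blocks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (k in seq_along(blocks)) {
    stem <- file.path(dir, sprintf("block_%04d", k))
    utils::write.table(blocks[[k]]$snps, paste0(stem, ".snps"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(blocks[[k]]$corr, paste0(stem, ".corr"),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a pre-computed pairwise r-squared list
#'
#' Three-column whitespace-delimited table `id_a id_b r2` (header optional,
#' detected from the first line).
#'
#' @param path file path.
#' @return data.frame with columns `id_a`, `id_b`, `r2`.
#' @export
read_r2_list <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(trimws(first), "\\s+")[[1]][3])))
  x <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  names(x) <- c("id_a", "id_b", "r2")
  if (any(x$r2 < 0 | x$r2 > 1)) stop("r2 values outside [0, 1] in ", path)
  x
}

find_block <- function(blocks, snp_id) {
  for (k in seq_along(blocks))
    if (snp_id %in% blocks[[k]]$snps$snp_id) return(k)
  NA_integer_
}

#' Build LD-independent intervals around index SNPs
#'
#' Each interval spans from the leftmost to the rightmost panel SNP whose
#' r-squared with the index SNP is at least `r2_threshold`, extended by
#' `pad_bp` on both sides. Intervals on the same chromosome that overlap
#' (closed-interval semantics) are merged so the result is LD-independent;
#' a merged interval carries all contributing index SNP ids, separated by
#' commas. An index SNP absent from the panel degenerates to
#' `[pos - pad_bp, pos + pad_bp]` with a warning.
#'
#' @param index_snps [sumstats] rows for the index SNPs.
#' @param blocks list of [ld_block] objects.
#' @param r2_threshold LD threshold in (0, 1].
#' @param pad_bp non-negative basepair padding.
#' @return data.frame with columns `chrom`, `start`, `end`, `index_snp`.
#' @export
build_intervals <- function(index_snps, blocks, r2_threshold = 0.5,
                            pad_bp = 0) {
  if (r2_threshold <= 0 || r2_threshold > 1)
    stop("r2_threshold must lie in (0, 1]")
  if (pad_bp < 0) stop("pad_bp must be >= 0")
  rows <- lapply(seq_len(nrow(index_snps)), function(i) {
    id <- index_snps$snp_id[i]
    k <- find_block(blocks, id)
    if (is.na(k)) {
      warning("index SNP ", id, " absent from LD panel; ",
              "interval degenerates to position +/- pad")
      return(data.frame(chrom = index_snps$chrom[i],
                        start = max(1L, index_snps$pos[i] - pad_bp),
                        end = index_snps$pos[i] + pad_bp,
                        index_snp = id, stringsAsFactors = FALSE))
    }
    b <- blocks[[k]]
    j <- block_index(b, id)
    friends <- which(b$corr[j, ]^2 >= r2_threshold)
    span <- range(b$snps$pos[friends])
    data.frame(chrom = b$snps$chrom[1],
               start = max(1L, span[1] - pad_bp), end = span[2] + pad_bp,
               index_snp = id, stringsAsFactors = FALSE)
  })
  merge_intervals(do.call(rbind, rows))
}

#' Merge overlapping intervals per chromosome
#'
#' Closed-interval merge; the merged row carries the comma-joined index ids.
#'
#' @param intervals data.frame with `chrom`, `start`, `end`, `index_snp`.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0) return(intervals)
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end))
  red <- GenomicRanges::reduce(gr)
  hit <- GenomicRanges::findOverlaps(red, gr)
  ids <- vapply(seq_along(red), function(i) {
    members <- S4Vectors::subjectHits(hit)[S4Vectors::queryHits(hit) == i]
    paste(intervals$index_snp[members], collapse = ",")
  }, character(1))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red), end = GenomicRanges::end(red),
    index_snp = ids, stringsAsFactors = FALSE)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Exclude LD proxies between two index-SNP lists
#'
#' Drops SNPs from `list_b` that are in high LD (r-squared above
#' `proxy_r2`) with any SNP of `list_a`, so that the same association
#' signal is not tested twice when the lookup is run in both directions.
#'
#' @param list_a,list_b [sumstats] index-SNP tables.
#' @param blocks list of [ld_block] objects (r2 evaluated within blocks).
#' @param proxy_r2 exclusion threshold, default 0.8.
#' @return `list_b` with proxies removed; dropped ids in attribute
#'   `"excluded"`.
#' @export
exclude_ld_proxies <- function(list_a, list_b, blocks, proxy_r2 = 0.8) {
  drop <- vapply(seq_len(nrow(list_b)), function(i) {
    id_b <- list_b$snp_id[i]
    k <- find_block(blocks, id_b)
    if (is.na(k)) return(FALSE)
    in_block <- intersect(list_a$snp_id, blocks[[k]]$snps$snp_id)
    any(vapply(in_block, function(id_a)
      pairwise_r2(blocks[[k]], id_a, id_b) > proxy_r2, logical(1)))
  }, logical(1))
  out <- list_b[!drop, , drop = FALSE]
  class(out) <- class(list_b)
  attr(out, "excluded") <- list_b$snp_id[drop]
  out
}
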