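#' Read gene annotations from a BED-like table
#'
#' Tab-delimited columns `gene_id`, `chrom`, `start`, `end` (1-based,
#' inclusive), header optional. A `chr` prefix on chromosome names is
#' normalized away with a warning.
#'
#' @param path file path.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gene_bed <- function(path) {
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[3])))
  x <- utils::read.table(path, header = has_header, sep = "\t",
                         stringsAsFactors = FALSE)
  names(x)[1:4] <- c("gene_id", "chrom", "start", "end")
  x$chrom <- as.character(x$chrom)
  if (any(grepl("^chr", x$chrom))) {
    warning("normalizing 'chr' prefix on chromosome names")
    x$chrom <- sub("^chr", "", x$chrom)
  }
  if (any(x$start > x$end)) stop("gene with start > end in ", path)
  x[, c("gene_id", "chrom", "start", "end")]
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions in attribute
#'   `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  bad <- vapply(parts, length, integer(1)) < 3
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields in ", path)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene-id vectors.
#' @param descriptions optional descriptions, recycled.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- attr(sets, "description") %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter gene sets by size against an annotation universe
#'
#' Sets are intersected with the annotated gene universe first; the size
#' filter applies to the intersected size.
#'
#' @param sets list from [read_gmt()].
#' @param universe character vector of annotated gene ids.
#' @param min_size,max_size inclusive size bounds, defaults 10 and 200.
#' @export
filter_gene_sets <- function(sets, universe, min_size = 10,
                             max_size = 200) {
  trimmed <- lapply(sets, intersect, universe)
  sz <- vapply(trimmed, length, integer(1))
  keep <- sz >= min_size & sz <= max_size
  out <- trimmed[keep]
  attr(out, "description") <- attr(sets, "description")[keep]
  out
}

intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    sub("^chr", "", intervals$chrom),
    IRanges::IRanges(intervals$start, intervals$end))
}

#' Assign genes to LD intervals with flanking windows
#'
#' Gene g is assigned to interval i iff the gene span extended by
#' `flank_bp` on both sides intersects the interval (closed intervals).
#'
#' @param intervals data.frame `chrom`, `start`, `end` (plus `index_snp`).
#' @param annotations data.frame from [read_gene_bed()].
#' @param flank_bp flanking window, default 50000 (50 kb up- and
#'   downstream).
#' @return list, one character vector of gene ids per interval.
#' @export
intervals_to_genes <- function(intervals, annotations, flank_bp = 50000) {
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  gr_int <- intervals_to_granges(intervals)
  gr_gene <- GenomicRanges::GRanges(
    sub("^chr", "", annotations$chrom),
    IRanges::IRanges(pmax(1, annotations$start - flank_bp),
                     annotations$end + flank_bp))
  hits <- GenomicRanges::findOverlaps(gr_int, gr_gene)
  out <- rep(list(character(0)), nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    g <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    out[[i]] <- annotations$gene_id[g]
  }
  out
}

# Fast interval->gene lookup used inside the permutation loop: plain
# vectorized interval arithmetic on a pre-flanked copy of the annotation
# (the user-facing intervals_to_genes goes through GenomicRanges once).
flanked_annotation <- function(annotations, flank_bp) {
  list(chrom = sub("^chr", "", annotations$chrom),
       start = pmax(1, annotations$start - flank_bp),
       end = annotations$end + flank_bp)
}

hit_gene_idx <- function(fl, chrom, start, end) {
  which(fl$chrom == chrom & fl$start <= end & fl$end >= start)
}

# Chromosome lengths implied by an annotation table (+ margin), used as
# the relocation universe for the permutation null.
annotation_genome <- function(annotations, margin = 0L) {
  lens <- tapply(annotations$end, annotations$chrom, max)
  data.frame(chrom = names(lens),
             length = as.integer(lens) + margin,
             stringsAsFactors = FALSE)
}

# Relocate each interval uniformly at random in the genome, preserving its
# length; returns a data.frame of the same shape.
relocate_intervals <- function(intervals, genome) {
  widths <- intervals$end - intervals$start
  total <- sum(genome$length)
  chr_idx <- sample.int(nrow(genome), nrow(intervals), replace = TRUE,
                        prob = genome$length / total)
  start <- vapply(seq_len(nrow(intervals)), function(i) {
    L <- genome$length[chr_idx[i]]
    max_start <- max(1L, L - widths[i])
    sample.int(max_start, 1)
  }, integer(1))
  data.frame(chrom = genome$chrom[chr_idx], start = start,
             end = start + widths, index_snp = intervals$index_snp,
             stringsAsFactors = FALSE)
}

# One permutation draw matched on gene-count class: each interval is
# relocated until it covers (with flank) a number of genes within
# `class_tol` of its observed count, up to `max_tries` rejections.
# Returns the per-interval hit-gene index lists directly.
relocate_matched_hits <- function(widths, fl, genome, obs_counts,
                                  class_tol = 1, max_tries = 50) {
  lapply(seq_along(widths), function(i) {
    hits <- integer(0)
    for (try in seq_len(max_tries)) {
      ci <- sample.int(nrow(genome), 1,
                       prob = genome$length / sum(genome$length))
      L <- genome$length[ci]
      s <- sample.int(max(1L, L - widths[i]), 1)
      hits <- hit_gene_idx(fl, genome$chrom[ci], s, s + widths[i])
      if (abs(length(hits) - obs_counts[i]) <= class_tol) break
    }
    hits
  })
}

#' Interval-based gene-set enrichment with permutation and resampling
#'
#' For each gene set, the observed statistic is the number of intervals
#' overlapping at least one set gene (after [intervals_to_genes()]
#' assignment with flanks). The null relocates each interval uniformly at
#' random within the annotated genome, preserving its length and matching
#' its gene-count class within one gene (rejection sampling); the
#' empirical p-value is `(1 + #{permutations >= observed}) / (R + 1)`.
#' A second, familywise stage corrects for testing many sets: `B`
#' additional null relocations are scored against the first-stage null,
#' and each set's corrected p is the fraction of replicates in which the
#' best (smallest) empirical p across all sets is at least as small as
#' that set's own empirical p, floored at the empirical p itself.
#'
#' @param intervals data.frame `chrom`, `start`, `end`, `index_snp`
#'   (pairwise non-overlapping; see [build_intervals()]).
#' @param annotations gene annotation data.frame.
#' @param sets list of gene-id vectors (size-filter first with
#'   [filter_gene_sets()]).
#' @param flank_bp gene-assignment flank, default 50000.
#' @param R first-stage permutations, >= 100; default 10000.
#' @param B second-stage resampling replicates; default 1000.
#' @param seed integer seed; results are reproducible bit-for-bit.
#' @param match_gene_class match relocations on observed gene count (+/- 1);
#'   `FALSE` relocates unconditionally.
#' @return data.frame `set_id`, `description`, `n_genes`,
#'   `observed_overlap`, `empirical_p`, `corrected_p`, sorted by
#'   empirical p.
#' @export
test_gene_sets <- function(intervals, annotations, sets, flank_bp = 50000,
                           R = 10000, B = 1000, seed = 1,
                           match_gene_class = TRUE) {
  if (R < 100) stop("R must be >= 100")
  set.seed(seed)
  genome <- annotation_genome(annotations, margin = flank_bp)
  fl <- flanked_annotation(annotations, flank_bp)
  obs_genes <- intervals_to_genes(intervals, annotations, flank_bp)
  obs_counts <- vapply(obs_genes, length, integer(1))
  if (all(obs_counts == 0))
    warning("no interval overlaps any annotated gene")
  # gene x set membership matrix for fast scoring
  membership <- vapply(sets, function(s) annotations$gene_id %in% s,
                       logical(nrow(annotations)))
  membership <- matrix(membership, nrow = nrow(annotations),
                       dimnames = list(NULL, names(sets)))
  score_idx <- function(hit_lists) {
    stat <- integer(length(sets))
    for (h in hit_lists)
      if (length(h) > 0)
        stat <- stat + (colSums(membership[h, , drop = FALSE]) > 0)
    stat
  }
  widths <- intervals$end - intervals$start
  observed <- score_idx(lapply(obs_genes, match, annotations$gene_id))
  draw <- function() {
    hits <- if (match_gene_class)
      relocate_matched_hits(widths, fl, genome, obs_counts)
    else {
      perm <- relocate_intervals(intervals, genome)
      lapply(seq_len(nrow(perm)), function(i)
        hit_gene_idx(fl, perm$chrom[i], perm$start[i], perm$end[i]))
    }
    score_idx(hits)
  }
  null_raw <- vapply(seq_len(R), function(r) draw(),
                     integer(length(sets)))
  null_mat <- if (is.matrix(null_raw)) t(null_raw)
              else matrix(null_raw, ncol = 1)        # R x n_sets
  exceed <- colSums(null_mat >= matrix(observed, R, length(sets),
                                       byrow = TRUE))
  emp_p <- (1 + exceed) / (R + 1)
  # familywise stage: min-p distribution over B fresh null datasets
  corrected <- rep(NA_real_, length(sets))
  if (B > 0) {
    min_p_boot <- vapply(seq_len(B), function(b) {
      stat_b <- draw()
      p_b <- (1 + colSums(null_mat >= matrix(stat_b, R, length(sets),
                                             byrow = TRUE))) / (R + 1)
      min(p_b)
    }, numeric(1))
    corrected <- vapply(emp_p, function(p) mean(min_p_boot <= p),
                        numeric(1))
    corrected <- pmax(corrected, emp_p)
  }
  out <- data.frame(
    set_id = names(sets),
    description = attr(sets, "description") %||% rep(NA_character_,
                                                     length(sets)),
    n_genes = vapply(sets, length, integer(1)),
    observed_overlap = observed,
    empirical_p = emp_p, corrected_p = corrected,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$empirical_p, out$set_id), , drop = FALSE]
}
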