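#' GWAS summary-statistics records
#'
#' A `sumstats` object is a plain `data.frame` (class `c("sumstats",
#' "data.frame")`) with one row per SNP and the columns `snp_id`, `chrom`,
#' `pos`, `allele1`, `allele2`, `z`, `p`, `n_case`, `n_control`, `accuracy`.
#' `allele1` is the effect allele: the allele whose dosage the z-score is
#' predicted for, so flipping `allele1`/`allele2` negates `z`. Positions are
#' 1-based GRCh37 basepairs. `accuracy` is the predicted imputation accuracy
#' in \[0, 1\]; typed (directly genotyped) SNPs carry `accuracy = 1`.
#'
#' @param snp_id character vector of SNP identifiers (must be unique).
#' @param chrom chromosome labels (`"1"`–`"22"`, `"X"`); a leading `"chr"`
#'   prefix is stripped.
#' @param pos integer basepair positions, 1-based.
#' @param allele1,allele2 effect and other allele.
#' @param z signed association z-scores. If missing, derived from `p` as
#'   `2 * pnorm(-|z|)` is inverted using the sign of `direction`.
#' @param p two-sided p-values; filled in from `z` when absent.
#' @param n_case,n_control per-study case and control counts (recycled).
#' @param accuracy imputation accuracy metric, 1 for typed SNPs.
#' @return a `sumstats` data.frame.
#' @export
sumstats <- function(snp_id, chrom, pos, allele1, allele2,
                     z = NULL, p = NULL,
                     n_case = NA_integer_, n_control = NA_integer_,
                     accuracy = 1) {
  n <- length(snp_id)
  chrom <- sub("^chr", "", as.character(chrom))
  if (is.null(z) && is.null(p))
    stop("at least one of `z` and `p` must be supplied")
  if (is.null(z)) z <- rep(NA_real_, n)
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(z))
  fill <- is.na(p) & !is.na(z)
  p[fill] <- 2 * stats::pnorm(-abs(z[fill]))
  x <- data.frame(
    snp_id = as.character(snp_id), chrom = chrom, pos = as.integer(pos),
    allele1 = toupper(as.character(allele1)),
    allele2 = toupper(as.character(allele2)),
    z = as.numeric(z), p = as.numeric(p),
    n_case = as.integer(rep_len(n_case, n)),
    n_control = as.integer(rep_len(n_control, n)),
    accuracy = as.numeric(rep_len(accuracy, n)),
    stringsAsFactors = FALSE
  )
  validate_sumstats(x)
}

validate_sumstats <- function(x) {
  dup <- x$snp_id[duplicated(x$snp_id)]
  if (length(dup) > 0)
    stop("duplicated snp_id: ", paste(unique(dup), collapse = ", "))
  if (any(x$allele1 == x$allele2, na.rm = TRUE))
    stop("allele1 must differ from allele2")
  bad_p <- !is.na(x$p) & (x$p < 0 | x$p > 1)
  if (any(bad_p)) stop("p-values outside [0, 1]")
  bad_acc <- !is.na(x$accuracy) & (x$accuracy < 0 | x$accuracy > 1)
  if (any(bad_acc)) stop("accuracy outside [0, 1]")
  ok <- !is.na(x$p) & !is.na(x$z) & abs(x$z) < 30
  if (any(ok)) {
    expect <- 2 * stats::pnorm(-abs(x$z[ok]))
    rel <- abs(x$p[ok] - expect) / pmax(expect, .Machine$double.eps)
    if (any(rel > 1e-4))
      warning(sum(rel > 1e-4), " record(s) have p inconsistent with z")
  }
  class(x) <- c("sumstats", "data.frame")
  x
}

#' Default column map for summary-statistics files
#'
#' Maps internal field names to file column names; override entries to read
#' files with other headers, e.g. `sumstats_dialect(snp_id = "MarkerName")`.
#'
#' @param ... named overrides of the defaults.
#' @export
sumstats_dialect <- function(...) {
  d <- list(snp_id = "SNP", chrom = "CHR", pos = "BP",
            allele1 = "A1", allele2 = "A2", z = "Z", p = "P",
            beta = "BETA", se = "SE", direction = "DIR",
            n_case = "NCASE", n_control = "NCONTROL", accuracy = "INFO")
  ov <- list(...)
  d[names(ov)] <- ov
  d
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or whitespace-delimited table with a header line. The z-score
#' is taken from the `z` column when present, otherwise derived as `beta/se`,
#' otherwise from a (`p`, `direction`) pair as
#' `sign(direction) * qnorm(1 - p/2)`. Rows with `p` but no direction column
#' are rejected rather than assigned an unsigned `|z|`. Rows missing any of
#' id, chromosome, position or either allele are skipped; the number skipped
#' is reported via a message and the `"n_skipped"` attribute.
#'
#' @param path file path.
#' @param dialect column-name map from [sumstats_dialect()].
#' @param drop_ambiguous drop strand-ambiguous (A/T, C/G) SNPs instead of
#'   keeping them.
#' @return a [sumstats] data.frame with attribute `n_skipped`.
#' @export
read_sumstats <- function(path, dialect = sumstats_dialect(),
                          drop_ambiguous = FALSE) {
  # tab-delimited when the header contains tabs (empty fields preserved),
  # otherwise any-whitespace-delimited
  sep <- if (grepl("\t", readLines(path, n = 1))) "\t" else ""
  raw <- tryCatch(
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, comment.char = "", sep = sep,
                      na.strings = c("NA", "")),
    error = function(e) stop("unparseable summary-statistics header/table in ",
                             path, ": ", conditionMessage(e))
  )
  get <- function(field) {
    col <- dialect[[field]]
    if (!is.null(col) && col %in% names(raw)) raw[[col]] else NULL
  }
  id <- get("snp_id"); chrom <- get("chrom"); pos <- get("pos")
  a1 <- get("allele1"); a2 <- get("allele2")
  if (is.null(id) || is.null(chrom) || is.null(pos) ||
      is.null(a1) || is.null(a2))
    stop("header must provide id, chromosome, position and both alleles")
  z <- get("z"); p <- get("p")
  if (is.null(z)) {
    beta <- get("beta"); se <- get("se")
    if (!is.null(beta) && !is.null(se)) {
      z <- beta / se
    } else if (!is.null(p)) {
      dir <- get("direction")
      if (is.null(dir))
        stop("p-values without a z, beta/se or direction column: ",
             "cannot assign a signed z-score")
      sgn <- ifelse(is.character(dir) | is.factor(dir),
                    ifelse(as.character(dir) %in% c("-", "neg"), -1, 1),
                    sign(as.numeric(dir)))
      z <- sgn * stats::qnorm(1 - p / 2)
    } else {
      stop("no usable association column: need Z, BETA+SE or P+direction")
    }
  }
  keep <- !is.na(id) & !is.na(chrom) & !is.na(pos) &
    !is.na(a1) & a1 != "" & !is.na(a2) & a2 != "" & !is.na(z)
  n_skipped <- sum(!keep)
  if (n_skipped > 0)
    message("read_sumstats: skipped ", n_skipped,
            " row(s) with missing mandatory fields")
  nc <- get("n_case"); nn <- get("n_control"); acc <- get("accuracy")
  x <- sumstats(
    snp_id = id[keep], chrom = chrom[keep], pos = pos[keep],
    allele1 = a1[keep], allele2 = a2[keep], z = z[keep],
    p = if (is.null(p)) NULL else p[keep],
    n_case = if (is.null(nc)) NA_integer_ else nc[keep],
    n_control = if (is.null(nn)) NA_integer_ else nn[keep],
    accuracy = if (is.null(acc)) 1 else acc[keep]
  )
  if (drop_ambiguous) {
    amb <- is_strand_ambiguous(x$allele1, x$allele2)
    if (any(amb))
      message("read_sumstats: dropped ", sum(amb), " strand-ambiguous SNP(s)")
    x <- x[!amb, , drop = FALSE]
    class(x) <- c("sumstats", "data.frame")
  }
  attr(x, "n_skipped") <- n_skipped
  x
}

#' Write a summary-statistics table
#'
#' Writes tab-delimited text using the same column map as [read_sumstats()],
#' so a read/write/read cycle round-trips all fields.
#'
#' @inheritParams read_sumstats
#' @param x a [sumstats] data.frame.
#' @export
write_sumstats <- function(x, path, dialect = sumstats_dialect()) {
  out <- data.frame(x$snp_id, x$chrom, x$pos, x$allele1, x$allele2,
                    x$z, x$p, x$n_case, x$n_control, x$accuracy)
  names(out) <- unlist(dialect[c("snp_id", "chrom", "pos", "allele1",
                                 "allele2", "z", "p", "n_case",
                                 "n_control", "accuracy")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Is an allele pair strand-ambiguous?
#'
#' A/T and C/G pairs read the same on both strands, so a strand flip between
#' two studies cannot be detected from the alleles alone.
#'
#' @param a1,a2 allele vectors.
#' @return logical vector.
#' @export
is_strand_ambiguous <- function(a1, a2) {
  ok <- a1 %in% names(DNA_COMPLEMENT) & a2 %in% names(DNA_COMPLEMENT)
  out <- rep(FALSE, length(a1))
  out[ok] <- DNA_COMPLEMENT[a1[ok]] == a2[ok]
  out
}

#' Harmonize two studies' records for the same SNP
#'
#' Aligns record `b` to record `a`'s effect allele. If `b`'s alleles are the
#' reverse of `a`'s, `b`'s z-score is negated and its alleles swapped
#' (`flipped = TRUE`). Strand complements are likewise resolved. Pairs whose
#' alleles are strand-ambiguous (A/T or C/G) are flagged `ambiguous = TRUE`
#' because orientation cannot be verified.
#'
#' Harmonizing the returned `b` against `a` a second time is the identity:
#' the operation is an involution on the flip flag.
#'
#' @param a,b single-row [sumstats] records with equal `snp_id`.
#' @return list with elements `a`, `b` (aligned), `flipped`, `ambiguous`.
#' @export
harmonize <- function(a, b) {
  if (a$snp_id != b$snp_id)
    stop("harmonize: records refer to different SNPs (",
         a$snp_id, " vs ", b$snp_id, ")")
  ambiguous <- is_strand_ambiguous(a$allele1, a$allele2)
  flipped <- FALSE
  comp <- function(x) unname(DNA_COMPLEMENT[x])
  if (b$allele1 == a$allele1 && b$allele2 == a$allele2) {
    # already aligned
  } else if (b$allele1 == a$allele2 && b$allele2 == a$allele1) {
    b$z <- -b$z
    tmp <- b$allele1; b$allele1 <- b$allele2; b$allele2 <- tmp
    flipped <- TRUE
  } else if (!ambiguous &&
             identical(comp(b$allele1), a$allele1) &&
             identical(comp(b$allele2), a$allele2)) {
    b$allele1 <- a$allele1; b$allele2 <- a$allele2
  } else if (!ambiguous &&
             identical(comp(b$allele1), a$allele2) &&
             identical(comp(b$allele2), a$allele1)) {
    b$z <- -b$z
    b$allele1 <- a$allele1; b$allele2 <- a$allele2
    flipped <- TRUE
  } else {
    stop("harmonize: incompatible alleles for ", a$snp_id, ": ",
         a$allele1, "/", a$allele2, " vs ", b$allele1, "/", b$allele2)
  }
  list(a = a, b = b, flipped = flipped, ambiguous = ambiguous)
}

#' Per-study metadata
#'
#' @param label study label.
#' @param n_case,n_control case and control counts.
#' @param inflation variance of the study's z-scores over a well-behaved SNP
#'   set (mean chi-square); exceeds 1 under polygenicity or confounding.
#' @export
study_meta <- function(label, n_case, n_control, inflation = 1) {
  if (n_case < 0 || n_control < 0 || n_case + n_control <= 0)
    stop("study_meta: need n_case + n_control > 0")
  if (inflation <= 0) stop("study_meta: inflation must be > 0")
  structure(list(label = label, n_case = as.integer(n_case),
                 n_control = as.integer(n_control),
                 n_total = as.integer(n_case + n_control),
                 inflation = inflation),
            class = "study_meta")
}

#' @export
print.study_meta <- function(x, ...) {
  cat(sprintf("Study %s: %d cases / %d controls (N = %d), z-variance %.3f\n",
              x$label, x$n_case, x$n_control, x$n_total, x$inflation))
  invisible(x)
}
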