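#' Conditional-Gaussian imputation of untyped z-scores within an LD block
#'
#' Treats the block's z-scores as a zero-mean multivariate normal with
#' covariance equal to the LD correlation matrix. For each untyped target
#' SNP t, with Sigma the typed-by-typed correlation submatrix and w the
#' vector of correlations between t and the typed SNPs, the imputed score
#' is the conditional mean
#' \deqn{z_t = w' (\Sigma + \lambda I)^{-1} z_{typed}}
#' and the predicted accuracy is
#' \deqn{r^2_{pred} = w' (\Sigma + \lambda I)^{-1} w,}
#' clipped to \[0, 1\] to guard small negative values from finite
#' precision. The ridge term \eqn{\lambda} regularizes near-singular LD;
#' typed SNPs are returned unchanged with `r2pred = 1`.
#'
#' @param block an [ld_block].
#' @param typed named numeric vector of observed z-scores; names must be
#'   SNP ids present in the block.
#' @param lambda ridge regularizer, non-negative; default 0.1.
#' @return data.frame with columns `snp_id`, `z_imputed`, `r2pred`, `typed`.
#' @export
impute_block <- function(block, typed, lambda = 0.1) {
  if (lambda < 0) stop("lambda must be >= 0")
  ids <- block$snps$snp_id
  if (is.null(names(typed)) || !all(names(typed) %in% ids))
    stop("typed z-scores must be named with SNP ids present in the block")
  ti <- match(names(typed), ids)
  S <- block$corr[ti, ti, drop = FALSE] + diag(lambda, length(ti))
  Sinv_z <- tryCatch(solve(S, unname(typed)),
                     error = function(e)
                       stop("typed correlation matrix numerically singular; ",
                            "use a positive ridge lambda"))
  out <- data.frame(snp_id = ids, z_imputed = NA_real_, r2pred = NA_real_,
                    typed = ids %in% names(typed), stringsAsFactors = FALSE)
  out$z_imputed[out$typed] <- unname(typed[match(ids[out$typed],
                                                 names(typed))])
  out$r2pred[out$typed] <- 1
  for (j in which(!out$typed)) {
    w <- block$corr[j, ti]
    out$z_imputed[j] <- sum(w * Sinv_z)
    out$r2pred[j] <- min(1, max(0, sum(w * solve(S, w))))
  }
  out
}

#' Impute every untyped panel SNP across blocks
#'
#' Applies [impute_block()] block by block, taking typed z-scores from a
#' [sumstats] table. Panel SNPs absent from the study are imputed; study
#' SNPs absent from the panel pass through unchanged with `typed = TRUE`.
#'
#' @param study a [sumstats] table of typed SNPs.
#' @param blocks list of [ld_block] objects.
#' @param lambda ridge regularizer.
#' @return [sumstats] table covering panel and study SNPs, with extra
#'   columns preserved in `accuracy` (r2pred) and attribute `"imputed"`.
#' @export
impute_sumstats <- function(study, blocks, lambda = 0.1) {
  res_list <- lapply(blocks, function(b) {
    present <- intersect(b$snps$snp_id, study$snp_id)
    typed <- stats::setNames(study$z[match(present, study$snp_id)], present)
    res <- if (length(typed) == 0) {
      data.frame(snp_id = b$snps$snp_id, z_imputed = 0,
                 r2pred = 0, typed = FALSE, stringsAsFactors = FALSE)
    } else impute_block(b, typed, lambda)
    cbind(res, b$snps[match(res$snp_id, b$snps$snp_id),
                      c("chrom", "pos", "allele1", "allele2")])
  })
  res <- do.call(rbind, res_list)
  extra <- study[!study$snp_id %in% res$snp_id, , drop = FALSE]
  out <- sumstats(
    snp_id = c(res$snp_id, extra$snp_id),
    chrom = c(res$chrom, extra$chrom),
    pos = c(res$pos, extra$pos),
    allele1 = c(res$allele1, extra$allele1),
    allele2 = c(res$allele2, extra$allele2),
    z = c(res$z_imputed, extra$z),
    n_case = c(study$n_case[match(res$snp_id, study$snp_id)], extra$n_case),
    n_control = c(study$n_control[match(res$snp_id, study$snp_id)],
                  extra$n_control),
    accuracy = c(res$r2pred, rep(1, nrow(extra)))
  )
  fill <- is.na(out$n_case)
  out$n_case[fill] <- stats::median(study$n_case, na.rm = TRUE)
  out$n_control[fill] <- stats::median(study$n_control, na.rm = TRUE)
  attr(out, "imputed") <- !c(res$typed, rep(TRUE, nrow(extra)))
  out
}

#' Filter imputation results by predicted accuracy
#'
#' Keeps records with `r2pred >= min_r2pred`; typed SNPs always survive.
#'
#' @param results data.frame from [impute_block()] (columns `r2pred`,
#'   `typed`), or a [sumstats] table using `accuracy` as r2pred.
#' @param min_r2pred threshold in \[0, 1\].
#' @return surviving rows, with the number dropped in attribute
#'   `"n_dropped"`.
#' @export
filter_by_accuracy <- function(results, min_r2pred) {
  if (min_r2pred < 0 || min_r2pred > 1) stop("min_r2pred must be in [0, 1]")
  r2 <- if ("r2pred" %in% names(results)) results$r2pred else results$accuracy
  typed <- if ("typed" %in% names(results)) results$typed else r2 >= 1
  keep <- typed | r2 >= min_r2pred
  out <- results[keep, , drop = FALSE]
  class(out) <- class(results)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
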