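#' Simulation configuration for paired GWAS z-score sets
#'
#' Defaults reproduce the statistical structure of a large psychiatric
#' cross-disorder setting: study sizes 35,476/46,839 and 9,747/14,278
#' with 500 shared cases and 9,200 shared controls, marginal z-variances
#' 1.82 and 1.24, and independent z-scores across SNPs (`ld_decay = 0`);
#' set `ld_decay > 0` for AR-1 LD within blocks.
#'
#' @param n_snps total SNP count; must equal `n_blocks * block_size`.
#' @param n_blocks,block_size LD-block layout.
#' @param ld_decay AR-1 correlation parameter in \[0, 1).
#' @param overlap an [overlap_spec].
#' @param inflation1,inflation2 marginal z-score variances (>= 1).
#' @param shared_fraction fraction of SNPs given a true shared effect.
#' @param shared_effect_z mean non-centrality added to both studies'
#'   z-scores at shared loci (random sign, same sign in both studies).
#' @param seed integer seed.
#' @export
simulation_config <- function(n_snps = 10000, n_blocks = 100,
                              block_size = n_snps / n_blocks,
                              ld_decay = 0,
                              overlap = overlap_spec(35476, 46839,
                                                     9747, 14278,
                                                     500, 9200),
                              inflation1 = 1.82, inflation2 = 1.24,
                              shared_fraction = 0, shared_effect_z = 4,
                              seed = 1) {
  if (block_size != as.integer(block_size) ||
      n_blocks * as.integer(block_size) != n_snps)
    stop("n_blocks * block_size must equal n_snps exactly")
  if (ld_decay < 0 || ld_decay >= 1) stop("ld_decay must lie in [0, 1)")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]")
  if (inflation1 < 1 || inflation2 < 1)
    stop("inflation factors must be >= 1")
  structure(list(n_snps = as.integer(n_snps),
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 ld_decay = ld_decay, overlap = overlap,
                 inflation1 = inflation1, inflation2 = inflation2,
                 shared_fraction = shared_fraction,
                 shared_effect_z = shared_effect_z,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

ar1_matrix <- function(m, rho) {
  if (m == 1) return(matrix(1, 1, 1))
  rho^abs(outer(seq_len(m), seq_len(m), "-"))
}

#' Simulate a pair of overlapping GWAS summary-statistics sets
#'
#' Per block, the latent LD matrix is AR-1 with parameter `ld_decay`. Per
#' SNP, the null (z1, z2) pair is bivariate normal with marginal
#' variances `inflation1`/`inflation2` and covariance
#' `theoretical_overlap_cov(overlap)`; LD is applied by multiplying each
#' block's z-vectors by the Cholesky factor of the AR-1 matrix, so the
#' joint covariance is the Kronecker product of the 2x2 null and the LD
#' matrix. A `shared_fraction` of SNPs (at most one per block, placed at
#' the block centre) receives a mean shift of `shared_effect_z` with a
#' common random sign in both studies. SNP positions are laid out at 1 kb
#' spacing, one chromosome per block (cycling 1..22).
#'
#' @param config a [simulation_config].
#' @return list with `study1`, `study2` ([sumstats]), `blocks` (list of
#'   [ld_block]), and `truth` (data.frame `snp_id`, `shared`, `effect1`,
#'   `effect2`).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cc <- theoretical_overlap_cov(config$overlap)
  K <- matrix(c(config$inflation1, cc, cc, config$inflation2), 2, 2)
  build_null(config$inflation1, config$inflation2, cc)  # validates K
  Lk <- chol(K)                                          # 2x2 upper
  m <- config$block_size
  Lld <- t(chol(ar1_matrix(m, config$ld_decay)))         # m x m lower
  n_shared_total <- round(config$shared_fraction * config$n_snps)
  shared_blocks <- if (n_shared_total > 0)
    sort(sample.int(config$n_blocks, min(n_shared_total, config$n_blocks)))
  else integer(0)
  ids <- sprintf("rs%06d", seq_len(config$n_snps))
  alle <- cbind(sample(c("A", "T"), config$n_snps, replace = TRUE),
                sample(c("C", "G"), config$n_snps, replace = TRUE))
  z1 <- z2 <- numeric(config$n_snps)
  eff1 <- eff2 <- numeric(config$n_snps)
  blocks <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    idx <- ((b - 1) * m + 1):(b * m)
    X <- matrix(stats::rnorm(2 * m), m, 2)
    Z <- (Lld %*% X) %*% Lk       # cov = K (x) ar1
    if (b %in% shared_blocks) {
      j <- idx[ceiling(m / 2)]
      sgn <- sample(c(-1, 1), 1)
      eff1[j] <- sgn * config$shared_effect_z
      eff2[j] <- sgn * config$shared_effect_z
    }
    z1[idx] <- Z[, 1] + eff1[idx]
    z2[idx] <- Z[, 2] + eff2[idx]
    chrom <- as.character((b - 1) %% 22 + 1)
    pos <- (b - 1) * m * 1000 + seq_len(m) * 1000
    blocks[[b]] <- ld_block(
      data.frame(snp_id = ids[idx], chrom = chrom, pos = pos,
                 allele1 = alle[idx, 1], allele2 = alle[idx, 2],
                 stringsAsFactors = FALSE),
      ar1_matrix(m, config$ld_decay))
  }
  make_study <- function(z, n_case, n_control)
    sumstats(snp_id = ids,
             chrom = unlist(lapply(blocks, function(b) b$snps$chrom)),
             pos = unlist(lapply(blocks, function(b) b$snps$pos)),
             allele1 = alle[, 1], allele2 = alle[, 2], z = z,
             n_case = n_case, n_control = n_control)
  list(study1 = make_study(z1, config$overlap$n1_case,
                           config$overlap$n1_control),
       study2 = make_study(z2, config$overlap$n2_case,
                           config$overlap$n2_control),
       blocks = blocks,
       truth = data.frame(snp_id = ids, shared = eff1 != 0,
                          effect1 = eff1, effect2 = eff2,
                          stringsAsFactors = FALSE),
       config = config)
}

#' Simulate gene annotations and gene sets
#'
#' Genes are placed uniformly at random without overlap on a single
#' synthetic chromosome of `genome_size` bp; gene sets are sampled
#' uniformly from the gene universe. An optional `enriched_near` interval
#' table seeds one extra set (`"ENRICHED"`) with the genes closest to
#' each interval, for power checks.
#'
#' @param genome_size chromosome length in bp.
#' @param n_genes number of genes.
#' @param gene_length fixed gene length in bp, default 10000.
#' @param n_sets number of random sets.
#' @param set_size_range inclusive size range, default c(10, 200).
#' @param enriched_near optional interval data.frame; adds set "ENRICHED".
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return list with `annotations` and `sets`.
#' @export
simulate_annotation <- function(genome_size = 5e6, n_genes = 200,
                                gene_length = 10000, n_sets = 50,
                                set_size_range = c(10, 200),
                                enriched_near = NULL, seed = 1) {
  set.seed(seed)
  if (n_genes * gene_length > genome_size)
    stop("cannot pack ", n_genes, " genes of ", gene_length,
         " bp into ", genome_size, " bp")
  if (set_size_range[1] > n_genes)
    stop("set_size_range exceeds the gene count")
  # non-overlapping placement: shuffle slack among the gaps
  slack <- genome_size - n_genes * gene_length
  gaps <- stats::rmultinom(1, slack %/% 1000, rep(1, n_genes + 1)) * 1000
  starts <- cumsum(gaps[seq_len(n_genes)]) +
    (seq_len(n_genes) - 1) * gene_length + 1
  ann <- data.frame(gene_id = sprintf("G%04d", seq_len(n_genes)),
                    chrom = "1", start = as.integer(starts),
                    end = as.integer(starts + gene_length - 1),
                    stringsAsFactors = FALSE)
  sizes <- if (n_sets > 0)
    sample(seq(min(set_size_range[1], n_genes),
               min(set_size_range[2], n_genes)), n_sets, replace = TRUE)
  else integer(0)
  sets <- lapply(sizes, function(s) sample(ann$gene_id, s))
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  if (!is.null(enriched_near)) {
    hit <- unique(unlist(intervals_to_genes(enriched_near, ann,
                                            flank_bp = 50000)))
    pad <- max(0, set_size_range[1] - length(hit))
    sets <- c(sets, list(ENRICHED = union(
      hit, sample(setdiff(ann$gene_id, hit), pad))))
  }
  attr(sets, "description") <- rep("synthetic", length(sets))
  list(annotations = ann, sets = sets)
}

#' Write a simulated dataset in pipeline input formats
#'
#' Emits `study1.tsv`, `study2.tsv` (sumstats), `panel/` (LD blocks),
#' `truth.tsv`, and — when annotation output is supplied — `genes.bed`
#' and `sets.gmt`.
#'
#' @param sim output of [simulate_pair()].
#' @param dir output directory.
#' @param annotation optional output of [simulate_annotation()].
#' @export
write_simulation <- function(sim, dir, annotation = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_sumstats(sim$study1, file.path(dir, "study1.tsv"))
  write_sumstats(sim$study2, file.path(dir, "study2.tsv"))
  write_ld_panel(sim$blocks, file.path(dir, "panel"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(annotation)) {
    utils::write.table(annotation$annotations, file.path(dir, "genes.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_gmt(annotation$sets, file.path(dir, "sets.gmt"))
  }
  invisible(dir)
}
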