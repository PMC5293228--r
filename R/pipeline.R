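#' Assemble and validate a pipeline run configuration
#'
#' A run configuration names the input files and every stage parameter.
#' It can be built from a YAML file ([read_run_config()]) or directly
#' from arguments. Referenced files must exist at validation time.
#'
#' @param index_snps path to the index-SNP sumstats table (the discovery
#'   study's hits to be cross-queried).
#' @param conditioning path to the discovery study's sumstats (supplies
#'   the conditioning z-scores).
#' @param targets character vector of target-study sumstats paths; two or
#'   more are meta-analyzed.
#' @param panel optional LD panel directory (enables imputation and
#'   LD-interval construction).
#' @param genes optional gene BED path; `gene_sets` optional GMT path —
#'   both required for the gene-set stage.
#' @param out_dir output directory.
#' @param ridge,min_r2pred imputation parameters.
#' @param weight meta-analysis weighting, `"total"` or `"effective"`.
#' @param overlap an [overlap_spec], or `NULL` when `cov` is given.
#' @param cov overlap covariance; overrides the value derived from
#'   `overlap` when non-`NULL`.
#' @param var1,var2 marginal z-variances; `NA` estimates them from the
#'   supplied sumstats via [estimate_inflation()].
#' @param alpha nominal level; `m` Bonferroni test count (`NA`: number
#'   tested).
#' @param r2_threshold,flank_bp interval construction and gene flank.
#' @param R,B gene-set permutation and resampling counts.
#' @param seed integer seed for the permutation stage.
#' @export
run_config <- function(index_snps, conditioning, targets, out_dir,
                       panel = NULL, genes = NULL, gene_sets = NULL,
                       ridge = 0.1, min_r2pred = 0,
                       weight = "total", overlap = NULL, cov = NULL,
                       var1 = NA_real_, var2 = NA_real_,
                       alpha = 0.05, m = NA_integer_,
                       r2_threshold = 0.5, flank_bp = 50000,
                       R = 10000, B = 1000, seed = 1) {
  paths <- c(index_snps, conditioning, targets, genes, gene_sets)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (!is.null(panel) && !dir.exists(panel))
    stop("panel directory not found: ", panel)
  if (is.null(cov) && is.null(overlap))
    stop("supply either `overlap` (shared-sample counts) or `cov`")
  structure(list(index_snps = index_snps, conditioning = conditioning,
                 targets = targets, panel = panel, genes = genes,
                 gene_sets = gene_sets, out_dir = out_dir, ridge = ridge,
                 min_r2pred = min_r2pred, weight = weight,
                 overlap = overlap, cov = cov, var1 = var1, var2 = var2,
                 alpha = alpha, m = m, r2_threshold = r2_threshold,
                 flank_bp = flank_bp, R = R, B = B,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys mirror the `run_config()` arguments;
#'   `overlap` is a 6-element map (`n1_case`, `n1_control`, `n2_case`,
#'   `n2_control`, `ns_case`, `ns_control`).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$overlap)) y$overlap <- do.call(overlap_spec, y$overlap)
  do.call(run_config, y)
}

#' Run the cross-trait shared-locus pipeline end-to-end
#'
#' Stages, in order: (1) optional imputation of each target study onto
#' the LD panel; (2) sample-size-weighted meta-analysis of the targets;
#' (3) index-SNP mapping and filtering; (4) bivariate-null construction
#' and conditional transformation of the target z-scores given the
#' discovery z-scores; (5) shared-locus report with binomial enrichment
#' and Bonferroni correction; (6) optional LD-interval gene-set
#' enrichment around the nominal hits. A failing stage aborts with the
#' stage named; outputs written so far are moved under `failed/`.
#' Identical configuration and seed give identical outputs.
#'
#' @param config a [run_config] (or YAML path).
#' @return the run summary, invisibly (also written to
#'   `summary.json`): all counts, the null-model parameters, the
#'   enrichment p, per-stage wall times and the output-file manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  timings <- c()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      failed <- file.path(out, "failed")
      if (!dir.exists(failed)) dir.create(failed)
      for (f in list.files(out, full.names = TRUE, include.dirs = FALSE))
        if (!dir.exists(f)) file.copy(f, failed)
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  index <- read_sumstats(config$index_snps)
  cond <- read_sumstats(config$conditioning)
  targets <- lapply(config$targets, read_sumstats)
  blocks <- if (!is.null(config$panel)) read_ld_panel(config$panel)

  targets <- stage("impute", {
    if (is.null(blocks)) targets
    else lapply(targets, function(s) {
      imp <- impute_sumstats(s, blocks, lambda = config$ridge)
      filter_by_accuracy(imp, config$min_r2pred)
    })
  })

  meta <- stage("meta", {
    m <- meta_analyze(targets, weight = config$weight)
    write_sumstats(m, file.path(out, "meta.tsv"))
    m
  })

  mapping <- stage("map", map_snps(index, meta))
  mapped <- mapping$mapped

  corrected <- stage("overlap_correct", {
    var1 <- if (is.na(config$var1)) estimate_inflation(cond$z)
            else config$var1
    var2 <- if (is.na(config$var2)) estimate_inflation(meta$z)
            else config$var2
    cc <- if (!is.null(config$cov)) config$cov
          else theoretical_overlap_cov(config$overlap)
    model <- build_null(var1, var2, cc)
    z1 <- z2 <- numeric(nrow(mapped))
    for (i in seq_len(nrow(mapped))) {
      id <- mapped$snp_id[i]
      a <- cond[cond$snp_id == id, , drop = FALSE]
      b <- meta[meta$snp_id == id, , drop = FALSE]
      if (nrow(a) == 1) {
        h <- harmonize(a, b)
        z1[i] <- a$z; z2[i] <- h$b$z
      } else {
        z1[i] <- 0; z2[i] <- b$z   # SNP absent from conditioning study
      }
    }
    cbind(conditional_transform(z1, z2, model),
          z1 = z1, z2 = z2, model = I(rep(list(model), nrow(mapped))))
  })
  model <- corrected$model[[1]]

  report <- stage("shared_loci", {
    p_src <- index$p[match(mapped$snp_id, index$snp_id)]
    m_tests <- if (is.na(config$m)) nrow(mapped) else config$m
    rep <- build_report(mapped, corrected$p_corrected, p_source = p_src,
                        m = m_tests, alpha = config$alpha,
                        tally = mapping$tally,
                        genes = if (!is.null(config$genes))
                          read_gene_bed(config$genes))
    write_report(rep, out)
    rep
  })

  geneset <- NULL
  if (!is.null(config$genes) && !is.null(config$gene_sets) &&
      !is.null(blocks)) {
    geneset <- stage("geneset", {
      hits <- mapped[corrected$p_corrected < config$alpha, , drop = FALSE]
      ann <- read_gene_bed(config$genes)
      sets <- filter_gene_sets(read_gmt(config$gene_sets), ann$gene_id)
      if (nrow(hits) == 0 || length(sets) == 0) NULL
      else {
        intervals <- build_intervals(hits, blocks,
                                     r2_threshold = config$r2_threshold)
        res <- suppressWarnings(test_gene_sets(
          intervals, ann, sets, flank_bp = config$flank_bp,
          R = config$R, B = config$B, seed = config$seed))
        utils::write.table(res, file.path(out, "gene_sets.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res
      }
    })
  }

  summary <- list(
    counts = as.list(report$counts),
    model = list(var1 = model$var1, var2 = model$var2,
                 cov = model$cov, corr = model$corr),
    enrichment_p = report$enrichment_p,
    m = report$m, alpha = report$alpha,
    n_gene_sets = if (is.null(geneset)) 0L else nrow(geneset),
    stage_seconds = as.list(timings),
    manifest = list.files(out, recursive = TRUE))
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # frozen copy of the resolved configuration, for provenance
  cfg <- config
  cfg$overlap <- if (!is.null(cfg$overlap)) unclass(cfg$overlap)
  yaml::write_yaml(unclass(cfg), file.path(out, "config_resolved.yaml"))
  invisible(summary)
}
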