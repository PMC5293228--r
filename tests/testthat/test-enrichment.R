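test_that("map_snps excludes X and indel variants then intersects", {
  idx <- make_index_list(n_auto = 111, n_x = 3, n_indel = 14)
  no_target <- map_snps(idx)
  expect_equal(unname(no_target$tally["n_input"]), 128)
  expect_equal(unname(no_target$tally["n_excluded_x"]), 3)
  expect_equal(unname(no_target$tally["n_excluded_indel"]), 14)
  expect_equal(unname(no_target$tally["n_mapped"]), 111)
  # target study missing 4 of the mappable SNPs
  target <- data.frame(snp_id = no_target$mapped$snp_id[-(1:4)])
  with_target <- map_snps(idx, target)
  expect_equal(unname(with_target$tally["n_absent"]), 4)
  expect_equal(unname(with_target$tally["n_tested"]), 107)
  expect_equal(nrow(with_target$mapped), 107)
})

test_that("an all-autosomal SNV list fully present maps identically", {
  idx <- make_index_list(10, 0, 0)
  m <- map_snps(idx, data.frame(snp_id = idx$snp_id))
  expect_equal(m$mapped$snp_id, idx$snp_id)
  expect_true(all(m$tally[c("n_excluded_x", "n_excluded_indel",
                            "n_absent")] == 0))
})

test_that("symbolic alleles count as indels", {
  idx <- sumstats(c("a", "b", "c"), "2", 1:3 * 100,
                  c("A", "I", "<DEL>"), c("G", "D", "T"), z = 1:3)
  m <- map_snps(idx)
  expect_equal(unname(m$tally["n_excluded_indel"]), 2)
})

test_that("count_nominal uses a strict inequality", {
  expect_equal(count_nominal(rep(1, 5)), 0)
  expect_equal(count_nominal(c(0.049, 0.05, 0.051), 0.05), 1)
  expect_error(count_nominal(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(count_nominal(0.5, alpha = 0), "alpha")
})

test_that("all 22 printed shared-SNP p-values are nominal", {
  t1 <- read_published_snps()
  expect_equal(nrow(t1), 22)
  expect_equal(count_nominal(t1$p_nominal, 0.05), 22)
})

test_that("binomial enrichment matches the printed 1.46e-8 and edge cases", {
  expect_equal(binomial_enrichment(0, 107, 0.05), 1.0)
  expect_equal(binomial_enrichment(5, 5, 0.5), 0.03125)
  p <- binomial_enrichment(22, 107, 0.05)
  expect_equal(signif(p, 3), 1.46e-8)
  expect_error(binomial_enrichment(6, 5, 0.5), "k <= n")
  expect_error(binomial_enrichment(1, 5, 1), "p0")
})

test_that("binomial tail agrees with log-space brute force for n <= 30", {
  # independent oracle: direct summation of the binomial mass in logs
  brute <- function(k, n, p0) {
    if (k == 0) return(1)
    terms <- vapply(k:n, function(j)
      lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0), numeric(1))
    m <- max(terms)
    exp(m + log(sum(exp(terms - m))))
  }
  set.seed(41)
  for (i in 1:50) {
    n <- sample(1:30, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.01, 0.99)
    expect_equal(binomial_enrichment(k, n, p0), brute(k, n, p0),
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni at m = 111 reproduces the printed corrections", {
  t1 <- read_published_snps()
  corr <- bonferroni(t1$p_nominal, 111)
  expect_equal(round(corr[t1$snp_id == "rs2535627"], 4), 0.0052)
  expect_equal(sum(corr < 0.05), 2)
  # the >0.9999 display convention kicks in above the cutoff
  expect_equal(format_bonferroni(corr[t1$snp_id == "rs3735025"]),
               ">0.9999")
  expect_equal(format_bonferroni(corr[t1$snp_id == "rs211829"]), "0.9768")
})

test_that("bonferroni is monotone and capped at 1", {
  expect_equal(bonferroni(0, 5), 0)
  expect_equal(bonferroni(0.5, 3), 1)
  p <- sort(runif(20))
  expect_true(all(diff(bonferroni(p, 7)) >= 0))
  expect_true(all(bonferroni(p, 50) >= bonferroni(p, 10)))
  expect_true(all(bonferroni(p, 1e6) <= 1))
  expect_error(bonferroni(0.5, 0), "m")
})

test_that("direction concordance counts sign agreement, zeros discordant", {
  expect_equal(direction_concordance(c(1, 2), c(3, 0.1))$fraction, 1)
  expect_equal(direction_concordance(c(1, 1), c(1, -1))$fraction, 0.5)
  dz <- direction_concordance(c(1, 0), c(1, 1))
  expect_equal(dz$fraction, 0.5)
  expect_identical(dz$zero_flag, c(FALSE, TRUE))
})

test_that("truly shared loci are overwhelmingly direction-concordant", {
  set.seed(42)
  hits <- 0
  for (r in 1:20) {
    eff <- sample(c(-4, 4), 22, replace = TRUE)
    z1 <- eff + rnorm(22)
    z2 <- eff + rnorm(22)
    hits <- hits + (direction_concordance(z1, z2)$fraction > 0.9)
  }
  expect_gte(hits, 18)
})

test_that("build_report sorts, tie-breaks and keeps counts consistent", {
  snps <- sumstats(paste0("r", 1:5), c("2", "1", "1", "3", "1"),
                   c(500L, 900L, 100L, 50L, 200L), rep("A", 5),
                   rep("G", 5), z = c(2.5, 0.1, 1.2, 2.2, 0.1))
  p_corr <- c(0.01, 0.9, 0.2, 0.01, 0.9)
  rep <- build_report(snps, p_corr, m = 111, alpha = 0.05)
  # ascending p; ties broken by chromosome then position
  expect_equal(rep$table_full$snp_id, c("r1", "r4", "r3", "r5", "r2"))
  expect_equal(nrow(rep$table_nominal), 2)
  expect_equal(unname(rep$counts["n_nominal"]),
               count_nominal(p_corr, 0.05))
  expect_equal(rep$enrichment_p, binomial_enrichment(2, 5, 0.05))
  expect_true(all(rep$table_full$p_bonferroni >=
                    rep$table_full$p_corrected))
})

test_that("nearby genes are joined within the flanking window", {
  snps <- sumstats(c("r1", "r2"), "1", c(52000L, 450000L),
                   c("A", "T"), c("G", "C"), z = c(3, 3))
  rep <- build_report(snps, c(0.01, 0.02), m = 2, alpha = 0.05,
                      genes = toy_annotation(), gene_flank_bp = 5000)
  tab <- rep$table_full
  expect_equal(tab$nearby_gene[tab$snp_id == "r1"], "g2")
  expect_true(is.na(tab$nearby_gene[tab$snp_id == "r2"]))
})

test_that("write_report emits consistent tables and summary JSON", {
  snps <- make_index_list(6, 0, 0)
  rep <- build_report(snps, c(0.01, 0.3, 0.6, 0.02, 0.9, 0.04),
                      m = 10, alpha = 0.05)
  dir <- tempfile()
  write_report(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$n_nominal, 3)
  expect_equal(js$enrichment_p, rep$enrichment_p)
  tab <- read.table(file.path(dir, "shared_loci_full.tsv"), header = TRUE,
                    sep = "\t")
  expect_equal(nrow(tab), 6)
})
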