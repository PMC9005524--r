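# A model that leans entirely on the flanking-deletion feature: lets us force
# a high probability on loci whose depth features show no change, to exercise
# the secondary checks in isolation.
flank_only_model <- function() {
  set.seed(12)
  n <- 200L
  flank <- rep(0:1, each = n / 2)
  d <- data.frame(loh = flank == 0,
                  adjusted_baf = runif(n, 0, 0.05),
                  as_depth_ratio = runif(n, 0.95, 1.05),
                  consistency = runif(n, 0.5, 1),
                  total_depth_ratio = runif(n, 1.9, 2.1),
                  purity = runif(n, 0.1, 1),
                  ploidy = 2, flank_deletion = flank)
  loh_model(loh ~ ., data = d, seed = 2L)
}

constructed_locus <- function(sites, ref_len = 600L, flank_b = 1L,
                              purity = 0.8) {
  gi <- default_gene_intervals()$A
  seg <- data.frame(chrom = gi$chrom, start = gi$start - 1000L,
                    end = gi$end + 1000L, a_copy = 1L, b_copy = flank_b)
  loh_locus(gene = "A", alleles = c("A*01:01", "A*02:01"), sites = sites,
            ref_len = ref_len, r_t = 1e8, r_n = 1e8, purity = purity,
            ploidy = 2, segments = seg, gene_interval = gi)
}

per_bin_sites <- function(ratios_a, ratios_b, depth_n = 100L) {
  n <- length(ratios_a)
  coord <- (seq_len(n) - 1L) * 150L + 10L
  site_depths(coord,
              ad_t = as.integer(round(depth_n * ratios_a)),
              bd_t = as.integer(round(depth_n * ratios_b)),
              ad_n = rep(depth_n, n), bd_n = rep(depth_n, n))
}

test_that("secondary checks revoke high-probability calls but never create them", {
  fit <- flank_only_model()
  # flanking deletion fires the model, but depth features show no change
  s <- per_bin_sites(rep(1, 4), rep(1, 4))
  lc <- constructed_locus(s, flank_b = 0L)
  cl <- call_locus(fit, lc)
  expect_gt(cl$probability, fit$config$probability_threshold)
  expect_false(cl$secondary_check_passed)
  expect_equal(cl$status, "no-LOH")
  expect_length(cl$deleted_alleles, 0L)
  # a locus failing the probability threshold stays no-LOH even with passing
  # secondary features
  s2 <- per_bin_sites(rep(1, 4), rep(0.3, 4))
  lc2 <- constructed_locus(s2, flank_b = 1L)
  cl2 <- call_locus(flank_only_model(), lc2)
  if (cl2$probability < 0.5) expect_equal(cl2$status, "no-LOH")
  # statuses are a function of (model, locus): deterministic
  expect_identical(call_locus(fit, lc)$probability, cl$probability)
})

test_that("the deleted allele is the one with lower normalized depth", {
  fit <- shared_model()
  lc <- simulate_locus(fixture_params(), seed = 41L, loh = TRUE, purity = 0.9,
                       clonality = 1, deleted = 2, flank_del = TRUE)
  cl <- call_locus(fit, lc)
  expect_equal(cl$status, "LOH")
  expect_equal(cl$deleted_alleles, lc$alleles[2])
  lc1 <- simulate_locus(fixture_params(), seed = 42L, loh = TRUE, purity = 0.9,
                        clonality = 1, deleted = 1, flank_del = TRUE)
  cl1 <- call_locus(fit, lc1)
  expect_equal(cl1$deleted_alleles, lc1$alleles[1])
})

test_that("bi-allelic deletions are flagged at the 25%-of-bins boundary", {
  fit <- shared_model()
  # allele a deep-deleted everywhere; allele b ratio < 0.5 in exactly 1 of 4
  # bins -> 25% of bins, boundary included -> both deleted
  s_bi <- per_bin_sites(rep(0.05, 4), c(1, 1, 1, 0.4))
  cl_bi <- call_locus(fit, constructed_locus(s_bi, flank_b = 0L, purity = 1))
  expect_equal(cl_bi$status, "LOH")
  expect_setequal(cl_bi$deleted_alleles, c("A*01:01", "A*02:01"))
  # retained allele healthy in all bins -> single-allele deletion
  s_one <- per_bin_sites(rep(0.05, 4), rep(1, 4))
  cl_one <- call_locus(fit, constructed_locus(s_one, flank_b = 0L, purity = 1))
  expect_equal(cl_one$status, "LOH")
  expect_equal(cl_one$deleted_alleles, "A*01:01")
  # below the boundary (0 of 4 bins at ratio 0.55) -> single
  s_nb <- per_bin_sites(rep(0.05, 4), rep(0.55, 4))
  cl_nb <- call_locus(fit, constructed_locus(s_nb, flank_b = 0L, purity = 1))
  expect_equal(cl_nb$deleted_alleles, "A*01:01")
})

test_that("undefined features produce an explicit no-call", {
  fit <- shared_model()
  s <- site_depths(c(10L, 200L), ad_t = c(50L, 50L), bd_t = c(50L, 50L),
                   ad_n = c(2L, 2L), bd_n = c(2L, 2L))
  cl <- call_locus(fit, constructed_locus(s))
  expect_equal(cl$status, "no-call")
  expect_true(is.na(cl$probability))
})

test_that("heuristic annotation mirrors manual-labeling criteria with an audit trail", {
  # pure clonal loss with flanking deletion: criteria 1-4 all fire
  s_loh <- per_bin_sites(rep(1, 4), rep(0, 4))
  ann <- annotate_locus_heuristic(constructed_locus(s_loh, flank_b = 0L,
                                                    purity = 1))
  expect_equal(ann$label, "LOH")
  expect_true(all(ann$criteria[c("c1_consistent_depth", "c2_baf_shift",
                                 "c3_ratio_depleted", "c4_flank_deletion")]))
  # no-change locus
  s_flat <- per_bin_sites(rep(1, 4), rep(1, 4))
  ann0 <- annotate_locus_heuristic(constructed_locus(s_flat))
  expect_equal(ann0$label, "no-LOH")
  # weak low-purity loss: relaxation recorded in the audit trail
  set.seed(6)
  lc_weak <- simulate_locus(fixture_params(), loh = TRUE, purity = 0.15,
                            clonality = 1)
  ann_w <- annotate_locus_heuristic(lc_weak)
  expect_true(ann_w$criteria[["c5_low_purity_relaxation"]])
  expect_true(any(grepl("relaxed", ann_w$notes)))
})

test_that("call tables collect one row per locus", {
  fit <- shared_model()
  loci <- lapply(43:45, function(sd) simulate_locus(fixture_params(), seed = sd))
  tab <- calls_table(lapply(loci, function(lc) call_locus(fit, lc)))
  expect_equal(nrow(tab), 3L)
  expect_true(all(c("probability", "status", "deleted_alleles") %in% names(tab)))
})
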