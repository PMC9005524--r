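test_that("bins tile the reference at 150 bp anchored at coordinate 0", {
  b <- make_bins(c(10L, 200L, 440L), 450L)
  expect_equal(b$bin, c(0L, 1L, 2L))
  expect_equal(b$n_bins, 3L)
  expect_equal(make_bins(integer(0), 400L)$n_bins, 3L)  # last bin short
  set.seed(5)
  coords <- sort(sample(0:3199, 60))
  expect_equal(make_bins(coords, 3200L)$bin, coords %/% 150L)
})

test_that("adjusted BAF is 0 when tumor and normal allelic balance agree", {
  # balanced sites plus capture-biased sites with normal BAF 0.35
  s <- make_flat_sites(ref_len = 1500L)
  biased <- site_depths(s$coord, ad_t = rep(130L, nrow(s)),
                        bd_t = rep(70L, nrow(s)),
                        ad_n = rep(130L, nrow(s)), bd_n = rep(70L, nrow(s)))
  expect_equal(adjusted_baf(s, 1500L), 0)
  expect_equal(adjusted_baf(biased, 1500L), 0)
  # literal reading: bin score is the absolute ratio itself -> 1 at no change
  expect_equal(adjusted_baf(s, 1500L, literal = TRUE), 1)
})

test_that("pure clonal loss of the b allele drives adjusted BAF to 1", {
  s <- make_flat_sites(ref_len = 1500L)
  s$bd_t <- rep(0L, nrow(s))
  s <- site_depths(s$coord, s$ad_t, s$bd_t, s$ad_n, s$bd_n)
  expect_equal(adjusted_baf(s, 1500L), 1)
})

test_that("depth ratio features hit their forced values on constructed loci", {
  s <- make_flat_sites(ref_len = 1500L)
  # tumor == normal, equal read totals -> AS ratio 1, total ratio 2
  expect_equal(as_depth_ratio(s, 1500L, r_t = 1e8, r_n = 1e8), 1)
  expect_equal(total_depth_ratio(s, 1500L, r_t = 1e8, r_n = 1e8), 2)
  # allele-2 tumor depth halved -> AS ratio 0.5, total 1.5
  s2 <- site_depths(s$coord, s$ad_t, s$bd_t %/% 2L, s$ad_n, s$bd_n)
  expect_equal(as_depth_ratio(s2, 1500L, 1e8, 1e8), 0.5)
  expect_equal(total_depth_ratio(s2, 1500L, 1e8, 1e8), 1.5)
  # clonal one-allele loss at purity 1 -> total ratio 1 + 0 = 1
  s3 <- site_depths(s$coord, s$ad_t, rep(0L, nrow(s)), s$ad_n, s$bd_n)
  expect_equal(total_depth_ratio(s3, 1500L, 1e8, 1e8), 1)
  expect_equal(as_depth_ratio(s3, 1500L, 1e8, 1e8), 0)
})

test_that("exome read totals normalize depth ratios", {
  s <- make_flat_sites(ref_len = 1500L)
  # tumor sequenced twice as deep exome-wide: ratios cancel back to 1 and 2
  s2 <- site_depths(s$coord, s$ad_t * 2L, s$bd_t * 2L, s$ad_n, s$bd_n)
  expect_equal(as_depth_ratio(s2, 1500L, r_t = 2e8, r_n = 1e8), 1)
  expect_equal(total_depth_ratio(s2, 1500L, r_t = 2e8, r_n = 1e8), 2)
})

test_that("consistency scores bin votes and splits empty bins evenly", {
  s <- make_flat_sites(ref_len = 1500L)
  expect_equal(depth_consistency(s, 1500L), 0.5)  # all ties
  s1 <- site_depths(s$coord, s$ad_t + 10L, s$bd_t, s$ad_n, s$bd_n)
  expect_equal(depth_consistency(s1, 1500L), 1)   # allele 1 higher everywhere
  # 4 bins: allele 1 higher in 3, the 4th empty -> max(mean(1,1,1,.5), ...) = 0.875
  coord <- c(10L, 160L, 310L)
  s4 <- site_depths(coord, ad_t = c(50L, 50L, 50L), bd_t = c(20L, 20L, 20L),
                    ad_n = c(40L, 40L, 40L), bd_n = c(40L, 40L, 40L))
  expect_equal(depth_consistency(s4, 600L), 0.875)
})

test_that("flanking deletion flag respects the 10 kb window and b-copy zero", {
  gi <- list(chrom = "6", start = 100000L, end = 103000L)
  seg <- function(start, end, b) {
    data.frame(chrom = "6", start = start, end = end, a_copy = 1L, b_copy = b)
  }
  expect_equal(flank_deletion(seg(101000L, 102000L, 0L), gi), 0)
  # deletion ending exactly 10,001 bp upstream of the gene -> outside
  expect_equal(flank_deletion(seg(80000L, 100000L - 10001L, 0L), gi), 1)
  # ending 9,999 bp upstream -> inside the window
  expect_equal(flank_deletion(seg(80000L, 100000L - 9999L, 0L), gi), 0)
  expect_equal(flank_deletion(seg(90000L, 115000L, 1L), gi), 1)
  # other chromosome ignored
  other <- seg(101000L, 102000L, 0L); other$chrom <- "7"
  expect_equal(flank_deletion(other, gi), 1)
})

test_that("segment tables read in Sequenza and BED-like dialects agree", {
  sq <- data.frame(chromosome = "6", start.pos = 101L, end.pos = 200L,
                   A = 1L, B = 0L, extra = "x")
  f1 <- tempfile(); write.table(sq, f1, sep = "\t", row.names = FALSE, quote = FALSE)
  bed <- data.frame(chrom = "6", start = 100L, end = 200L,
                    a_copy = 1L, b_copy = 0L)
  f2 <- tempfile(); write.table(bed, f2, sep = "\t", row.names = FALSE, quote = FALSE)
  a <- read_segments(f1)
  b <- read_segments(f2)
  expect_equal(a$start, 100L)  # 1-based inclusive converted to 0-based half-open
  expect_equal(a[, c("chrom", "start", "end", "a_copy", "b_copy")],
               b[, c("chrom", "start", "end", "a_copy", "b_copy")])
})

test_that("assembled feature vectors compose the per-feature values", {
  s <- make_flat_sites(ref_len = 1500L)
  gi <- list(chrom = "6", start = 100000L, end = 103000L)
  seg_none <- data.frame(chrom = "6", start = 90000L, end = 115000L,
                         a_copy = 1L, b_copy = 1L)
  f <- locus_features(s, 1500L, 1e8, 1e8, purity = 0.6, ploidy = 2,
                      segments = seg_none, gene_interval = gi)
  expect_equal(names(f), FEATURE_NAMES)
  expect_equal(unname(unlist(f)), c(0, 1, 0.5, 2, 0.6, 2, 1))
  # pure clonal LOH with flanking deletion
  s_loh <- site_depths(s$coord, s$ad_t, rep(0L, nrow(s)), s$ad_n, s$bd_n)
  seg_del <- data.frame(chrom = "6", start = 90000L, end = 115000L,
                        a_copy = 1L, b_copy = 0L)
  f2 <- locus_features(s_loh, 1500L, 1e8, 1e8, purity = 1, ploidy = 2,
                       segments = seg_del, gene_interval = gi)
  expect_equal(unname(unlist(f2)), c(1, 0, 1, 1, 1, 2, 0))
  # purity clipped to [0.1, 1], ploidy floored at 1
  f3 <- locus_features(s, 1500L, 1e8, 1e8, purity = 0.03, ploidy = 0.4)
  expect_equal(f3$purity, 0.1)
  expect_equal(f3$ploidy, 1)
})

test_that("a fully filtered locus yields NA features and no NaN leakage", {
  s <- site_depths(c(10L, 200L), ad_t = c(5L, 5L), bd_t = c(5L, 5L),
                   ad_n = c(2L, 3L), bd_n = c(2L, 3L))  # below the depth floor
  expect_true(is.na(adjusted_baf(s, 450L)))
  expect_true(is.na(as_depth_ratio(s, 450L, 1e8, 1e8)))
  f <- locus_features(s, 450L, 1e8, 1e8, purity = 0.5, ploidy = 2)
  expect_true(anyNA(f))
  expect_false(any(is.nan(unlist(f))))
})

test_that("every feature matches its brute-force oracle on 100 random loci", {
  params <- fixture_params()
  for (i in 1:100) {
    lc <- simulate_locus(params, seed = 1000L + i)
    s <- lc$sites
    expect_equal(adjusted_baf(s, lc$ref_len), oracle_adjusted_baf(s, lc$ref_len),
                 label = sprintf("adjusted_baf locus %d", i))
    expect_equal(as_depth_ratio(s, lc$ref_len, lc$r_t, lc$r_n),
                 oracle_as_ratio(s, lc$ref_len, lc$r_t, lc$r_n),
                 label = sprintf("as_depth_ratio locus %d", i))
    expect_equal(total_depth_ratio(s, lc$ref_len, lc$r_t, lc$r_n),
                 oracle_total_ratio(s, lc$ref_len, lc$r_t, lc$r_n),
                 label = sprintf("total_depth_ratio locus %d", i))
    expect_equal(depth_consistency(s, lc$ref_len),
                 oracle_consistency(s, lc$ref_len),
                 label = sprintf("consistency locus %d", i))
  }
})

test_that("features are invariant under allele relabeling and tumor-mass scaling", {
  params <- fixture_params()
  for (i in 1:20) {
    lc <- simulate_locus(params, seed = 2000L + i)
    s <- lc$sites
    sw <- site_depths(s$coord, ad_t = s$bd_t, bd_t = s$ad_t,
                      ad_n = s$bd_n, bd_n = s$ad_n)
    expect_equal(adjusted_baf(sw, lc$ref_len) == 0,
                 adjusted_baf(s, lc$ref_len) == 0)
    expect_equal(as_depth_ratio(sw, lc$ref_len, lc$r_t, lc$r_n),
                 as_depth_ratio(s, lc$ref_len, lc$r_t, lc$r_n))
    expect_equal(total_depth_ratio(sw, lc$ref_len, lc$r_t, lc$r_n),
                 total_depth_ratio(s, lc$ref_len, lc$r_t, lc$r_n))
    expect_equal(depth_consistency(sw, lc$ref_len),
                 depth_consistency(s, lc$ref_len))
    # doubling all tumor depths and R_T together changes nothing
    s2 <- site_depths(s$coord, s$ad_t * 3L, s$bd_t * 3L, s$ad_n, s$bd_n)
    expect_equal(as_depth_ratio(s2, lc$ref_len, lc$r_t * 3, lc$r_n),
                 as_depth_ratio(s, lc$ref_len, lc$r_t, lc$r_n))
    expect_equal(total_depth_ratio(s2, lc$ref_len, lc$r_t * 3, lc$r_n),
                 total_depth_ratio(s, lc$ref_len, lc$r_t, lc$r_n))
    # ranges
    cons <- depth_consistency(s, lc$ref_len)
    expect_gte(cons, 0.5); expect_lte(cons, 1)
    expect_gte(adjusted_baf(s, lc$ref_len), 0)
    expect_gte(total_depth_ratio(s, lc$ref_len, lc$r_t, lc$r_n),
               as_depth_ratio(s, lc$ref_len, lc$r_t, lc$r_n))
  }
})

test_that("adjusted BAF rises and AS depth ratio falls with effective LOH fraction", {
  params <- fixture_params()
  effs <- c(0, 0.3, 0.6, 1)
  mean_baf <- mean_ratio <- numeric(length(effs))
  set.seed(99)
  for (k in seq_along(effs)) {
    bafs <- ratios <- numeric(40)
    for (i in 1:40) {
      lc <- simulate_locus(params, loh = effs[k] > 0, purity = effs[k],
                           clonality = 1, deleted = 2)
      bafs[i] <- adjusted_baf(lc$sites, lc$ref_len)
      ratios[i] <- as_depth_ratio(lc$sites, lc$ref_len, lc$r_t, lc$r_n)
    }
    mean_baf[k] <- mean(bafs); mean_ratio[k] <- mean(ratios)
  }
  expect_true(all(diff(mean_baf) > 0))
  expect_true(all(diff(mean_ratio) < 0))
})
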