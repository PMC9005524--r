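#' Canonical feature order expected by the classifier
#' @export
FEATURE_NAMES <- c("adjusted_baf", "as_depth_ratio", "consistency",
                   "total_depth_ratio", "purity", "ploidy", "flank_deletion")

#' Site depth table for a heterozygous locus
#'
#' One row per mismatch site between the two homologous alleles, with tumor
#' and normal depth of each allele at that site. Allele 2 is the designated
#' "b" allele, so \code{BAF = bd / (ad + bd)}; the final features are
#' invariant under swapping the two alleles.
#'
#' @param coord 0-based site coordinates in the allele-1 frame.
#' @param ad_t,bd_t tumor depths of allele 1 / allele 2 at each site.
#' @param ad_n,bd_n normal depths of allele 1 / allele 2 at each site.
#' @return data.frame of class \code{site_depths}, sorted by \code{coord},
#'   with added columns \code{baf_t}, \code{baf_n} (NaN when the sample has
#'   zero depth at the site).
#' @export
site_depths <- function(coord, ad_t, bd_t, ad_n, bd_n) {
  stopifnot(all(ad_t >= 0), all(bd_t >= 0), all(ad_n >= 0), all(bd_n >= 0))
  df <- data.frame(coord = as.integer(coord), ad_t = as.integer(round(ad_t)),
                   bd_t = as.integer(round(bd_t)),
                   ad_n = as.integer(round(ad_n)),
                   bd_n = as.integer(round(bd_n)))
  df <- df[order(df$coord), , drop = FALSE]
  df$baf_t <- df$bd_t / (df$ad_t + df$bd_t)
  df$baf_n <- df$bd_n / (df$ad_n + df$bd_n)
  rownames(df) <- NULL
  class(df) <- c("site_depths", "data.frame")
  df
}

#' Assign mismatch sites to fixed 150-bp bins
#'
#' Bins tile \code{[0, ref_len)} anchored at allele-1 coordinate 0; the last
#' bin may be shorter. Sites are assigned by coordinate.
#'
#' @param coords integer site coordinates (0-based, allele-1 frame).
#' @param ref_len allele-1 reference length.
#' @param bin_width bin width in bp (default 150).
#' @return list with \code{bin} (0-based bin index per site) and
#'   \code{n_bins}.
#' @export
make_bins <- function(coords, ref_len, bin_width = 150L) {
  stopifnot(ref_len >= 1L, all(coords >= 0L), all(coords < ref_len))
  list(bin = as.integer(coords %/% bin_width),
       n_bins = as.integer(ceiling(ref_len / bin_width)))
}

# Sites usable for the BAF- and ratio-based features: enough normal depth to
# trust the normal BAF, and a normal BAF strictly inside (0,1) (a normal BAF
# at 0 or 1 is a capture artifact and would make the adjustment degenerate).
usable_sites <- function(sites, min_normal_depth = 10L) {
  (sites$ad_n + sites$bd_n) >= min_normal_depth &
    !is.nan(sites$baf_n) & sites$baf_n > 0 & sites$baf_n < 1
}

bin_median <- function(x, bin, n_bins) {
  out <- rep(NA_real_, n_bins)
  if (length(x) > 0L) {
    agg <- tapply(x, factor(bin, levels = 0:(n_bins - 1L)), stats::median,
                  na.rm = TRUE)
    out <- as.numeric(agg)
  }
  out
}

#' Adjusted b-allele frequency feature
#'
#' At each usable mismatch site the tumor BAF is divided by the normal BAF,
#' cancelling allele-specific probe-capture bias. Ratios are summarised per
#' 150-bp bin by their median, each bin scored by the absolute deviation of
#' that median from 1, and the feature is the median bin score. It is 0 when
#' tumor and normal show the same allelic balance and grows with allelic
#' imbalance; complete clonal loss of the b allele gives |0/BAF_N - 1| = 1.
#'
#' With \code{literal = TRUE} the bin score is instead the median of
#' \code{abs(BAF_T/BAF_N)} (the ratio's absolute value, not its deviation
#' from 1), an alternative reading under which the no-change value is 1
#' rather than 0.
#'
#' @param sites \code{site_depths}.
#' @param ref_len allele-1 reference length.
#' @param min_normal_depth site usability floor on normal depth (default 10).
#' @param literal use the absolute-ratio bin score (default FALSE).
#' @return Non-negative scalar, or NA (no-call) when no site is usable.
#' @export
adjusted_baf <- function(sites, ref_len, min_normal_depth = 10L,
                         literal = FALSE) {
  use <- usable_sites(sites, min_normal_depth) & !is.nan(sites$baf_t)
  s <- sites[use, , drop = FALSE]
  if (nrow(s) == 0L) return(NA_real_)
  b <- make_bins(s$coord, ref_len)
  r <- s$baf_t / s$baf_n
  m <- bin_median(r, b$bin, b$n_bins)
  score <- if (literal) {
    bin_median(abs(r), b$bin, b$n_bins)
  } else {
    abs(m - 1)
  }
  stats::median(score[!is.na(score)])
}

# Per-bin medians of exome-normalized tumor/normal depth ratio, one column
# per allele. Sites need normal depth > 0 for the allele (and the usability
# floor); bins where either allele has no valid site are NA.
allele_bin_ratios <- function(sites, ref_len, r_t, r_n,
                              min_normal_depth = 10L) {
  stopifnot(r_t > 0, r_n > 0)
  use <- usable_sites(sites, min_normal_depth)
  s <- sites[use, , drop = FALSE]
  n_bins <- make_bins(integer(0), ref_len)$n_bins
  out <- matrix(NA_real_, nrow = n_bins, ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  if (nrow(s) > 0L) {
    b <- make_bins(s$coord, ref_len)
    ok_a <- s$ad_n > 0
    ok_b <- s$bd_n > 0
    out[, "a"] <- bin_median((s$ad_t[ok_a] / s$ad_n[ok_a]) * (r_n / r_t),
                             b$bin[ok_a], b$n_bins)
    out[, "b"] <- bin_median((s$bd_t[ok_b] / s$bd_n[ok_b]) * (r_n / r_t),
                             b$bin[ok_b], b$n_bins)
  }
  out
}

#' Allele-specific sequencing depth ratio feature
#'
#' Per site and allele, tumor depth over normal depth, normalized by the
#' exome-wide tumor/normal read totals so the no-change expectation is 1
#' regardless of sequencing mass. Per bin, the median ratio is computed for
#' each allele and the lower of the two allele medians represents the bin;
#' the feature is the median over bins where both allele medians are
#' defined. Values well below 1 indicate loss of one allele.
#'
#' @param sites \code{site_depths}.
#' @param ref_len allele-1 reference length.
#' @param r_t,r_n exome-wide read totals for tumor and normal.
#' @param min_normal_depth site usability floor (default 10).
#' @return Non-negative scalar, or NA when no bin is usable.
#' @export
as_depth_ratio <- function(sites, ref_len, r_t, r_n, min_normal_depth = 10L) {
  m <- allele_bin_ratios(sites, ref_len, r_t, r_n, min_normal_depth)
  lo <- pmin(m[, "a"], m[, "b"])
  if (all(is.na(lo))) return(NA_real_)
  stats::median(lo, na.rm = TRUE)
}

#' Total sequencing depth ratio feature
#'
#' Same per-allele normalized bin medians as [as_depth_ratio()], but each bin
#' is represented by the sum of the two allele medians; the feature is the
#' median over usable bins. The no-change expectation is 2; clonal loss of
#' one allele in a pure tumor gives 1; values well above 2 point to
#' amplification of the retained allele rather than deletion.
#'
#' @inheritParams as_depth_ratio
#' @return Non-negative scalar, or NA when no bin is usable.
#' @export
total_depth_ratio <- function(sites, ref_len, r_t, r_n,
                              min_normal_depth = 10L) {
  m <- allele_bin_ratios(sites, ref_len, r_t, r_n, min_normal_depth)
  tot <- m[, "a"] + m[, "b"]
  if (all(is.na(tot))) return(NA_real_)
  stats::median(tot, na.rm = TRUE)
}

#' Consistency of sequencing depth feature
#'
#' Each 150-bp bin votes for the allele with the higher median tumor depth
#' over its mismatch sites (1 for the higher allele, 0 for the lower, 0.5
#' each on ties or when the bin holds no site). Per-allele scores are the
#' mean vote over all bins, and the feature is the larger of the two. An
#' allele that is consistently lower across the whole gene — the signature of
#' a real deletion rather than stochastic depth variation — drives the
#' feature towards 1; balanced alleles give 0.5.
#'
#' @param sites \code{site_depths}.
#' @param ref_len allele-1 reference length.
#' @return Scalar in [0.5, 1].
#' @export
depth_consistency <- function(sites, ref_len) {
  n_bins <- make_bins(integer(0), ref_len)$n_bins
  if (nrow(sites) == 0L) return(0.5)
  b <- make_bins(sites$coord, ref_len)
  med_a <- bin_median(sites$ad_t, b$bin, b$n_bins)
  med_b <- bin_median(sites$bd_t, b$bin, b$n_bins)
  vote_a <- ifelse(is.na(med_a) | is.na(med_b) | med_a == med_b, 0.5,
                   as.numeric(med_a > med_b))
  max(mean(vote_a), mean(1 - vote_a))
}

#' Read an allele-specific copy-number segment table
#'
#' Supports the Sequenza \code{*_segments.txt} layout (columns
#' \code{chromosome}, \code{start.pos}, \code{end.pos}, \code{A}, \code{B};
#' 1-based inclusive coordinates) and a generic BED-like TSV with columns
#' \code{chrom}, \code{start}, \code{end}, \code{a_copy}, \code{b_copy}
#' (0-based half-open). Both are converted to 0-based half-open internally.
#'
#' @param path segment table path.
#' @param format "auto", "sequenza" or "bed".
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{a_copy}, \code{b_copy}.
#' @export
read_segments <- function(path, format = c("auto", "sequenza", "bed")) {
  format <- match.arg(format)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (format == "auto") {
    format <- if (all(c("chromosome", "start.pos", "end.pos") %in% names(df)))
      "sequenza" else "bed"
  }
  if (format == "sequenza") {
    out <- data.frame(chrom = as.character(df$chromosome),
                      start = df$start.pos - 1L, end = df$end.pos,
                      a_copy = df$A, b_copy = df$B)
  } else {
    need <- c("chrom", "start", "end", "a_copy", "b_copy")
    if (!all(need %in% names(df))) {
      stop("BED-like segment table needs columns: ", paste(need, collapse = ", "))
    }
    out <- df[, need]
    out$chrom <- as.character(out$chrom)
  }
  stopifnot(all(out$start < out$end), all(out$b_copy >= 0))
  out
}

#' Flanking-region deletion feature
#'
#' Most HLA LOH events arise from deletions much larger than the gene itself,
#' so a b-allele copy number of zero in any segment within \code{window} bp
#' of the gene is strong supporting evidence. Binary: 0 when such a segment
#' overlaps the flanked interval, 1 otherwise.
#'
#' @param segments segment data.frame (see [read_segments()]).
#' @param gene_interval list or vector with \code{chrom}, \code{start},
#'   \code{end} (0-based half-open).
#' @param window flank size in bp each side (default 10000).
#' @return 0 (deletion present) or 1 (no deletion).
#' @export
flank_deletion <- function(segments, gene_interval, window = 10000L) {
  gi <- as.list(gene_interval)
  lo <- as.numeric(gi$start) - window
  hi <- as.numeric(gi$end) + window
  hit <- segments$chrom == gi$chrom & segments$b_copy == 0 &
    segments$end > lo & segments$start < hi
  if (any(hit)) 0 else 1
}

#' Default HLA class I gene intervals (hs37d5, chromosome 6, 0-based)
#' @return Named list of \code{list(chrom, start, end)} for genes A, B, C.
#' @export
default_gene_intervals <- function() {
  list(A = list(chrom = "6", start = 29910246L, end = 29913661L),
       B = list(chrom = "6", start = 31321648L, end = 31324989L),
       C = list(chrom = "6", start = 31236525L, end = 31239913L))
}

#' Assemble the full feature vector for one heterozygous locus
#'
#' Combines the four allele-specific features with tumor purity (clipped to
#' [0.1, 1]), tumor ploidy (rounded to an integer >= 1) and the
#' flanking-deletion flag, in the canonical order \code{FEATURE_NAMES}.
#'
#' @param sites \code{site_depths} for the locus.
#' @param ref_len allele-1 reference length.
#' @param r_t,r_n exome-wide read totals.
#' @param purity tumor purity estimate.
#' @param ploidy tumor ploidy estimate.
#' @param segments segment table, or NULL to skip the flanking feature
#'   (recorded as 1).
#' @param gene_interval gene interval for the flanking feature.
#' @param min_normal_depth site usability floor (default 10).
#' @param baf_literal passed to [adjusted_baf()].
#' @return One-row data.frame with columns \code{FEATURE_NAMES}; any NA
#'   allele-specific feature marks the locus as a no-call.
#' @export
locus_features <- function(sites, ref_len, r_t, r_n, purity, ploidy,
                           segments = NULL, gene_interval = NULL,
                           min_normal_depth = 10L, baf_literal = FALSE) {
  fd <- if (is.null(segments) || is.null(gene_interval)) 1 else
    flank_deletion(segments, gene_interval)
  out <- data.frame(
    adjusted_baf = adjusted_baf(sites, ref_len, min_normal_depth,
                                literal = baf_literal),
    as_depth_ratio = as_depth_ratio(sites, ref_len, r_t, r_n,
                                    min_normal_depth),
    consistency = depth_consistency(sites, ref_len),
    total_depth_ratio = total_depth_ratio(sites, ref_len, r_t, r_n,
                                          min_normal_depth),
    purity = min(max(purity, 0.1), 1),
    ploidy = max(round(ploidy), 1),
    flank_deletion = fd
  )
  out[, FEATURE_NAMES]
}
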