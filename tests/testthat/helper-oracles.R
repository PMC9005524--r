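# Straight-line brute-force recomputations of the locus features, written
# independently of the package internals: explicit loops over sites and bins,
# no shared helpers.

oracle_usable <- function(s, min_n = 10L) {
  (s$ad_n + s$bd_n) >= min_n & (s$ad_n + s$bd_n) > 0 &
    s$bd_n / (s$ad_n + s$bd_n) > 0 & s$bd_n / (s$ad_n + s$bd_n) < 1
}

oracle_adjusted_baf <- function(s, ref_len, min_n = 10L) {
  n_bins <- ceiling(ref_len / 150)
  keep <- oracle_usable(s, min_n) & (s$ad_t + s$bd_t) > 0
  scores <- c()
  for (b in 0:(n_bins - 1)) {
    rs <- c()
    for (i in seq_len(nrow(s))) {
      if (keep[i] && s$coord[i] %/% 150 == b) {
        baf_t <- s$bd_t[i] / (s$ad_t[i] + s$bd_t[i])
        baf_n <- s$bd_n[i] / (s$ad_n[i] + s$bd_n[i])
        rs <- c(rs, baf_t / baf_n)
      }
    }
    if (length(rs) > 0) scores <- c(scores, abs(median(rs) - 1))
  }
  if (length(scores) == 0) NA_real_ else median(scores)
}

oracle_bin_ratio <- function(s, ref_len, r_t, r_n, allele, min_n = 10L) {
  n_bins <- ceiling(ref_len / 150)
  keep <- oracle_usable(s, min_n)
  out <- rep(NA_real_, n_bins)
  for (b in 0:(n_bins - 1)) {
    rs <- c()
    for (i in seq_len(nrow(s))) {
      if (keep[i] && s$coord[i] %/% 150 == b) {
        dt <- if (allele == 1) s$ad_t[i] else s$bd_t[i]
        dn <- if (allele == 1) s$ad_n[i] else s$bd_n[i]
        if (dn > 0) rs <- c(rs, (dt / dn) * (r_n / r_t))
      }
    }
    if (length(rs) > 0) out[b + 1] <- median(rs)
  }
  out
}

oracle_as_ratio <- function(s, ref_len, r_t, r_n, min_n = 10L) {
  m1 <- oracle_bin_ratio(s, ref_len, r_t, r_n, 1, min_n)
  m2 <- oracle_bin_ratio(s, ref_len, r_t, r_n, 2, min_n)
  lo <- pmin(m1, m2)
  if (all(is.na(lo))) NA_real_ else median(lo[!is.na(lo)])
}

oracle_total_ratio <- function(s, ref_len, r_t, r_n, min_n = 10L) {
  m1 <- oracle_bin_ratio(s, ref_len, r_t, r_n, 1, min_n)
  m2 <- oracle_bin_ratio(s, ref_len, r_t, r_n, 2, min_n)
  tot <- m1 + m2
  if (all(is.na(tot))) NA_real_ else median(tot[!is.na(tot)])
}

oracle_consistency <- function(s, ref_len) {
  n_bins <- ceiling(ref_len / 150)
  if (nrow(s) == 0) return(0.5)
  v1 <- v2 <- numeric(0)
  for (b in 0:(n_bins - 1)) {
    in_bin <- s$coord %/% 150 == b
    if (!any(in_bin)) {
      v1 <- c(v1, 0.5); v2 <- c(v2, 0.5)
    } else {
      m1 <- median(s$ad_t[in_bin]); m2 <- median(s$bd_t[in_bin])
      if (m1 > m2) { v1 <- c(v1, 1); v2 <- c(v2, 0) }
      else if (m2 > m1) { v1 <- c(v1, 0); v2 <- c(v2, 1) }
      else { v1 <- c(v1, 0.5); v2 <- c(v2, 0.5) }
    }
  }
  max(mean(v1), mean(v2))
}

# Brute-force pileup: count reads covering each position one by one.
oracle_pileup <- function(reads, L) {
  d <- integer(L)
  for (p in seq_len(L) - 1L) {
    for (i in seq_len(nrow(reads))) {
      if (reads$start[i] <= p && p < reads$start[i] + reads$aligned_length[i])
        d[p + 1L] <- d[p + 1L] + 1L
    }
  }
  d
}

# Constructed no-change locus: identical tumor/normal depths, all bins
# populated, optionally biased normal BAF.
make_flat_sites <- function(ref_len = 1500L, per_bin = 4L, ad = 120L,
                            bd = 120L) {
  n_bins <- ref_len %/% 150L
  coord <- as.vector(vapply(0:(n_bins - 1L), function(b)
    b * 150L + seq(10L, by = 30L, length.out = per_bin), integer(per_bin)))
  site_depths(coord, ad_t = rep(ad, length(coord)),
              bd_t = rep(bd, length(coord)),
              ad_n = rep(ad, length(coord)), bd_n = rep(bd, length(coord)))
}
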