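#' Parameters for the synthetic fixture generator
#'
#' Defaults emulate a deeply sequenced, HLA-boosted paired exome: per-locus
#' mean site coverage around 500x with negative-binomial overdispersion,
#' allele-specific capture bias around a balanced normal BAF, an LOH
#' prevalence of 19.6% among heterozygous loci, and flanking deletions
#' accompanying 73% of LOH events.
#'
#' @param n_loci number of loci in a cohort (default 720).
#' @param sites_range range of mismatch-site counts per locus (default
#'   30-80).
#' @param allele_len allele reference length in bp (default 3200).
#' @param sigma_bias spread of the allele-1 capture fraction around 0.5
#'   (default 0.08), reflecting allele-specific probe capture.
#' @param coverage_normal,coverage_tumor mean total site coverage per sample
#'   (default 500 each).
#' @param dispersion negative-binomial dispersion of site coverage (default
#'   0.1; variance mu + dispersion * mu^2).
#' @param prevalence fraction of loci with planted LOH (default 0.196).
#' @param flank_del_frac fraction of LOH events accompanied by a flanking
#'   b-allele deletion segment (default 0.73).
#' @param purity_range range from which tumor purity is drawn uniformly
#'   (default 0.15-1).
#' @param clonal_prob probability an LOH event is fully clonal (default
#'   0.7); otherwise clonality is uniform over \code{clonality_range}.
#' @param clonality_range subclonal clonality range (default 0.3-1).
#' @param indel_frac fraction of mismatch sites that are indel first
#'   positions rather than SNVs (default 0.1).
#' @param exome_reads exome-wide read total for both samples (default 4e8).
#' @param seed master seed.
#' @return list of class \code{fixture_params}.
#' @export
fixture_params <- function(n_loci = 720L, sites_range = c(30L, 80L),
                           allele_len = 3200L, sigma_bias = 0.08,
                           coverage_normal = 500, coverage_tumor = 500,
                           dispersion = 0.1, prevalence = 0.196,
                           flank_del_frac = 0.73,
                           purity_range = c(0.15, 1), clonal_prob = 0.7,
                           clonality_range = c(0.3, 1), indel_frac = 0.1,
                           exome_reads = 4e8, seed = 1L) {
  structure(as.list(environment()), class = "fixture_params")
}

rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, size = 1 / dispersion, mu = mu)
}

# Draw site depths for both alleles of one sample. Total site depth is
# negative-binomial; the allele split given the total is binomial, so each
# allele depth is marginally NB with the same dispersion while the BAF noise
# matches read sampling.
draw_site_depths <- function(n_sites, coverage, rel_a, rel_b, dispersion) {
  mu <- coverage * (rel_a + rel_b)
  tot <- rnb(n_sites, mu, dispersion)
  a <- stats::rbinom(n_sites, tot, rel_a / (rel_a + rel_b))
  list(a = a, b = tot - a)
}

#' Simulate one heterozygous locus with optional planted LOH
#'
#' Draws mismatch-site coordinates, an allele-specific capture bias, and
#' tumor/normal depths at each site. Under planted LOH of effective fraction
#' e = purity x clonality, the lost allele's expected tumor depth scales by
#' (1 - e) while the retained allele is unchanged; without LOH the tumor
#' marginals equal the normal marginals. Segment rows reflect the planted
#' flanking-deletion truth.
#'
#' @param params \code{fixture_params}.
#' @param seed optional seed for this locus.
#' @param loh plant an LOH event? Drawn from \code{params$prevalence} when
#'   NULL.
#' @param purity,clonality,deleted,flank_del optional overrides of the drawn
#'   truth (deleted is 1 or 2, the index of the lost allele).
#' @param gene gene letter (default "A").
#' @param patient patient identifier.
#' @return \code{loh_locus} with an additional \code{truth} element
#'   (\code{loh}, \code{deleted} index, \code{deleted_allele} name,
#'   \code{purity}, \code{clonality}, \code{flank_deletion}) and a
#'   \code{gen} element recording the capture fraction and depth parameters
#'   (used to draw matched normal replicates for mixtures).
#' @export
simulate_locus <- function(params = fixture_params(), seed = NULL,
                           loh = NULL, purity = NULL, clonality = NULL,
                           deleted = NULL, flank_del = NULL, gene = "A",
                           patient = "SIM") {
  if (!is.null(seed)) set.seed(seed)
  n_sites <- sample(params$sites_range[1]:params$sites_range[2], 1L)
  coord <- sort(sample.int(params$allele_len, n_sites) - 1L)
  f <- min(max(stats::rnorm(1, 0.5, params$sigma_bias), 0.25), 0.75)
  if (is.null(loh)) loh <- stats::runif(1) < params$prevalence
  if (is.null(purity)) purity <- stats::runif(1, params$purity_range[1],
                                              params$purity_range[2])
  if (is.null(clonality)) {
    clonality <- if (!loh || stats::runif(1) < params$clonal_prob) 1 else
      stats::runif(1, params$clonality_range[1], params$clonality_range[2])
  }
  if (is.null(deleted)) deleted <- sample(1:2, 1L)
  if (is.null(flank_del)) {
    flank_del <- loh && stats::runif(1) < params$flank_del_frac
  }
  e <- if (loh) purity * clonality else 0
  rel_n <- c(a = f, b = 1 - f)
  rel_t <- rel_n
  rel_t[deleted] <- rel_t[deleted] * (1 - e)
  nd <- draw_site_depths(n_sites, params$coverage_normal, rel_n["a"],
                         rel_n["b"], params$dispersion)
  td <- draw_site_depths(n_sites, params$coverage_tumor, rel_t["a"],
                         rel_t["b"], params$dispersion)
  sites <- site_depths(coord, ad_t = td$a, bd_t = td$b,
                       ad_n = nd$a, bd_n = nd$b)
  ploidy <- sample(1:4, 1L, prob = c(0.05, 0.7, 0.15, 0.1))
  gi <- default_gene_intervals()[[gene]]
  segments <- data.frame(
    chrom = gi$chrom,
    start = gi$start - 50000L, end = gi$end + 50000L,
    a_copy = 1L, b_copy = if (flank_del) 0L else 1L
  )
  alleles <- paste0(gene, "*", sprintf("%02d:01", c(1, 2)))
  locus <- loh_locus(gene = gene, alleles = alleles, sites = sites,
                     ref_len = params$allele_len, r_t = params$exome_reads,
                     r_n = params$exome_reads, purity = purity,
                     ploidy = ploidy, segments = segments,
                     gene_interval = gi, patient = patient)
  locus$truth <- list(loh = loh, deleted = if (loh) deleted else NA_integer_,
                      deleted_allele = if (loh) alleles[deleted] else NA_character_,
                      purity = purity, clonality = if (loh) clonality else NA_real_,
                      flank_deletion = flank_del)
  locus$gen <- list(f = f, coverage_normal = params$coverage_normal,
                    coverage_tumor = params$coverage_tumor,
                    dispersion = params$dispersion)
  locus
}

#' Draw an independent normal replicate of a locus's site depths
#'
#' Uses the locus's own capture fraction and depth parameters, so the
#' replicate is exchangeable with the original normal — the ingredient for
#' mixture tumor slots and negative controls.
#'
#' @param locus \code{loh_locus} produced by [simulate_locus()].
#' @return list with components \code{a} and \code{b}: fresh normal depths
#'   at the locus's sites.
#' @export
simulate_normal_replicate <- function(locus) {
  g <- locus$gen
  stopifnot(!is.null(g))
  draw_site_depths(nrow(locus$sites), g$coverage_normal, g$f, 1 - g$f,
                   g$dispersion)
}

#' Simulate a truth-labeled cohort of heterozygous loci
#'
#' @param params \code{fixture_params}; \code{params$seed} seeds the whole
#'   cohort reproducibly.
#' @return list with \code{loci} (list of \code{loh_locus}), \code{features}
#'   (data.frame: \code{loh} label plus the seven features, one row per
#'   locus) and \code{truth} (data.frame of planted truth).
#' @export
simulate_cohort <- function(params = fixture_params()) {
  set.seed(params$seed)
  genes <- c("A", "B", "C")
  loci <- vector("list", params$n_loci)
  for (i in seq_len(params$n_loci)) {
    loci[[i]] <- simulate_locus(params, gene = genes[(i - 1L) %% 3L + 1L],
                                patient = sprintf("P%04d", (i - 1L) %/% 3L + 1L))
  }
  features <- do.call(rbind, lapply(loci, function(lc)
    cbind(loh = lc$truth$loh,
          locus_features(lc$sites, lc$ref_len, lc$r_t, lc$r_n, lc$purity,
                         lc$ploidy, lc$segments, lc$gene_interval))))
  truth <- do.call(rbind, lapply(loci, function(lc)
    data.frame(patient = lc$patient, gene = lc$gene, loh = lc$truth$loh,
               deleted_allele = lc$truth$deleted_allele,
               purity = lc$truth$purity, clonality = lc$truth$clonality,
               flank_deletion = lc$truth$flank_deletion,
               stringsAsFactors = FALSE)))
  list(loci = loci, features = features, truth = truth)
}

#' Write a cohort's truth table as TSV
#' @param cohort result of [simulate_cohort()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_truth_tsv <- function(cohort, path) {
  utils::write.table(cohort$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a synthetic allele-database fixture (cDNA + gDNA MSA text)
#'
#' Builds a small family of alleles of one gene from a random reference:
#' each non-reference allele carries planted substitutions, and selected
#' gDNA rows have whole segments masked as unsequenced (\code{*}). Masked
#' segments are always identical to those of a 4-digit sibling listed
#' earlier, so imputation can restore the true sequence exactly; the truth
#' sequences are returned for comparison.
#'
#' @param n_alleles number of alleles (>= 3; default 5).
#' @param seed seed.
#' @param gene gene letter (default "A").
#' @param exon_len,intron_len segment lengths (defaults 210 and 120).
#' @param n_exons number of exons (default 3).
#' @param n_subs substitutions per non-reference allele (default 12).
#' @return list with \code{cdna} and \code{gdna} (character vectors of MSA
#'   lines), \code{truth} (named character vector of full-length genomic
#'   sequences), \code{names} (allele names in MSA order) and
#'   \code{masked} (named list of masked segment names per allele).
#' @export
simulate_msa_fixture <- function(n_alleles = 5L, seed = 1L, gene = "A",
                                 exon_len = 210L, intron_len = 120L,
                                 n_exons = 3L, n_subs = 12L) {
  stopifnot(n_alleles >= 3L)
  set.seed(seed)
  seg_names <- character(0)
  seg_len <- integer(0)
  for (k in seq_len(n_exons)) {
    seg_names <- c(seg_names, paste0("exon", k))
    seg_len <- c(seg_len, exon_len)
    if (k < n_exons) {
      seg_names <- c(seg_names, paste0("intron", k))
      seg_len <- c(seg_len, intron_len)
    }
  }
  total <- sum(seg_len)
  ref <- random_dna(total)
  ref_chars <- strsplit(ref, "")[[1]]
  # names: two 4-digit siblings within the first group, then distinct groups
  names_ <- c(sprintf("%s*01:01", gene), sprintf("%s*01:01:02", gene),
              sprintf("%s*01:02", gene))
  if (n_alleles > 3L) {
    names_ <- c(names_, sprintf("%s*%02d:01", gene, seq_len(n_alleles - 3L) + 1L))
  }
  seg_id <- rep(seq_along(seg_names), seg_len)
  truth <- character(n_alleles)
  rows <- character(n_alleles)
  masked <- vector("list", n_alleles)
  names(masked) <- names_
  truth_chars <- vector("list", n_alleles)
  for (i in seq_len(n_alleles)) {
    ch <- ref_chars
    if (i > 1L) {
      pos <- sample.int(total, n_subs)
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
      }
    }
    truth_chars[[i]] <- ch
    truth[i] <- paste(ch, collapse = "")
  }
  names(truth) <- names_
  # allele 2 is a 4-digit sibling of allele 1: make it identical to allele 1
  truth_chars[[2L]] <- truth_chars[[1L]]
  truth[2L] <- truth[1L]
  for (i in seq_len(n_alleles)) {
    ch <- truth_chars[[i]]
    row <- if (i == 1L) ch else ifelse(ch == ref_chars, "-", ch)
    mask <- character(0)
    if (i == 2L) {
      # sibling with unsequenced intron 1 in gDNA; donor = allele 1
      mask <- "intron1"
    } else if (i == 3L && n_exons >= 3L) {
      mask <- "exon3"  # 2-digit-group donor path exercised downstream
    }
    grow <- row
    for (m in mask) grow[seg_id == which(seg_names == m)] <- "*"
    masked[[i]] <- mask
    rows[i] <- paste0(names_[i], " ", paste(grow, collapse = ""))
  }
  seg_header <- paste0("# segments: ",
                       paste(sprintf("%s:%d", seg_names, seg_len),
                             collapse = " "))
  exon_keep <- grepl("^exon", seg_names)
  cdna_rows <- vapply(seq_len(n_alleles), function(i) {
    ch <- truth_chars[[i]]
    row <- if (i == 1L) ch else ifelse(ch == ref_chars, "-", ch)
    paste0(names_[i], " ", paste(row[exon_keep[seg_id]], collapse = ""))
  }, "")
  cdna_header <- paste0("# segments: ",
                        paste(sprintf("%s:%d", seg_names[exon_keep],
                                      seg_len[exon_keep]), collapse = " "))
  list(cdna = c("# hlaloh-msa v1", "# kind: cDNA", cdna_header, cdna_rows),
       gdna = c("# hlaloh-msa v1", "# kind: gDNA", seg_header, rows),
       truth = truth, names = names_, masked = masked)
}

#' Write reads reproducing per-allele depth profiles as a SAM file
#'
#' Deterministically decomposes each allele's per-position depth vector into
#' perfectly aligned reads (CIGAR all-match, NM 0) whose pileup equals the
#' input exactly, and writes them with proper \code{@SQ} headers. Useful for
#' round-trip testing of the SAM reading and depth computation path.
#'
#' @param depths named list of integer depth vectors, one per allele.
#' @param sequences named list of allele reference sequences (must cover the
#'   alleles in \code{depths}).
#' @param path output SAM path.
#' @param max_read_len maximum emitted read length (default 150).
#' @return Invisibly, the path.
#' @export
write_profile_sam <- function(depths, sequences, path, max_read_len = 150L) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted")
  for (al in names(depths)) {
    lines <- c(lines, sprintf("@SQ\tSN:%s\tLN:%d", al,
                              nchar(sequences[[al]])))
  }
  qn <- 0L
  for (al in names(depths)) {
    d <- as.integer(depths[[al]])
    seq_chars <- strsplit(sequences[[al]], "")[[1]]
    while (any(d > 0L)) {
      r <- rle(d > 0L)
      ends <- cumsum(r$lengths)
      begins <- ends - r$lengths + 1L
      pass_cov <- integer(length(d))
      for (j in which(r$values)) {
        s <- begins[j]
        while (s <= ends[j]) {
          len <- min(max_read_len, ends[j] - s + 1L)
          qn <- qn + 1L
          rd <- paste(seq_chars[s:(s + len - 1L)], collapse = "")
          lines <- c(lines, paste(
            sprintf("r%06d", qn), 0L, al, s, 60L, sprintf("%dM", len), "*",
            0L, 0L, rd, strrep("I", len), "NM:i:0", sep = "\t"))
          pass_cov[s:(s + len - 1L)] <- pass_cov[s:(s + len - 1L)] + 1L
          s <- s + len
        }
      }
      d <- d - pass_cov
    }
  }
  writeLines(lines, path)
  invisible(path)
}
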