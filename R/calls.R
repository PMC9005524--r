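#' Bundle everything needed to call one heterozygous locus
#'
#' @param gene gene letter ("A", "B" or "C").
#' @param alleles character vector of the two typed allele names.
#' @param sites \code{site_depths} at the mismatch positions.
#' @param ref_len allele-1 reference length.
#' @param r_t,r_n exome-wide read totals for tumor and normal.
#' @param purity,ploidy tumor purity and ploidy estimates.
#' @param segments optional segment table for the flanking feature.
#' @param gene_interval optional gene interval matching \code{segments}.
#' @param patient optional patient identifier.
#' @return list of class \code{loh_locus}.
#' @export
loh_locus <- function(gene, alleles, sites, ref_len, r_t, r_n, purity,
                      ploidy, segments = NULL, gene_interval = NULL,
                      patient = NA_character_) {
  structure(list(gene = gene, alleles = alleles, sites = sites,
                 ref_len = ref_len, r_t = r_t, r_n = r_n, purity = purity,
                 ploidy = ploidy, segments = segments,
                 gene_interval = gene_interval, patient = patient),
            class = "loh_locus")
}

#' @export
print.loh_locus <- function(x, ...) {
  cat(sprintf("<loh_locus> HLA-%s %s/%s: %d mismatch sites over %d bp, purity %.2f\n",
              x$gene, x$alleles[1], x$alleles[2], nrow(x$sites), x$ref_len,
              x$purity))
  invisible(x)
}

#' Call LOH status for one locus
#'
#' Applies the fitted classifier to the locus feature vector, then the
#' post-hoc decision rules:
#' \itemize{
#'   \item secondary check — a locus is only called LOH when, in addition to
#'     the probability reaching the threshold, its allele-specific depth
#'     ratio is below 0.98 and its adjusted BAF is above 0.02; this guards
#'     specificity at low tumor purity. The checks can only revoke an LOH
#'     call, never create one.
#'   \item deleted-allele assignment — the allele with the lower aggregate
#'     (median over bins) normalized depth ratio is labeled deleted.
#'   \item bi-allelic rule — if the higher-depth allele's per-bin normalized
#'     ratio is itself below 0.5 in at least 25% of informative bins, both
#'     alleles are labeled deleted.
#' }
#' Loci with undefined features (all sites filtered) return status
#' \code{"no-call"}.
#'
#' @param model \code{loh_model}.
#' @param locus \code{loh_locus}.
#' @param features optional precomputed one-row feature data.frame; computed
#'   from the locus when NULL.
#' @return list of class \code{loh_call}: \code{probability}, \code{status}
#'   ("LOH", "no-LOH" or "no-call"), \code{deleted_alleles} (character
#'   vector, empty unless LOH), \code{secondary_check_passed},
#'   \code{features}.
#' @export
call_locus <- function(model, locus, features = NULL) {
  cfg <- model$config
  if (is.null(features)) {
    features <- locus_features(locus$sites, locus$ref_len, locus$r_t,
                               locus$r_n, locus$purity, locus$ploidy,
                               locus$segments, locus$gene_interval)
  }
  if (anyNA(features)) {
    return(structure(list(probability = NA_real_, status = "no-call",
                          deleted_alleles = character(0),
                          secondary_check_passed = NA, features = features,
                          gene = locus$gene, alleles = locus$alleles,
                          patient = locus$patient),
                     class = "loh_call"))
  }
  prob <- predict(model, features)
  secondary <- features$as_depth_ratio < cfg$as_ratio_max &
    features$adjusted_baf > cfg$adjusted_baf_min
  is_loh <- prob >= cfg$probability_threshold && secondary
  deleted <- character(0)
  if (is_loh) {
    m <- allele_bin_ratios(locus$sites, locus$ref_len, locus$r_t, locus$r_n)
    agg_a <- stats::median(m[, "a"], na.rm = TRUE)
    agg_b <- stats::median(m[, "b"], na.rm = TRUE)
    lower <- if (agg_a <= agg_b) 1L else 2L
    higher_col <- if (lower == 1L) "b" else "a"
    deleted <- locus$alleles[lower]
    hv <- m[, higher_col]
    hv <- hv[!is.na(hv)]
    if (length(hv) > 0L &&
        mean(hv < cfg$biallelic_ratio) >= cfg$biallelic_frac) {
      deleted <- locus$alleles
    }
  }
  structure(list(probability = as.numeric(prob),
                 status = if (is_loh) "LOH" else "no-LOH",
                 deleted_alleles = deleted,
                 secondary_check_passed = as.logical(secondary),
                 features = features, gene = locus$gene,
                 alleles = locus$alleles, patient = locus$patient),
            class = "loh_call")
}

#' @export
print.loh_call <- function(x, ...) {
  cat(sprintf("<loh_call> HLA-%s: %s (p = %.3f)%s\n", x$gene, x$status,
              x$probability,
              if (length(x$deleted_alleles) > 0)
                paste0("; deleted: ", paste(x$deleted_alleles, collapse = ", "))
              else ""))
  invisible(x)
}

#' Heuristic annotation of a locus, mirroring manual labeling practice
#'
#' Encodes the visual criteria an analyst applies when labeling HLA LOH from
#' depth plots as a deterministic rule stack, producing a provisional label
#' with a per-criterion audit trail:
#' \enumerate{
#'   \item consistent decrease of one allele's tumor depth (consistency high);
#'   \item consistent shift of tumor vs normal BAF (adjusted BAF elevated);
#'   \item allele-specific normalized depth ratio depleted below 1;
#'   \item flanking segment with b-allele copy number 0;
#'   \item purity scaling — below 30% purity the depth/BAF thresholds of
#'     criteria 2-3 are relaxed, since less substantial shifts are expected;
#'   \item ploidy weighting — at ploidy >= 3 the flanking evidence
#'     (criterion 4) is required, because allele-specific ratios are
#'     unstable in highly aneuploid genomes.
#' }
#' The label is intended only for auditing synthetic truth and triaging
#' borderline loci, never as ground truth for evaluation.
#'
#' @param locus \code{loh_locus}.
#' @param features optional precomputed features.
#' @return list: \code{label} ("LOH"/"no-LOH"), \code{criteria} (named
#'   logical vector c1..c4 plus modifiers), \code{notes} character vector
#'   describing any relaxation applied.
#' @export
annotate_locus_heuristic <- function(locus, features = NULL) {
  if (is.null(features)) {
    features <- locus_features(locus$sites, locus$ref_len, locus$r_t,
                               locus$r_n, locus$purity, locus$ploidy,
                               locus$segments, locus$gene_interval)
  }
  notes <- character(0)
  low_purity <- features$purity < 0.3
  baf_thr <- if (low_purity) 0.05 else 0.10
  ratio_thr <- if (low_purity) 0.95 else 0.90
  if (low_purity) {
    notes <- c(notes, sprintf(
      "purity %.2f < 0.3: thresholds relaxed (BAF > %.2f, ratio < %.2f)",
      features$purity, baf_thr, ratio_thr))
  }
  criteria <- c(
    c1_consistent_depth = features$consistency >= 0.9,
    c2_baf_shift = features$adjusted_baf > baf_thr,
    c3_ratio_depleted = features$as_depth_ratio < ratio_thr,
    c4_flank_deletion = features$flank_deletion == 0,
    c5_low_purity_relaxation = low_purity,
    c6_high_ploidy = features$ploidy >= 3
  )
  label <- criteria["c1_consistent_depth"] && criteria["c2_baf_shift"] &&
    criteria["c3_ratio_depleted"]
  if (criteria["c6_high_ploidy"]) {
    label <- label && criteria["c4_flank_deletion"]
    notes <- c(notes,
               "ploidy >= 3: flanking deletion evidence required")
  }
  list(label = if (isTRUE(label)) "LOH" else "no-LOH",
       criteria = criteria, notes = notes, features = features)
}

#' Tabulate a list of locus calls
#' @param calls list of \code{loh_call}.
#' @return data.frame, one row per call.
#' @export
calls_table <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(patient = cl$patient, gene = cl$gene,
               allele1 = cl$alleles[1], allele2 = cl$alleles[2],
               probability = cl$probability, status = cl$status,
               deleted_alleles = paste(cl$deleted_alleles, collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
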