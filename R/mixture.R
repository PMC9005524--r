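#' Binomial thinning of depth values
#'
#' Each depth unit (read) is kept independently with probability \code{p} —
#' the depth-level equivalent of subsampling a fixed fraction of reads.
#'
#' @param depth integer vector (or list of vectors) of depths.
#' @param p retention probability in [0, 1].
#' @return Thinned depths, same shape as the input.
#' @export
thin_depths <- function(depth, p) {
  stopifnot(p >= 0, p <= 1)
  if (is.list(depth)) return(lapply(depth, thin_depths, p = p))
  stats::rbinom(length(depth), as.integer(depth), p)
}

#' Downsample a depth profile to a target mean coverage
#'
#' Per-position binomial thinning with retention probability
#' \code{target_depth / mean(current depth)}; exome read totals are scaled
#' by the same factor. Seeded for reproducibility.
#'
#' @param depths named list of per-allele integer depth vectors (or a
#'   \code{site_depths} table, in which case all four depth columns are
#'   thinned).
#' @param target_depth desired mean coverage; must not exceed the current
#'   mean.
#' @param seed optional seed.
#' @return Object of the same shape with thinned depths; attribute
#'   \code{scale} gives the retention probability applied.
#' @export
downsample_depths <- function(depths, target_depth, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(depths, "site_depths")) {
    cur <- mean(depths$ad_t + depths$bd_t + depths$ad_n + depths$bd_n) / 2
    if (target_depth > cur) {
      stop(sprintf("target depth %.1f exceeds current mean %.1f",
                   target_depth, cur))
    }
    p <- target_depth / cur
    out <- site_depths(depths$coord,
                       thin_depths(depths$ad_t, p), thin_depths(depths$bd_t, p),
                       thin_depths(depths$ad_n, p), thin_depths(depths$bd_n, p))
    attr(out, "scale") <- p
    return(out)
  }
  cur <- mean(unlist(depths))
  if (target_depth > cur) {
    stop(sprintf("target depth %.1f exceeds current mean %.1f",
                 target_depth, cur))
  }
  p <- target_depth / cur
  out <- thin_depths(depths, p)
  attr(out, "scale") <- p
  out
}

#' Mix a pure-tumor locus with normal reads at a given purity and clonality
#'
#' Emulates in-silico cell-line mixing on depth profiles. The HLA tumor slot
#' becomes a binomial thinning of the pure tumor depths at fraction
#' \code{purity * clonality} (the effective LOH-derived read fraction) plus
#' an independent normal replicate thinned at the complementary fraction, so
#' expected sequencing mass is conserved. Exome-level inputs follow the
#' stated purity: the purity feature passed downstream is \code{purity},
#' not the effective fraction, and the segment table is carried over
#' unchanged.
#'
#' @param locus a pure-tumor \code{loh_locus} from [simulate_locus()]
#'   (generated at purity 1, clonality 1).
#' @param purity stated tumor purity of the mixture.
#' @param clonality clonality of the LOH event among tumor cells.
#' @param seed optional seed.
#' @return A new \code{loh_locus} with mixed tumor depths, purity set to the
#'   stated purity, and truth updated to the mixture's purity/clonality.
#' @export
mix_locus <- function(locus, purity, clonality = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(purity >= 0, purity <= 1, clonality >= 0, clonality <= 1)
  q <- purity * clonality
  rep_n <- simulate_normal_replicate(locus)
  s <- locus$sites
  mixed <- site_depths(
    s$coord,
    ad_t = thin_depths(s$ad_t, q) + thin_depths(rep_n$a, 1 - q),
    bd_t = thin_depths(s$bd_t, q) + thin_depths(rep_n$b, 1 - q),
    ad_n = s$ad_n, bd_n = s$bd_n
  )
  out <- locus
  out$sites <- mixed
  out$purity <- max(purity, 0.1)
  out$truth$purity <- purity
  out$truth$clonality <- clonality
  out
}

#' Negative-control locus: normal reads in the tumor slot
#'
#' Fills the tumor columns with an independent normal replicate and
#' overrides the purity feature with an artificially stated value; the truth
#' is no-LOH by construction. Used to measure specificity across stated
#' purity levels.
#'
#' @param locus a no-LOH \code{loh_locus} (its normal columns and generator
#'   parameters are reused).
#' @param stated_purity purity value handed to the feature vector.
#' @param seed optional seed.
#' @return \code{loh_locus} with truth \code{loh = FALSE}.
#' @export
specificity_control <- function(locus, stated_purity, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rep_n <- simulate_normal_replicate(locus)
  out <- locus
  out$sites <- site_depths(locus$sites$coord, ad_t = rep_n$a, bd_t = rep_n$b,
                           ad_n = locus$sites$ad_n, bd_n = locus$sites$bd_n)
  out$purity <- max(stated_purity, 0.1)
  out$truth <- list(loh = FALSE, deleted = NA_integer_,
                    deleted_allele = NA_character_, purity = stated_purity,
                    clonality = NA_real_, flank_deletion = FALSE)
  out$segments$b_copy <- pmax(out$segments$b_copy, 1L)
  out
}

#' Limit-of-detection grid over tumor purity and clonality
#'
#' For every purity x clonality cell, generates fresh pure-tumor loci with
#' planted clonal LOH, mixes them to the cell's effective fraction, calls
#' them with the supplied model, and tallies sensitivity; matched
#' negative-control mixtures (no planted LOH) give per-cell specificity.
#' The model must have been trained on data generated from a different seed.
#'
#' @param model \code{loh_model}.
#' @param purities,clonalities numeric grids.
#' @param replicates mixing replicates per cell (default 10).
#' @param loci_per_rep planted-LOH loci per replicate (default 5).
#' @param neg_per_rep negative-control loci per replicate (default 5).
#' @param params \code{fixture_params} for the base loci.
#' @param seed master seed; every cell and replicate derives its own stream.
#' @return data.frame of class \code{lod_grid}: one row per cell with
#'   \code{purity}, \code{clonality}, \code{sensitivity} (NA when the cell
#'   has no positive truth), \code{specificity}, \code{n_pos}, \code{n_neg};
#'   attribute \code{calls} holds the per-locus call records behind the
#'   tallies.
#' @export
lod_grid <- function(model, purities = seq(0.3, 1, by = 0.1),
                     clonalities = seq(0.3, 1, by = 0.1), replicates = 10L,
                     loci_per_rep = 5L, neg_per_rep = 5L,
                     params = fixture_params(), seed = 1L) {
  cells <- expand.grid(purity = purities, clonality = clonalities)
  res <- vector("list", nrow(cells))
  call_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    p <- cells$purity[i]; cl <- cells$clonality[i]
    set.seed(seed + 7919L * i)
    truth <- logical(0); status <- character(0)
    for (r in seq_len(replicates)) {
      for (l in seq_len(loci_per_rep)) {
        base <- simulate_locus(params, loh = TRUE, purity = 1, clonality = 1)
        mx <- mix_locus(base, p, cl)
        truth <- c(truth, TRUE)
        status <- c(status, call_locus(model, mx)$status)
      }
      for (l in seq_len(neg_per_rep)) {
        base <- simulate_locus(params, loh = FALSE, purity = 1)
        neg <- mix_locus(base, p, cl)
        truth <- c(truth, FALSE)
        status <- c(status, call_locus(model, neg)$status)
      }
    }
    tp <- sum(truth & status == "LOH"); fn <- sum(truth & status != "LOH")
    fp <- sum(!truth & status == "LOH"); tn <- sum(!truth & status != "LOH")
    res[[i]] <- data.frame(
      purity = p, clonality = cl,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      n_pos = tp + fn, n_neg = tn + fp)
    call_rows[[i]] <- data.frame(purity = p, clonality = cl, truth = truth,
                                 status = status)
  }
  out <- do.call(rbind, res)
  class(out) <- c("lod_grid", "data.frame")
  attr(out, "replicates") <- replicates
  attr(out, "seed") <- seed
  attr(out, "calls") <- do.call(rbind, call_rows)
  out
}

#' @export
print.lod_grid <- function(x, ...) {
  cat(sprintf("<lod_grid> %d cells (%d replicates/cell)\n", nrow(x),
              attr(x, "replicates")))
  cat(sprintf("  sensitivity: min %.3f  specificity: min %.3f\n",
              suppressWarnings(min(x$sensitivity, na.rm = TRUE)),
              suppressWarnings(min(x$specificity, na.rm = TRUE))))
  invisible(as.data.frame(x))
}

#' Write an LOD grid as TSV
#' @param grid \code{lod_grid}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_lod_tsv <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
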