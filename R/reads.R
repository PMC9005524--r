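#' Stringent read filtering for allele-specific depth
#'
#' Reads mapped to the patient-specific reference are kept only if they align
#' essentially perfectly: at most 20% of the read's total length soft-clipped
#' (exactly 20% is retained) and no base mismatches. When a somatic mutation
#' has been called in the gene, a single mismatch is tolerated so that reads
#' carrying the mutation still contribute depth.
#'
#' @param reads data.frame with columns \code{allele}, \code{start} (0-based),
#'   \code{aligned_length}, \code{softclip_length}, \code{n_mismatches}.
#' @param somatic_mutation_in_gene logical; lifts the mismatch cap to 1.
#' @param max_softclip_frac maximum soft-clipped fraction of total read
#'   length (default 0.20).
#' @return The retained subset of \code{reads}.
#' @export
filter_reads <- function(reads, somatic_mutation_in_gene = FALSE,
                         max_softclip_frac = 0.20) {
  if (nrow(reads) == 0L) return(reads)
  total <- reads$aligned_length + reads$softclip_length
  max_mm <- if (somatic_mutation_in_gene) 1L else 0L
  keep <- reads$softclip_length <= max_softclip_frac * total &
    reads$n_mismatches <= max_mm
  reads[keep, , drop = FALSE]
}

#' Per-position sequencing depth from filtered reads
#'
#' Counts, at every reference position, the retained reads whose aligned
#' portion covers it; soft-clipped bases contribute nothing.
#'
#' @param reads filtered read data.frame (see [filter_reads()]).
#' @param reference_lengths named integer vector, allele name -> length.
#' @return Named list of integer depth vectors, one per allele in
#'   \code{reference_lengths} (0-based position \code{p} is element
#'   \code{p + 1}).
#' @export
compute_depth <- function(reads, reference_lengths) {
  out <- lapply(reference_lengths, function(L) integer(L))
  for (al in names(reference_lengths)) {
    r <- reads[reads$allele == al, , drop = FALSE]
    L <- reference_lengths[[al]]
    if (nrow(r) == 0L) next
    end <- r$start + r$aligned_length
    if (any(r$start < 0L) || any(end > L)) {
      bad <- which(r$start < 0L | end > L)[1L]
      stop(sprintf("read %d on allele %s spans [%d,%d) outside reference of length %d",
                   bad, al, r$start[bad], end[bad], L))
    }
    # difference-array pileup
    inc <- tabulate(r$start + 1L, nbins = L + 1L)
    dec <- tabulate(end + 1L, nbins = L + 1L)
    out[[al]] <- cumsum(inc - dec)[seq_len(L)]
  }
  out
}

cigar_softclip <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  vapply(ops, function(o) {
    len <- as.integer(sub("[A-Z=]$", "", o))
    sum(len[grepl("S$", o)])
  }, 1L)
}

cigar_aligned_ref_length <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  vapply(ops, function(o) {
    len <- as.integer(sub("[A-Z=]$", "", o))
    sum(len[grepl("[MD=X]$", o)])
  }, 1L)
}

cigar_indel_length <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))
  vapply(ops, function(o) {
    len <- as.integer(sub("[A-Z=]$", "", o))
    sum(len[grepl("[ID]$", o)])
  }, 1L)
}

#' Read alignments from SAM/BAM into read records
#'
#' Extracts, per primary alignment: soft-clip length (CIGAR S operations) and
#' substitution count. Substitutions come from the NM tag minus inserted and
#' deleted bases (NM counts edit distance, whereas the filter targets base
#' mismatches); if NM is absent the MD tag is parsed instead, and an error is
#' raised when neither is present.
#'
#' @param path SAM or BAM file aligned to the patient-specific reference.
#' @return data.frame with columns \code{allele}, \code{start} (0-based),
#'   \code{aligned_length} (reference bases consumed), \code{softclip_length},
#'   \code{n_mismatches}.
#' @export
read_sam_reads <- function(path) {
  is_sam <- grepl("\\.sam$", path, ignore.case = TRUE)
  bam <- if (is_sam) {
    tmp <- tempfile(fileext = ".bam")
    Rsamtools::asBam(path, sub("\\.bam$", "", tmp), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  par <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "cigar"), tag = c("NM", "MD"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE)
  )
  x <- Rsamtools::scanBam(bam, param = par)[[1]]
  n <- length(x$pos)
  if (n == 0L) {
    return(data.frame(allele = character(0), start = integer(0),
                      aligned_length = integer(0), softclip_length = integer(0),
                      n_mismatches = integer(0)))
  }
  nm <- x$tag$NM
  md <- x$tag$MD
  indel <- cigar_indel_length(x$cigar)
  mism <- integer(n)
  for (i in seq_len(n)) {
    if (!is.null(nm) && !is.na(nm[i])) {
      mism[i] <- max(nm[i] - indel[i], 0L)
    } else if (!is.null(md) && !is.na(md[i])) {
      subs <- regmatches(md[i], gregexpr("(?<![\\^A-Z])[A-Z]", md[i], perl = TRUE))[[1]]
      mism[i] <- length(subs)
    } else {
      stop(sprintf("alignment %d has neither NM nor MD tag", i))
    }
  }
  data.frame(allele = as.character(x$rname), start = x$pos - 1L,
             aligned_length = cigar_aligned_ref_length(x$cigar),
             softclip_length = cigar_softclip(x$cigar),
             n_mismatches = mism, stringsAsFactors = FALSE)
}

#' Write per-position depth profiles as TSV
#' @param depths named list of per-allele depth vector pairs:
#'   \code{list(tumor = <list per allele>, normal = <list per allele>)}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_depth_tsv <- function(depths, path) {
  rows <- do.call(rbind, lapply(names(depths$tumor), function(al) {
    data.frame(allele = al, pos = seq_along(depths$tumor[[al]]) - 1L,
               depth_tumor = depths$tumor[[al]],
               depth_normal = depths$normal[[al]])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
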