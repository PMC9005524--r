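#' Build a patient-specific HLA reference
#'
#' Collects the typed alleles of a patient into per-gene allele pairs. A gene
#' typed with the same allele name twice is homozygous by typing and excluded
#' from LOH calling (there is no second allele to lose). Heterozygous pairs
#' may still turn out effectively homozygous once aligned — see
#' [find_mismatch_sites()] — which is flagged separately.
#'
#' @param db imputed \code{allele_db} (every typed allele must be complete).
#' @param typing character vector of up to six class-I allele names, e.g.
#'   \code{c("A*01:01","A*02:01","B*07:02","B*07:02","C*04:01","C*07:01")}.
#' @return A \code{patient_reference}: named list (by gene) of
#'   \code{list(allele1, allele2, homozygous_by_typing)}, where the allele
#'   entries are records carrying assembled \code{sequence} strings.
#' @export
build_patient_reference <- function(db, typing) {
  unknown <- setdiff(typing, names(db$records))
  if (length(unknown) > 0L) {
    hints <- vapply(unknown, function(u) {
      near <- agrep(u, names(db$records), max.distance = 2, value = TRUE)
      if (length(near) == 0L) "no similar names" else
        paste(utils::head(near, 3L), collapse = ", ")
    }, "")
    stop("unknown allele(s): ",
         paste(sprintf("%s (nearest: %s)", unknown, hints), collapse = "; "))
  }
  info <- parse_allele_name(typing)
  loci <- list()
  for (g in unique(info$gene)) {
    al <- typing[info$gene == g]
    if (length(al) == 1L) al <- c(al, al)
    if (length(al) > 2L) {
      stop(sprintf("gene %s typed with %d alleles; at most 2 allowed",
                   g, length(al)))
    }
    mk <- function(nm) {
      rec <- db$records[[nm]]
      rec$sequence <- allele_sequence(rec)
      rec
    }
    loci[[g]] <- list(allele1 = mk(al[1L]), allele2 = mk(al[2L]),
                      homozygous_by_typing = al[1L] == al[2L])
  }
  structure(loci, class = "patient_reference")
}

#' @export
print.patient_reference <- function(x, ...) {
  cat("<patient_reference>\n")
  for (g in names(x)) {
    cat(sprintf("  HLA-%s: %s / %s%s\n", g, x[[g]]$allele1$name,
                x[[g]]$allele2$name,
                if (x[[g]]$homozygous_by_typing) "  [homozygous by typing]" else ""))
  }
  invisible(x)
}

#' Write a patient reference as FASTA
#'
#' One entry per distinct allele; sequence names are the allele names.
#'
#' @param ref \code{patient_reference}.
#' @param path output FASTA path.
#' @return Invisibly, the path.
#' @export
write_reference_fasta <- function(ref, path) {
  seqs <- list()
  for (g in names(ref)) {
    for (a in c("allele1", "allele2")) {
      rec <- ref[[g]][[a]]
      seqs[[rec$name]] <- rec$sequence
    }
  }
  x <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Locate positions of difference between two homologous alleles
#'
#' Globally aligns the two allele sequences (affine gap penalties: match +1,
#' mismatch -1, gap open -5, gap extend -1, so indels stay contiguous) and
#' records every substitution column as an SNV site. Each gap run contributes
#' exactly one site at its first position so that a long indel carries the
#' same weight as a single SNV. Coordinates are 0-based positions on allele 1;
#' a gap in allele 1 (insertion in allele 2) is anchored at the preceding
#' allele-1 base (0 at the start). Allele pairs separated by fewer than
#' \code{min_sites} sites are flagged effectively homozygous: with so few
#' informative positions, allele-specific depth cannot be measured reliably.
#'
#' @param seq1,seq2 nucleotide strings (allele 1 and allele 2).
#' @param min_sites minimum number of difference sites for the pair to count
#'   as heterozygous (default 5).
#' @return A \code{mismatch_map}: data.frame with columns \code{coord}
#'   (0-based, allele-1 frame), \code{coord2} (allele-2 frame), \code{kind}
#'   ("SNV" or "indel"), \code{base1}, \code{base2}; attributes
#'   \code{n_sites} and \code{effectively_homozygous}.
#' @export
find_mismatch_sites <- function(seq1, seq2, min_sites = 5L) {
  stopifnot(nchar(seq1) > 0L, nchar(seq2) > 0L)
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq1), Biostrings::DNAString(seq2),
    type = "global", substitutionMatrix = sub_mat,
    gapOpening = 5, gapExtension = 1
  )
  a1 <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  a2 <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # 0-based coordinate of each column; gap columns inherit the preceding base
  pos1 <- pmax(cumsum(a1 != "-") - 1L, 0L)
  pos2 <- pmax(cumsum(a2 != "-") - 1L, 0L)

  snv <- a1 != "-" & a2 != "-" & a1 != a2
  gap <- a1 == "-" | a2 == "-"
  runs <- rle(gap)
  run_start <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
  indel_first <- run_start[runs$values]

  coord <- c(pos1[snv], pos1[indel_first])
  coord2 <- c(pos2[snv], pos2[indel_first])
  kind <- c(rep("SNV", sum(snv)), rep("indel", length(indel_first)))
  base1 <- c(a1[snv], a1[indel_first])
  base2 <- c(a2[snv], a2[indel_first])
  o <- order(coord, kind)
  sites <- data.frame(coord = coord[o], coord2 = coord2[o], kind = kind[o],
                      base1 = base1[o], base2 = base2[o],
                      stringsAsFactors = FALSE)
  structure(sites,
            n_sites = nrow(sites),
            effectively_homozygous = nrow(sites) < min_sites,
            class = c("mismatch_map", "data.frame"))
}

#' Write mismatch sites as a BED-like TSV
#'
#' 0-based, half-open intervals of width 1 on the allele-1 reference.
#'
#' @param map \code{mismatch_map}.
#' @param allele name used in the first column.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
write_mismatch_bed <- function(map, allele, path) {
  df <- data.frame(chrom = allele, start = map$coord, end = map$coord + 1L,
                   kind = map$kind, base1 = map$base1, base2 = map$base2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
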