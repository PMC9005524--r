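#' Parse an HLA allele name
#'
#' Allele names follow class-I nomenclature, e.g. \code{"A*01:01"} or
#' \code{"B*07:02:01"}: a gene letter (A, B or C), then colon-separated
#' numeric fields. The first field is the 2-digit allele group, the first two
#' fields together form the 4-digit protein-level name, and an optional third
#' field gives the synonymous (6-digit) designation.
#'
#' @param x character vector of allele names.
#' @return A data.frame with columns \code{name}, \code{gene},
#'   \code{group} (2-digit name), \code{protein} (4-digit name) and
#'   \code{n_fields}.
#' @examples
#' parse_allele_name(c("A*01:01", "B*07:02:01"))
#' @export
parse_allele_name <- function(x) {
  m <- regmatches(x, regexec("^([ABC])\\*([0-9]+(?::[0-9]+)*)$", x))
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed allele name(s): ", paste(x[bad], collapse = ", "))
  }
  gene <- vapply(m, `[`, "", 2L)
  fields <- strsplit(vapply(m, `[`, "", 3L), ":", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  group <- paste0(gene, "*", vapply(fields, `[`, "", 1L))
  protein <- ifelse(
    nf >= 2L,
    paste0(group, ":", vapply(fields, function(f) if (length(f) >= 2L) f[2L] else NA_character_, "")),
    NA_character_
  )
  data.frame(name = x, gene = gene, group = group, protein = protein,
             n_fields = nf, stringsAsFactors = FALSE)
}

#' Gene letter of HLA allele names
#' @param x character vector of allele names.
#' @return Character vector of gene letters ("A", "B" or "C").
#' @export
allele_gene <- function(x) parse_allele_name(x)$gene

msa_symbols <- c(match = "-", gap = ".", unknown = "*")

#' Parse an allele multiple-sequence-alignment file
#'
#' Reads the package's simplified row-per-allele MSA dialect (modelled on the
#' IMGT/HLA alignment releases). The file contains comment/header lines
#' starting with \code{#}, one of which must declare the segment layout, e.g.
#' \preformatted{# segments: exon1:270 intron1:120 exon2:276}
#' followed by one row per allele: the allele name, whitespace, and a symbol
#' string. The first allele row is the reference and carries the actual
#' nucleotide sequence; subsequent rows use \code{-} for a match to the
#' reference, a base letter for a substitution, \code{.} for a deletion
#' relative to the reference and \code{*} for unsequenced positions. All rows
#' have the reference's length; insertions relative to the MSA reference are
#' not representable in this dialect.
#'
#' A segment (exon or intron) containing any \code{*} is recorded as missing
#' for that allele, mirroring incompletely sequenced database entries.
#'
#' @param path path to an MSA file, or a character vector of its lines via
#'   \code{text}.
#' @param text optional character vector of lines (overrides \code{path}).
#' @param kind "cDNA" (exons only) or "gDNA" (exons and introns); checked
#'   against the segment names in the header.
#' @return An \code{allele_db} object: list with \code{records} (named list;
#'   each record has \code{name}, \code{segments} — named list of nucleotide
#'   strings or \code{NA} when missing — \code{segment_names} and
#'   \code{imputed}, a named character vector of donor alleles filled in by
#'   [impute_database()]), \code{msa_order} (allele names in file order) and
#'   \code{kind}.
#' @seealso [impute_database()], [build_patient_reference()]
#' @export
parse_msa <- function(path = NULL, text = NULL, kind = c("gDNA", "cDNA")) {
  kind <- match.arg(kind)
  lines <- if (!is.null(text)) text else readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- grep("^#", lines, value = TRUE)
  rows <- grep("^#", lines, value = TRUE, invert = TRUE)
  seg_line <- grep("^#\\s*segments:", header, value = TRUE)
  if (length(seg_line) != 1L) {
    stop("MSA header must contain exactly one '# segments:' line")
  }
  seg_spec <- strsplit(trimws(sub("^#\\s*segments:", "", seg_line)), "\\s+")[[1]]
  seg_parts <- strsplit(seg_spec, ":", fixed = TRUE)
  seg_names <- vapply(seg_parts, `[`, "", 1L)
  seg_len <- as.integer(vapply(seg_parts, `[`, "", 2L))
  if (anyNA(seg_len)) stop("malformed segment spec in MSA header")
  if (kind == "cDNA" && any(grepl("^intron", seg_names))) {
    stop("cDNA MSA may not contain intron segments")
  }
  if (length(rows) == 0L) stop("empty allele database")

  tok <- strsplit(trimws(rows), "\\s+")
  names_ <- vapply(tok, `[`, "", 1L)
  seqs <- vapply(tok, `[`, "", 2L)
  parse_allele_name(names_)  # validates
  ref_len <- sum(seg_len)
  ref <- toupper(seqs[[1L]])
  if (nchar(ref) != ref_len) {
    stop(sprintf("reference row '%s' length %d does not match segment total %d",
                 names_[1L], nchar(ref), ref_len))
  }
  if (grepl("[^ACGT]", ref)) {
    stop(sprintf("reference row '%s' must be plain sequence", names_[1L]))
  }
  ref_chars <- strsplit(ref, "")[[1]]
  seg_id <- rep(seq_along(seg_names), seg_len)

  records <- vector("list", length(names_))
  for (i in seq_along(names_)) {
    s <- toupper(seqs[[i]])
    if (nchar(s) != ref_len) {
      stop(sprintf("allele '%s' (row %d): row length %d does not match reference length %d",
                   names_[i], i, nchar(s), ref_len))
    }
    ch <- strsplit(s, "")[[1]]
    if (i > 1L) {
      if (any(!ch %in% c("-", ".", "*", "A", "C", "G", "T"))) {
        stop(sprintf("allele '%s': unexpected symbol in row", names_[i]))
      }
      out <- ifelse(ch == "-", ref_chars, ch)
    } else {
      out <- ch
    }
    segs <- vector("list", length(seg_names))
    names(segs) <- seg_names
    for (k in seq_along(seg_names)) {
      piece <- out[seg_id == k]
      if (any(piece == "*")) {
        segs[[k]] <- NA_character_
      } else {
        segs[[k]] <- paste(piece[piece != "."], collapse = "")
      }
    }
    records[[i]] <- list(name = names_[i], segments = segs,
                         segment_names = seg_names,
                         imputed = character(0))
  }
  names(records) <- names_
  structure(list(records = records, msa_order = names_, kind = kind),
            class = "allele_db")
}

#' @export
print.allele_db <- function(x, ...) {
  n_missing <- sum(vapply(x$records, function(r)
    any(vapply(r$segments, function(s) is.na(s[1L]), TRUE)), 0L))
  cat(sprintf("<allele_db> %s: %d alleles, %d segments per allele, %d with missing segments\n",
              x$kind, length(x$records),
              length(x$records[[1L]]$segment_names), n_missing))
  invisible(x)
}

# Donor cascade: same 4-digit (protein) name, then same 2-digit group, then
# any allele, always scanning in MSA file order and skipping the allele itself.
find_donor <- function(db, name, segment) {
  info_all <- parse_allele_name(db$msa_order)
  has_seg <- vapply(db$msa_order, function(nm) {
    seg <- db$records[[nm]]$segments[[segment]]
    !is.null(seg) && !is.na(seg[1L])
  }, TRUE)
  if (name %in% db$msa_order) {
    info <- info_all[match(name, db$msa_order), ]
  } else {
    info <- parse_allele_name(name)
  }
  tiers <- list(
    !is.na(info$protein) & !is.na(info_all$protein) & info_all$protein == info$protein,
    info_all$group == info$group,
    rep(TRUE, nrow(info_all))
  )
  for (tier in tiers) {
    cand <- db$msa_order[tier & has_seg & db$msa_order != name]
    if (length(cand) > 0L) return(cand[[1L]])
  }
  NULL
}

#' Impute missing exons and introns across an allele database
#'
#' Most database alleles are only partially sequenced: many have cDNA (exon)
#' sequence but no introns, or lack individual segments entirely. Missing
#' exons are filled from the cDNA alignment and missing introns from the gDNA
#' alignment, taking each segment from a donor allele chosen by protein-level
#' identity: first an allele with the identical 4-digit name, then one from
#' the same 2-digit allele group, and finally the first allele listed in the
#' MSA; within a tier the earliest allele in MSA order that actually carries
#' the segment wins. Full-length genomic sequences are then assembled by
#' interleaving the (possibly imputed) exons with the (possibly imputed)
#' introns in genomic order.
#'
#' @param cdna_db \code{allele_db} parsed from the cDNA alignment (exons).
#' @param gdna_db \code{allele_db} parsed from the gDNA alignment
#'   (exons and introns interleaved).
#' @return A complete \code{allele_db} with the gDNA segment layout covering
#'   the union of alleles in the two inputs; every segment present, and each
#'   record's \code{imputed} naming the donor for each filled segment.
#' @export
impute_database <- function(cdna_db, gdna_db) {
  if (length(cdna_db$records) == 0L || length(gdna_db$records) == 0L) {
    stop("empty allele database")
  }
  layout <- gdna_db$records[[1L]]$segment_names
  exon_names <- grep("^exon", layout, value = TRUE)
  intron_names <- setdiff(layout, exon_names)
  if (!identical(sort(exon_names),
                 sort(cdna_db$records[[1L]]$segment_names))) {
    stop("cDNA segment layout does not match the gDNA exon layout")
  }
  all_names <- union(gdna_db$msa_order, cdna_db$msa_order)

  take <- function(db, name, segment) {
    rec <- db$records[[name]]
    if (!is.null(rec)) {
      seg <- rec$segments[[segment]]
      if (!is.null(seg) && !is.na(seg[1L])) {
        return(list(seq = seg, donor = NA_character_))
      }
    }
    donor <- find_donor(db, name, segment)
    if (is.null(donor)) {
      stop(sprintf("no donor found for %s segment %s", name, segment))
    }
    list(seq = db$records[[donor]]$segments[[segment]], donor = donor)
  }

  records <- vector("list", length(all_names))
  names(records) <- all_names
  for (nm in all_names) {
    segs <- vector("list", length(layout))
    names(segs) <- layout
    imputed <- character(0)
    for (sg in exon_names) {
      got <- take(cdna_db, nm, sg)
      segs[[sg]] <- got$seq
      if (!is.na(got$donor)) imputed[sg] <- got$donor
    }
    for (sg in intron_names) {
      got <- take(gdna_db, nm, sg)
      segs[[sg]] <- got$seq
      if (!is.na(got$donor)) imputed[sg] <- got$donor
    }
    records[[nm]] <- list(name = nm, segments = segs, segment_names = layout,
                          imputed = imputed)
  }
  order_ <- c(gdna_db$msa_order, setdiff(cdna_db$msa_order, gdna_db$msa_order))
  structure(list(records = records, msa_order = order_, kind = "genomic"),
            class = "allele_db")
}

#' Assembled full-length sequence of an allele record
#' @param record an allele record from an \code{allele_db}.
#' @return Single nucleotide string (segments concatenated in genomic order).
#' @export
allele_sequence <- function(record) {
  segs <- unlist(record$segments[record$segment_names])
  if (anyNA(segs)) {
    stop(sprintf("allele %s still has missing segments; run impute_database()",
                 record$name))
  }
  paste(segs, collapse = "")
}
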