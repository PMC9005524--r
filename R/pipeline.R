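pkg_version <- function() {
  as.character(utils::packageVersion("hlaloh"))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(config, seed) {
  c(sprintf("# hlaloh %s", pkg_version()),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %s", seed))
}

write_table_with_header <- function(df, path, config, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' @param path YAML file. Recognised keys mirror the arguments of
#'   [loh_pipeline()] (input paths, \code{r_t}, \code{r_n}, \code{purity},
#'   \code{ploidy}, \code{somatic_genes}, thresholds for [loh_config()],
#'   \code{seed}, \code{out_dir}).
#' @return Named list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Call HLA LOH end to end for one patient
#'
#' Orchestrates the full calling path: parse and impute the allele database,
#' assemble the patient-specific reference, locate mismatch sites between
#' each gene's homologous alleles, filter reads and compute allele-specific
#' depth, derive the seven features and call each heterozygous locus with
#' the supplied model. Genes homozygous by typing, or whose alleles differ
#' at fewer than five positions, are reported as excluded.
#'
#' @param model fitted \code{loh_model}.
#' @param cdna_msa,gdna_msa allele database MSA file paths.
#' @param typing character vector of typed allele names (up to six).
#' @param tumor_reads,normal_reads read records: either data.frames (see
#'   [filter_reads()]) or SAM/BAM paths.
#' @param r_t,r_n exome-wide read totals for tumor and normal.
#' @param purity,ploidy tumor purity and ploidy estimates.
#' @param segments optional segment table (data.frame or path readable by
#'   [read_segments()]).
#' @param gene_intervals named list of gene intervals (defaults to
#'   [default_gene_intervals()]).
#' @param somatic_genes genes with somatic HLA mutations (read filter allows
#'   one mismatch there).
#' @param patient patient identifier.
#' @param out_dir optional directory; when given, calls TSV and JSON are
#'   written there with a header embedding the package version, config hash
#'   and seed.
#' @param seed seed recorded in outputs.
#' @return list with \code{calls} (data.frame: one row per gene, including
#'   excluded loci), \code{loci} (the \code{loh_locus} objects of called
#'   genes) and \code{reference} (the \code{patient_reference}).
#' @export
loh_pipeline <- function(model, cdna_msa, gdna_msa, typing, tumor_reads,
                         normal_reads, r_t, r_n, purity, ploidy,
                         segments = NULL,
                         gene_intervals = default_gene_intervals(),
                         somatic_genes = character(0), patient = "patient",
                         out_dir = NULL, seed = 1L) {
  config <- list(typing = typing, r_t = r_t, r_n = r_n, purity = purity,
                 ploidy = ploidy, somatic_genes = somatic_genes,
                 seed = seed, model_config = unclass(model$config))
  cdna <- parse_msa(cdna_msa, kind = "cDNA")
  gdna <- parse_msa(gdna_msa, kind = "gDNA")
  db <- impute_database(cdna, gdna)
  ref <- build_patient_reference(db, typing)
  if (is.character(tumor_reads)) tumor_reads <- read_sam_reads(tumor_reads)
  if (is.character(normal_reads)) normal_reads <- read_sam_reads(normal_reads)
  if (is.character(segments)) segments <- read_segments(segments)

  rows <- list(); loci <- list(); calls <- list()
  for (g in names(ref)) {
    pair <- ref[[g]]
    alleles <- c(pair$allele1$name, pair$allele2$name)
    if (pair$homozygous_by_typing) {
      rows[[g]] <- data.frame(patient = patient, gene = g,
                              allele1 = alleles[1], allele2 = alleles[2],
                              probability = NA_real_,
                              status = "excluded: homozygous by typing",
                              deleted_alleles = "")
      next
    }
    map <- find_mismatch_sites(pair$allele1$sequence, pair$allele2$sequence)
    if (attr(map, "effectively_homozygous")) {
      rows[[g]] <- data.frame(patient = patient, gene = g,
                              allele1 = alleles[1], allele2 = alleles[2],
                              probability = NA_real_,
                              status = "excluded: effectively homozygous",
                              deleted_alleles = "")
      next
    }
    somatic <- g %in% somatic_genes
    lens <- stats::setNames(c(nchar(pair$allele1$sequence),
                              nchar(pair$allele2$sequence)), alleles)
    dep_t <- compute_depth(filter_reads(tumor_reads, somatic), lens)
    dep_n <- compute_depth(filter_reads(normal_reads, somatic), lens)
    sites <- site_depths(map$coord,
                         ad_t = dep_t[[alleles[1]]][map$coord + 1L],
                         bd_t = dep_t[[alleles[2]]][map$coord2 + 1L],
                         ad_n = dep_n[[alleles[1]]][map$coord + 1L],
                         bd_n = dep_n[[alleles[2]]][map$coord2 + 1L])
    locus <- loh_locus(gene = g, alleles = alleles, sites = sites,
                       ref_len = lens[[1L]], r_t = r_t, r_n = r_n,
                       purity = purity, ploidy = ploidy,
                       segments = segments,
                       gene_interval = gene_intervals[[g]],
                       patient = patient)
    cl <- call_locus(model, locus)
    loci[[g]] <- locus
    calls[[g]] <- cl
    rows[[g]] <- calls_table(list(cl))
  }
  calls_df <- do.call(rbind, rows)
  rownames(calls_df) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_with_header(calls_df, file.path(out_dir, "calls.tsv"),
                            config, seed)
    json <- list(version = pkg_version(), config_hash = config_hash(config),
                 seed = seed, calls = calls_df)
    jsonlite::write_json(json, file.path(out_dir, "calls.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(calls = calls_df, loci = loci, reference = ref)
}
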