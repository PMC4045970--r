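## Text exports and imports around the pipeline: truth tables for
## simulations, CP-software genotype files, per-site pileup summaries and
## concordance tables.

#' Write simulation truth tables
#'
#' One row per parental heterozygous site: scaffold, 0-based position,
#' truth cM (linear in physical position at the simulated genetic
#' density), and the per-progeny truth genotype (1 = variant haplotype
#' inherited).
#'
#' @param parents a `parent_pair`.
#' @param progeny a `progeny_set`.
#' @param path output TSV path.
#' @param parent which parent's sites to write.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(parents, progeny, path,
                              parent = c("paternal", "maternal")) {
  parent <- match.arg(parent)
  sel <- parents$variants$parent == parent
  v <- parents$variants[sel]
  tg <- truth_genotypes(progeny, parents, parent)
  out <- data.table(site = rownames(tg), scaffold = v$scaffold, pos = v$pos,
                    truth_cm = v$pos / 1e6 * progeny$cm_per_mb,
                    origin = v$origin)
  out <- cbind(out, as.data.table(tg) + 0L)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CP-format genotype (loc) file
#'
#' Text export in the dialect of CP mapping software: a header with the
#' population name, type `CP`, locus and individual counts, then one block
#' per marker with its segregation type and space-separated CP codes.
#'
#' @param geno a [cp_geno].
#' @param path output path.
#' @param name population name for the header.
#' @return `path`, invisibly.
#' @export
write_loc_file <- function(geno, path, name = "radmap_pop") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("name = %s", name), "popt = CP",
               sprintf("nloc = %d", nrow(geno$calls)),
               sprintf("nind = %d", ncol(geno$calls)), ""), con)
  for (i in seq_len(nrow(geno$calls))) {
    writeLines(sprintf("%s <%s>", rownames(geno$calls)[i],
                       geno$info$seg_type[i]), con)
    writeLines(paste(geno$calls[i, ], collapse = " "), con)
  }
  invisible(path)
}

#' Read per-site pileup summaries
#'
#' Input for the heterozygosity scan: either the native TSV (columns
#' `scaffold`, `pos`, `depth`, `allele_a`, `count_a`, `allele_b`,
#' `count_b`; 0-based positions) or a VCF with per-sample allele depths
#' (`AD` format field), from which depth and the two top allele counts of
#' the first sample are taken.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @return data.table with `scaffold`, `pos`, `depth`, `count_a`,
#'   `count_b`, ready for [call_het_sites()].
#' @export
read_site_summaries <- function(path, format = NULL) {
  format <- format %||% if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    dt <- as.data.table(utils::read.delim(path))
    need <- c("scaffold", "pos", "depth", "count_a", "count_b")
    if (!all(need %in% names(dt)))
      stop_radmap("site summary TSV must have columns: %s",
                  paste(need, collapse = ", "))
    return(dt[, c("scaffold", "pos", "depth", "count_a", "count_b"),
              with = FALSE])
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop_radmap("reading VCF site summaries requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")[, 1]
  counts <- lapply(strsplit(ad, ","), function(x) {
    k <- sort(as.integer(x), decreasing = TRUE)
    c(k[1], if (length(k) > 1) k[2] else 0L)
  })
  m <- do.call(rbind, counts)
  data.table(scaffold = as.character(v@fix[, "CHROM"]),
             pos = as.integer(v@fix[, "POS"]) - 1L,  # VCF is 1-based
             depth = m[, 1] + m[, 2],
             count_a = m[, 1], count_b = m[, 2])
}

#' Write concordance tables
#'
#' Emits the count matrix and the row-normalized fraction matrix as TSVs.
#'
#' @param concordance a `concordance` object.
#' @param counts_path,fractions_path output TSV paths.
#' @return Invisibly, the two paths.
#' @export
write_concordance <- function(concordance, counts_path, fractions_path) {
  wr <- function(m, p)
    utils::write.table(data.frame(scaffold = rownames(m), m,
                                  check.names = FALSE),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
  wr(concordance$counts, counts_path)
  wr(heatmap_fractions(concordance), fractions_path)
  invisible(c(counts_path, fractions_path))
}
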