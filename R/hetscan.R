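## Within-genome heterozygosity: depth-filtered heterozygous-site calls
## from per-site pileup summaries, sliding-window densities, and
## per-scaffold summaries.

#' Call heterozygous sites from per-site summaries
#'
#' A biallelic site is called heterozygous when its depth lies inside the
#' `[min_depth, max_depth]` window (guarding against low coverage and
#' collapsed repeats respectively) and the minor allele reaches
#' `min_minor_frac` of the reads.
#'
#' @param sites data.frame/data.table with columns `scaffold`, `pos`
#'   (0-based), `depth`, `count_a`, `count_b` (reads per allele).
#' @param min_depth,max_depth depth window (defaults 10 and 120).
#' @param min_minor_frac minor-allele fraction threshold (default 0.2).
#' @return data.table of heterozygous sites (subset of input rows).
#' @export
call_het_sites <- function(sites, min_depth = 10, max_depth = 120,
                           min_minor_frac = 0.2) {
  sites <- as.data.table(sites)
  minor <- pmin(sites$count_a, sites$count_b)
  keep <- sites$depth >= min_depth & sites$depth <= max_depth &
    minor / sites$depth >= min_minor_frac
  sites[keep]
}

#' Sliding-window variant density
#'
#' Windows start at 0 with the given step; the final window is truncated at
#' the scaffold end and its true length is used in the density denominator.
#' Scaffolds shorter than the step yield a single full-scaffold window.
#'
#' @param het_sites data.table with `scaffold`, `pos` columns.
#' @param scaffold_lengths named numeric vector of scaffold lengths.
#' @param window window length in bp (default 500000).
#' @param step step in bp (default 250000).
#' @return data.table `scaffold`, `window_start`, `window_end`,
#'   `variant_count`, `density` (variants per kb).
#' @export
window_scan <- function(het_sites, scaffold_lengths, window = 500000,
                        step = 250000) {
  het_sites <- as.data.table(het_sites)
  out <- lapply(names(scaffold_lengths), function(sc) {
    len <- scaffold_lengths[[sc]]
    starts <- if (len <= step) 0 else seq(0, len - 1, by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + window, len)
    pos <- het_sites[scaffold == sc]$pos
    cnt <- vapply(seq_along(starts), function(i)
      sum(pos >= starts[i] & pos < ends[i]), numeric(1))
    data.table(scaffold = sc, window_start = starts, window_end = ends,
               variant_count = cnt, density = cnt / ((ends - starts) / 1000))
  })
  rbindlist(out)
}

#' Unweighted average of per-scaffold densities
#'
#' @param densities numeric vector of per-scaffold variants/kb.
#' @param digits rounding applied to the mean (default 2, matching how such
#'   summaries are conventionally tabulated).
#' @return The unweighted mean density.
#' @export
average_heterozygosity <- function(densities, digits = 2) {
  round(mean(densities), digits)
}

#' Per-scaffold and genome-average heterozygosity
#'
#' Per-scaffold density is variants per kb of scaffold length; the genome
#' summary line is by default the unweighted mean over scaffolds (a
#' length-weighted alternative is available).
#'
#' @param het_sites data.table with `scaffold`, `pos`.
#' @param scaffold_lengths named numeric vector; zero-length scaffolds are
#'   excluded with a warning.
#' @param weighted use length-weighted averaging (default `FALSE`).
#' @return List with `per_scaffold` (data.table `scaffold`, `length_bp`,
#'   `variant_count`, `density`) and `average` (variants/kb, 2 decimals).
#' @export
genome_summary <- function(het_sites, scaffold_lengths, weighted = FALSE) {
  het_sites <- as.data.table(het_sites)
  if (any(scaffold_lengths == 0)) {
    warning("zero-length scaffolds excluded from heterozygosity summary")
    scaffold_lengths <- scaffold_lengths[scaffold_lengths > 0]
  }
  per <- data.table(scaffold = names(scaffold_lengths),
                    length_bp = as.numeric(scaffold_lengths))
  cnt <- het_sites[, .(variant_count = .N), by = scaffold]
  per <- merge(per, cnt, by = "scaffold", all.x = TRUE, sort = FALSE)
  per[is.na(variant_count), variant_count := 0]
  per[, density := variant_count / (length_bp / 1000)]
  avg <- if (weighted) {
    round(sum(per$variant_count) / (sum(per$length_bp) / 1000), 2)
  } else {
    average_heterozygosity(per$density)
  }
  list(per_scaffold = per, average = avg)
}
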