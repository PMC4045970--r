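## Reference indexing and tag alignment: unmasked scaffolds, repeat-masked
## scaffolds (repeat bases as N, never indexed) or gene models (only bases
## inside gene intervals are searchable), with coordinate lift-over back
## to assembly scaffolds.

#' Build a searchable reference index
#'
#' @param genome an `annotated_genome` (or a named character vector of
#'   scaffold sequences, in which case only `"unmasked"` mode is possible).
#' @param mode `"unmasked"`, `"masked"` (repeat intervals replaced by `N`)
#'   or `"genemodels"` (only gene-interval subsequences are indexed).
#' @param seed_len exact-seed length for the seed-and-verify search
#'   (default 23; four non-overlapping 23-mers tile a 92 bp tag, so any
#'   alignment with at most three edit events retains an intact seed).
#' @return Object of class `ref_index`: list with the index handle,
#'   `mode`, `liftover` (data.table `seq_idx`, `scaffold`, `offset`) and
#'   `indexed_bases` (count of searchable, non-`N` bases).
#' @export
build_reference_index <- function(genome, mode = c("unmasked", "masked",
                                                   "genemodels"),
                                  seed_len = 23) {
  mode <- match.arg(mode)
  if (is.character(genome))
    genome <- structure(list(seqs = genome,
                             lengths = nchar(genome),
                             repeats = data.table(scaffold = character(),
                                                  start = numeric(), end = numeric()),
                             genes = data.table(scaffold = character(),
                                                start = numeric(), end = numeric())),
                        class = "annotated_genome")
  if (mode == "unmasked") {
    seqs <- genome$seqs
    lift <- data.table(seq_idx = seq_along(seqs), scaffold = names(seqs),
                       offset = 0)
  } else if (mode == "masked") {
    seqs <- mask_sequences(genome)
    lift <- data.table(seq_idx = seq_along(seqs), scaffold = names(seqs),
                       offset = 0)
  } else {
    if (nrow(genome$genes) == 0)
      stop_radmap("genemodels mode requires a non-empty gene interval set")
    g <- as.data.table(genome$genes)
    seqs <- substring(genome$seqs[g$scaffold], g$start + 1, g$end)
    names(seqs) <- sprintf("gene%05d", seq_len(nrow(g)))
    lift <- data.table(seq_idx = seq_len(nrow(g)), scaffold = g$scaffold,
                       offset = g$start)
  }
  handle <- radmap_build_index(unname(seqs), k = seed_len)
  indexed <- sum(nchar(seqs)) - sum(vapply(
    gregexpr("N", seqs, fixed = TRUE),
    function(m) sum(m > 0), numeric(1)))
  structure(list(handle = handle, mode = mode, seqs = seqs, liftover = lift,
                 indexed_bases = indexed, seed_len = seed_len),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf("<ref_index> mode=%s, %d sequences, %.0f searchable bases\n",
              x$mode, length(x$seqs), x$indexed_bases))
  invisible(x)
}

#' Align tags to a reference index
#'
#' Seed-and-verify alignment under the marker-definition budget: at most
#' `max_mm` mismatches and `max_indel` indel bases (alignment score =
#' mismatches + 2 x indel bases). Both strands are searched. A tag is
#' `unique` only when a single locus attains the strictly best score,
#' `ambiguous` when the best score is tied across loci, `unaligned` when
#' no locus fits the budget.
#'
#' @param index a `ref_index`.
#' @param tags character vector of tag sequences (all of length
#'   `tag_len`; others are rejected).
#' @param sample_ids optional character vector parallel to `tags`.
#' @param max_mm,max_indel alignment budget (defaults 2 and 2).
#' @param tag_len required tag length (default 92).
#' @return data.table with one row per tag: `tag_idx`, `sample_id` (if
#'   given), `scaffold`, `pos` (0-based, forward strand of the assembly
#'   scaffold), `strand`, `mm`, `indel`, `n_hits`, `status`.
#' @export
align_tags <- function(index, tags, sample_ids = NULL, max_mm = 2,
                       max_indel = 2, tag_len = 92) {
  if (any(nchar(tags) != tag_len))
    stop_radmap("all tags must be exactly %d bases", tag_len)
  res <- as.data.table(radmap_align_tags(index$handle, tags, max_mm, max_indel))
  res[, tag_idx := .I]
  if (!is.null(sample_ids)) res[, sample_id := sample_ids]
  res <- merge(res, index$liftover, by = "seq_idx", all.x = TRUE, sort = FALSE)
  res[, pos := pos + fifelse(is.na(offset), 0, offset)]
  res[, offset := NULL]
  setorder(res, tag_idx)
  res[]
}

#' Pool unique alignments into per-locus clusters
#'
#' One cluster per (scaffold, position, strand); only uniquely aligned
#' tags enter. The depth window is applied to the pooled parental panel
#' (the discovery panel): clusters whose parental read count falls outside
#' `[min_depth, max_depth]` are dropped, guarding against undersampled
#' loci and collapsed repeats respectively.
#'
#' @param alignments table from [align_tags()] including `sample_id` and
#'   the aligned tag sequences in a `tag` column (attach before calling),
#'   one row per read.
#' @param parent_samples character vector of parental sample ids.
#' @param min_depth,max_depth parental-panel depth window (defaults 4 and
#'   200).
#' @return List with `clusters` (data.table `locus_id`, `scaffold`, `pos`,
#'   `strand`, `sample_id`, `tag`, `n`), `n_dropped_low`,
#'   `n_dropped_high`.
#' @export
build_clusters <- function(alignments, parent_samples, min_depth = 4,
                           max_depth = 200) {
  aln <- as.data.table(alignments)[status == "unique"]
  if (nrow(aln) == 0)
    return(list(clusters = data.table(), n_dropped_low = 0L, n_dropped_high = 0L))
  aln[, locus_id := sprintf("%s:%d:%s", scaffold, pos, strand)]
  clusters <- aln[, .(n = .N), by = .(locus_id, scaffold, pos, strand,
                                      sample_id, tag)]
  pdepth <- clusters[sample_id %in% parent_samples,
                     .(pd = sum(n)), by = locus_id]
  ok <- pdepth[pd >= min_depth & pd <= max_depth]$locus_id
  low <- sum(pdepth$pd < min_depth) +
    length(setdiff(unique(clusters$locus_id), pdepth$locus_id))
  high <- sum(pdepth$pd > max_depth)
  list(clusters = clusters[locus_id %in% ok],
       n_dropped_low = as.integer(low), n_dropped_high = as.integer(high))
}
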