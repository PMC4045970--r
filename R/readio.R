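## Read processing: barcode demultiplexing, trimming to the fixed tag
## length, and the low-quality read filter.

#' Demultiplex barcoded reads
#'
#' Assigns each read to the sample whose barcode exactly matches the read
#' prefix (longest barcode tried first, so prefix-free tables are
#' unambiguous); the barcode is stripped from matched reads. Reads
#' matching no barcode are counted as ambiguous and dropped.
#'
#' @param reads data.table with columns `read_id`, `seq`, `qual`.
#' @param barcode_table data.frame with columns `sample_id`, `barcode`
#'   (4-8 bases, unique across samples).
#' @return List with `reads` (input columns plus `sample_id`, barcode
#'   removed from `seq`/`qual`) and `counts` (`raw`, `ambiguous`,
#'   `assigned`).
#' @export
demultiplex <- function(reads, barcode_table) {
  bt <- as.data.table(barcode_table)
  if (anyDuplicated(bt$barcode))
    stop_radmap("duplicate barcode shared by samples: %s",
                paste(unique(bt$barcode[duplicated(bt$barcode)]), collapse = ", "))
  if (any(nchar(bt$barcode) < 4 | nchar(bt$barcode) > 8))
    stop_radmap("barcodes must be 4-8 bases")
  reads <- as.data.table(reads)
  n_raw <- nrow(reads)
  sample_id <- rep(NA_character_, n_raw)
  bclen <- rep(NA_integer_, n_raw)
  for (len in sort(unique(nchar(bt$barcode)), decreasing = TRUE)) {
    todo <- is.na(sample_id)
    if (!any(todo)) break
    pref <- substr(reads$seq[todo], 1, len)
    hit <- match(pref, bt$barcode[nchar(bt$barcode) == len])
    ids <- bt$sample_id[nchar(bt$barcode) == len]
    sample_id[todo] <- ids[hit]
    bclen[todo][!is.na(hit)] <- len
  }
  keep <- !is.na(sample_id)
  out <- reads[keep]
  out[, sample_id := sample_id[keep]]
  out[, seq := substr(seq, bclen[keep] + 1, nchar(seq))]
  out[, qual := substr(qual, bclen[keep] + 1, nchar(qual))]
  list(reads = out[],
       counts = c(raw = n_raw, ambiguous = sum(!keep), assigned = sum(keep)))
}

#' Trim post-barcode reads to the fixed tag length
#'
#' @param seqs,quals character vectors (post-barcode).
#' @param tag_len fixed tag length (default 92, i.e. 100 bp reads minus
#'   the longest 8 bp barcode).
#' @return List with `seq`, `qual` (trimmed, only reads long enough),
#'   `keep` (logical index into the input) and `too_short` count.
#' @export
trim_tag <- function(seqs, quals, tag_len = 92) {
  keep <- nchar(seqs) >= tag_len
  list(seq = substr(seqs[keep], 1, tag_len),
       qual = substr(quals[keep], 1, tag_len),
       keep = keep, too_short = sum(!keep))
}

#' Low-quality read filter
#'
#' A read is dropped when the number of bases below `min_q` reaches
#' `max_low_q + 1` (i.e. five or more sub-Q20 bases under the defaults).
#'
#' @param quals character vector of Phred+33 quality strings (equal
#'   lengths).
#' @param min_q quality threshold (default 20).
#' @param max_low_q maximum tolerated count of bases below `min_q`
#'   (default 4).
#' @return Logical vector: `TRUE` = keep.
#' @export
quality_filter <- function(quals, min_q = 20, max_low_q = 4) {
  if (length(quals) == 0) return(logical(0))
  w <- unique(nchar(quals))
  if (length(w) != 1) {
    return(vapply(quals, function(q)
      sum(utf8ToInt(q) - 33L < min_q) <= max_low_q, logical(1), USE.NAMES = FALSE))
  }
  r <- charToRaw(paste(quals, collapse = ""))
  low <- matrix(as.integer(r) - 33L < min_q, nrow = w)
  colSums(low) <= max_low_q
}

#' Demultiplex, trim and quality-filter a read set
#'
#' @param reads data.table with `read_id`, `seq`, `qual` (raw reads).
#' @param barcode_table data.frame `sample_id`, `barcode`.
#' @param tag_len fixed tag length (default 92).
#' @param min_q,max_low_q quality filter parameters.
#' @return List with `tags` (data.table `sample_id`, `read_id`, `tag`,
#'   `qual`), `counts` (named totals: raw, ambiguous, too_short,
#'   low_quality, retained) and `per_sample` (data.table of per-sample
#'   counts). Raw always equals retained + ambiguous + too_short +
#'   low_quality.
#' @export
process_reads <- function(reads, barcode_table, tag_len = 92, min_q = 20,
                          max_low_q = 4) {
  dm <- demultiplex(reads, barcode_table)
  tr <- trim_tag(dm$reads$seq, dm$reads$qual, tag_len)
  assigned <- dm$reads[tr$keep]
  assigned[, tag := tr$seq]
  assigned[, qual := tr$qual]
  qkeep <- quality_filter(assigned$qual, min_q, max_low_q)
  tags <- assigned[qkeep, .(sample_id, read_id, tag, qual)]
  counts <- c(raw = unname(dm$counts["raw"]),
              ambiguous = unname(dm$counts["ambiguous"]),
              too_short = tr$too_short,
              low_quality = sum(!qkeep),
              retained = nrow(tags))
  per_sample <- merge(
    dm$reads[, .(assigned = .N), by = sample_id],
    tags[, .(retained = .N), by = sample_id],
    by = "sample_id", all.x = TRUE)
  per_sample[is.na(retained), retained := 0]
  list(tags = tags, counts = counts, per_sample = per_sample)
}
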