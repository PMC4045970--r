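## Reference-strategy evaluation: scaffold x linkage-group concordance of
## mapped markers, row purities, and the percent-anchored summary metric.

#' Scaffold-by-linkage-group concordance matrix
#'
#' Counts mapped markers in each (scaffold, linkage group) cell for the
#' `top_n` longest scaffolds. A marker mis-assigned by the aligner (e.g. a
#' repeat collision) shows up as an off-modal cell; row purity (modal count
#' over row total) summarizes how cleanly each scaffold maps to one group.
#'
#' @param map a `genetic_map` (or a data.table from [map_table()]).
#' @param marker_info data.frame mapping `marker` to `scaffold` (its
#'   alignment scaffold).
#' @param scaffold_lengths named numeric vector (selects the top rows).
#' @param top_n number of scaffold rows (default 10).
#' @return Object of class `concordance`: list with `counts` (matrix rows =
#'   scaffolds, cols = LGs), `purity`, `modal_lg`, `off_top` (mapped
#'   markers on non-top scaffolds), `unaligned` (mapped markers with no
#'   scaffold).
#' @export
build_concordance <- function(map, marker_info, scaffold_lengths, top_n = 10) {
  tab <- if (inherits(map, "genetic_map")) map_table(map) else as.data.table(map)
  marker_info <- as.data.table(marker_info)
  tab <- merge(tab, marker_info[, .(marker, scaffold)], by = "marker",
               all.x = TRUE, sort = FALSE)
  top <- names(sort(scaffold_lengths, decreasing = TRUE))[
    seq_len(min(top_n, length(scaffold_lengths)))]
  lgs <- sort(unique(tab$lg))
  counts <- matrix(0L, length(top), length(lgs),
                   dimnames = if (length(lgs))
                     list(top, paste0("LG", lgs)) else list(top, NULL))
  unaligned <- sum(is.na(tab$scaffold))
  on_top <- tab[!is.na(scaffold) & scaffold %in% top]
  if (nrow(on_top) > 0) {
    t2 <- table(factor(on_top$scaffold, levels = top),
                factor(on_top$lg, levels = lgs))
    counts[] <- as.integer(t2)
  }
  off_top <- nrow(tab) - nrow(on_top) - unaligned
  rs <- rowSums(counts)
  modal <- apply(counts, 1, which.max)  # ties break toward lower LG index
  purity <- ifelse(rs > 0, counts[cbind(seq_along(modal), modal)] / rs, NA)
  structure(list(counts = counts, purity = purity,
                 modal_lg = colnames(counts)[modal], off_top = off_top,
                 unaligned = unaligned),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("<concordance> %d scaffolds x %d LGs; mean purity %.3f\n",
              nrow(x$counts), ncol(x$counts), mean(x$purity, na.rm = TRUE)))
  print(x$counts)
  invisible(x)
}

#' Percent of scored markers that were mapped
#'
#' @param n_mapped markers placed on the map.
#' @param n_scored markers scored (passing all quality filters).
#' @param digits rounding (default 0, the whole-percent convention of
#'   mapping summary tables).
#' @return `100 * n_mapped / n_scored`, rounded.
#' @export
percent_anchored <- function(n_mapped, n_scored, digits = 0) {
  if (n_scored == 0) stop_radmap("percent_anchored undefined for n_scored = 0")
  if (n_mapped > n_scored || n_mapped < 0) stop_radmap("need 0 <= n_mapped <= n_scored")
  round(100 * n_mapped / n_scored, digits)
}

#' Row-normalized concordance fractions
#'
#' @param concordance a `concordance` object.
#' @return Matrix of per-row fractions (each non-empty row sums to 1);
#'   empty rows are all zero and flagged in the `"zero_rows"` attribute.
#' @export
heatmap_fractions <- function(concordance) {
  counts <- concordance$counts
  rs <- rowSums(counts)
  frac <- counts / ifelse(rs == 0, 1, rs)
  attr(frac, "zero_rows") <- rownames(counts)[rs == 0]
  frac
}
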