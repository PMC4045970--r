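## Genetic-map-guided scaffold anchoring: assignment of scaffolds to
## linkage groups, ordering/orientation into megascaffolds, AGP emission,
## and the per-group mapping statistics table.

#' Assign scaffolds to linkage groups
#'
#' Each scaffold with at least one mapped marker is assigned to the modal
#' linkage group of its markers; minority markers are counted as conflicts
#' but never split a scaffold. The scaffold's genetic position is the mean
#' cM of its modal-group markers only.
#'
#' @param map a `genetic_map` or [map_table()] output.
#' @param marker_info data.frame mapping `marker` to `scaffold` and `pos`.
#' @return List with `anchors` (data.table `scaffold`, `lg`, `n_markers`,
#'   `n_conflict`, `mean_cm`) and `unanchored` (scaffolds named in
#'   `marker_info` with no mapped marker).
#' @export
assign_scaffolds <- function(map, marker_info) {
  tab <- if (inherits(map, "genetic_map")) map_table(map) else as.data.table(map)
  marker_info <- as.data.table(marker_info)
  tab <- merge(tab, marker_info[, .(marker, scaffold)], by = "marker", sort = FALSE)
  tab <- tab[!is.na(scaffold)]
  anchors <- tab[, {
    k <- table(lg)
    modal <- as.integer(names(k)[which.max(k)])
    .(lg = modal, n_markers = .N, n_conflict = sum(lg != modal),
      mean_cm = mean(cm[lg == modal]))
  }, by = scaffold]
  unanchored <- setdiff(unique(marker_info$scaffold), anchors$scaffold)
  list(anchors = anchors, unanchored = unanchored)
}

#' Order and orient anchored scaffolds into megascaffolds
#'
#' Within each linkage group, scaffolds are sorted by the mean cM of their
#' markers (ties broken by descending length) and oriented by the sign of
#' the Spearman rank correlation between marker physical positions and cM
#' positions; scaffolds with fewer than two distinct cM positions (or zero
#' correlation) stay unoriented and are written as `+`. Components are
#' joined with fixed-length `N` gaps into AGP v2.1 rows.
#'
#' @param anchors output of [assign_scaffolds()].
#' @param map a `genetic_map` or [map_table()] output.
#' @param marker_info data.frame with `marker`, `scaffold`, `pos`.
#' @param scaffold_lengths named numeric vector.
#' @param gap_len inter-scaffold gap length in bases (default 100).
#' @return Object of class `megascaffold_set`: list with `scaffolds`
#'   (data.table incl. `orientation`), `agp` (data.table of AGP v2.1 rows)
#'   and `lengths` (named megascaffold lengths).
#' @export
order_orient <- function(anchors, map, marker_info, scaffold_lengths,
                         gap_len = 100) {
  tab <- if (inherits(map, "genetic_map")) map_table(map) else as.data.table(map)
  marker_info <- as.data.table(marker_info)
  tab <- merge(tab, marker_info[, .(marker, scaffold, phys_pos = pos)],
               by = "marker", sort = FALSE)
  anc <- as.data.table(anchors$anchors)
  anc[, len := scaffold_lengths[scaffold]]
  setorder(anc, lg, mean_cm, -len, scaffold)
  orient_one <- function(sc, lg_i) {
    mk <- tab[scaffold == sc & lg == lg_i]
    if (length(unique(mk$cm)) < 2) return("unoriented")
    rho <- suppressWarnings(cor(mk$phys_pos, mk$cm, method = "spearman"))
    if (is.na(rho) || rho == 0) return("unoriented")
    if (rho > 0) "+" else "-"
  }
  anc[, orientation := mapply(orient_one, scaffold, lg)]
  agp_rows <- list(); meg_len <- numeric(0)
  for (g in sort(unique(anc$lg))) {
    sub <- anc[lg == g]
    obj <- sprintf("megascaffold%d", g)
    beg <- 1; part <- 0L
    for (i in seq_len(nrow(sub))) {
      if (i > 1) {
        part <- part + 1L
        agp_rows[[length(agp_rows) + 1]] <- data.table(
          object = obj, object_beg = beg, object_end = beg + gap_len - 1,
          part_number = part, component_type = "U", component_id = as.character(gap_len),
          component_beg = "scaffold", component_end = "yes",
          orientation = "map")
        beg <- beg + gap_len
      }
      part <- part + 1L
      len <- sub$len[i]
      agp_rows[[length(agp_rows) + 1]] <- data.table(
        object = obj, object_beg = beg, object_end = beg + len - 1,
        part_number = part, component_type = "W", component_id = sub$scaffold[i],
        component_beg = "1", component_end = as.character(len),
        orientation = if (sub$orientation[i] == "-") "-" else "+")
      beg <- beg + len
    }
    meg_len[obj] <- beg - 1
  }
  structure(list(scaffolds = anc, agp = rbindlist(agp_rows), lengths = meg_len),
            class = "megascaffold_set")
}

#' Write megascaffolds as AGP v2.1
#' @param meg a `megascaffold_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(meg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  agp <- meg$agp
  lines <- apply(agp, 1, function(r) paste(r, collapse = "\t"))
  writeLines(lines, con)
  invisible(path)
}

#' Read an AGP file
#' @param path AGP file written by [write_agp()] (or any AGP v2.1 file).
#' @return data.table of AGP rows with standard column names.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  dt <- as.data.table(do.call(rbind, strsplit(lines, "\t")))
  names(dt) <- c("object", "object_beg", "object_end", "part_number",
                 "component_type", "component_id", "component_beg",
                 "component_end", "orientation")
  for (col in c("object_beg", "object_end", "part_number"))
    dt[[col]] <- as.integer(dt[[col]])
  dt
}

#' Per-linkage-group mapping statistics
#'
#' Builds the standard per-group summary of a map-anchored assembly:
#' marker density (markers per cM, 1 decimal), mean inter-marker interval,
#' anchored physical size and Mb/cM (2 decimals), with a totals row. The
#' totals mean interval uses markers minus one interval per group.
#'
#' @param lg character or integer linkage-group labels.
#' @param cm numeric map length of each group (cM).
#' @param markers integer mapped marker count per group.
#' @param physical_mb numeric anchored physical size per group (Mb).
#' @param scaffolds optional integer scaffold count per group.
#' @return data.table with one row per group plus a `Total` row; columns
#'   `lg`, `cm`, `markers`, `markers_per_cm`, `mean_interval_cm`,
#'   `physical_mb`, `mb_per_cm` and (if given) `scaffolds`.
#' @export
map_stats <- function(lg, cm, markers, physical_mb, scaffolds = NULL) {
  if (length(lg) == 0) return(data.table())
  dt <- data.table(lg = as.character(lg), cm = cm, markers = markers,
                   physical_mb = physical_mb)
  if (!is.null(scaffolds)) dt$scaffolds <- scaffolds
  tot <- data.table(lg = "Total", cm = sum(cm), markers = sum(markers),
                    physical_mb = sum(physical_mb))
  if (!is.null(scaffolds)) tot$scaffolds <- sum(scaffolds)
  out <- rbindlist(list(dt, tot), fill = TRUE)
  n_lg <- nrow(dt)
  n_intervals <- c(pmax(markers - 1, 1), max(sum(markers) - n_lg, 1))
  out[, markers_per_cm := round(markers / cm, 1)]
  out[, mean_interval_cm := round(cm / n_intervals, 2)]
  out[, mb_per_cm := round(physical_mb / cm, 2)]
  out[]
}
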