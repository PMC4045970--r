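## Linkage map construction for CP (cross-pollinator) F1 populations:
## two-point recombination/LOD estimation, grouping, Stam-style weighted
## least-squares ordering, and Kosambi map distances.

#' Kosambi map function
#'
#' Converts a recombination fraction to a map distance in centimorgans,
#' `d = 25 * ln((1 + 2r) / (1 - 2r))`. The Kosambi function allows partial
#' crossover interference and is the map function used throughout the
#' estimation side of this package.
#'
#' @param r numeric vector of recombination fractions in `[0, 0.5)`.
#'   Values at or above 0.5 map to `Inf`.
#' @return Numeric vector of distances in cM.
#' @examples
#' kosambi_cm(c(0, 0.1, 0.25))
#' @export
kosambi_cm <- function(r) {
  if (any(r < 0, na.rm = TRUE)) stop_radmap("recombination fractions must be >= 0")
  out <- ifelse(r >= 0.5, Inf, 25 * log((1 + 2 * r) / (1 - 2 * r)))
  out[r == 0] <- 0
  out
}

#' Inverse Kosambi map function
#'
#' @param d numeric vector of map distances in cM.
#' @return Recombination fractions `r = 0.5 * tanh(2d / 100)`.
#' @export
kosambi_r <- function(d) 0.5 * tanh(2 * d / 100)

#' Haldane map function (no interference)
#'
#' Recombination fraction implied by a Poisson crossover process over a
#' distance of `d` cM; this is the truth-side conversion for the simulator,
#' whose crossovers are drawn without interference.
#'
#' @param d numeric vector of map distances in cM.
#' @return Recombination fractions `0.5 * (1 - exp(-2d / 100))`.
#' @export
haldane_r <- function(d) 0.5 * (1 - exp(-2 * d / 100))

## CP code bookkeeping ------------------------------------------------------

cp_codes <- function(seg_type) {
  switch(seg_type,
    "nnxnp" = c("nn", "np"),
    "lmxll" = c("ll", "lm"),
    "hkxhk" = c("hh", "hk", "kk"),
    stop_radmap("unknown segregation type '%s'", seg_type)
  )
}

seg_parent_het <- function(seg_type) {
  switch(seg_type,
    "nnxnp" = c(father = TRUE, mother = FALSE),
    "lmxll" = c(father = FALSE, mother = TRUE),
    "hkxhk" = c(father = TRUE, mother = TRUE),
    stop_radmap("unknown segregation type '%s'", seg_type)
  )
}

#' CP genotype container
#'
#' Bundles a marker-by-progeny matrix of CP genotype codes with per-marker
#' metadata. Codes are `nn`/`np` (paternal testcross), `ll`/`lm` (maternal
#' testcross), `hh`/`hk`/`kk` (intercross) and `--` for missing.
#'
#' @param calls character matrix, rows = markers, columns = progeny; row
#'   names are marker ids, column names progeny ids.
#' @param info data.frame with one row per marker: columns `marker`,
#'   `seg_type`, and optionally `scaffold`, `pos` (0-based), `source`.
#' @return An object of class `cp_geno`.
#' @export
cp_geno <- function(calls, info) {
  info <- as.data.table(info)
  if (is.null(rownames(calls))) rownames(calls) <- info$marker
  if (!identical(rownames(calls), as.character(info$marker)))
    stop_radmap("rownames(calls) must match info$marker")
  if (!all(info$seg_type %in% c("nnxnp", "lmxll", "hkxhk")))
    stop_radmap("seg_type must be nnxnp, lmxll or hkxhk")
  if (!"source" %in% names(info)) info$source <- "radseq"
  valid <- c(unlist(lapply(c("nnxnp", "lmxll", "hkxhk"), cp_codes)), MISSING_CALL)
  if (!all(calls %in% valid)) stop_radmap("invalid CP codes in calls matrix")
  structure(list(calls = calls, info = info), class = "cp_geno")
}

#' @export
print.cp_geno <- function(x, ...) {
  cat(sprintf("<cp_geno> %d markers x %d progeny (%s)\n",
              nrow(x$calls), ncol(x$calls),
              paste(sprintf("%s: %d", names(table(x$info$seg_type)),
                            table(x$info$seg_type)), collapse = ", ")))
  invisible(x)
}

#' Merge external (e.g. SSR) markers into a CP genotype set
#'
#' External markers arrive as CP-coded genotype tables from assays that do
#' not go through the sequencing depth machinery; they bypass depth filters
#' but are still subjected to the integrity (missingness) and segregation
#' distortion filters before merging.
#'
#' @param geno a [cp_geno] object.
#' @param external a [cp_geno] object (or `calls` + `info` list) sharing the
#'   same progeny columns; its `source` is set to `"external"`.
#' @param max_missing maximum tolerated missing fraction (integrity filter).
#' @return A merged [cp_geno]; external markers failing filters are dropped.
#' @export
merge_external_markers <- function(geno, external, max_missing = 0.10) {
  if (nrow(external$calls) == 0) return(geno)
  if (!identical(colnames(geno$calls), colnames(external$calls)))
    stop_radmap("external table progeny ids do not match genotype matrix")
  keep <- vapply(seq_len(nrow(external$calls)), function(i) {
    calls <- external$calls[i, ]
    filter_integrity(calls, max_missing = max_missing) &&
      filter_distortion(calls, external$info$seg_type[i])
  }, logical(1))
  ext_info <- as.data.table(external$info)[keep]
  ext_info$source <- "external"
  info <- rbindlist(list(as.data.table(geno$info), ext_info), fill = TRUE)
  cp_geno(rbind(geno$calls, external$calls[keep, , drop = FALSE]), info)
}

## Two-point estimation -----------------------------------------------------

#' Two-point recombination fraction and LOD
#'
#' Estimates the recombination fraction between two CP markers and the LOD
#' score for linkage against independence (r = 0.5). Same-parent testcross
#' pairs use the closed-form maximum-likelihood estimate `r = R/N` with the
#' phase chosen to keep `r <= 0.5`; pairs involving intercross (`hkxhk`)
#' markers are fitted by numeric maximum likelihood over the joint progeny
#' class multinomial, maximized over parental phase combinations.
#'
#' @param calls_a,calls_b character vectors of CP codes over the same progeny.
#' @param type_a,type_b segregation types (`nnxnp`, `lmxll`, `hkxhk`).
#' @return A list with elements `r`, `lod`, `n` (informative progeny) and
#'   `phase`. Cross-parent testcross pairs share no meioses and return
#'   `r = NA`, `lod = 0`.
#' @export
estimate_rf <- function(calls_a, calls_b, type_a, type_b) {
  ok <- calls_a != MISSING_CALL & calls_b != MISSING_CALL
  n <- sum(ok)
  if (n == 0) return(list(r = NA_real_, lod = 0, n = 0L, phase = NA_character_))
  a <- calls_a[ok]; b <- calls_b[ok]
  testcross <- c("nnxnp", "lmxll")
  if (type_a %in% testcross && type_b %in% testcross) {
    if (type_a != type_b) {           # different parents: no shared meioses
      return(list(r = NA_real_, lod = 0, n = n, phase = NA_character_))
    }
    het <- cp_codes(type_a)[2]
    recomb <- xor(a == het, b == het)
    R <- sum(recomb)
    phase <- if (R <= n - R) "coupling" else "repulsion"
    Rm <- min(R, n - R)
    r <- Rm / n
    lod <- if (r == 0) n * log10(2)
           else (n - Rm) * log10(2 * (1 - r)) + Rm * log10(2 * r)
    return(list(r = r, lod = max(lod, 0), n = n, phase = phase))
  }
  rf_ml_pair(a, b, type_a, type_b, n)
}

## Joint progeny-class probabilities for a marker pair, as a function of r.
## Enumerates parental two-locus gametes; a parent heterozygous at both loci
## recombines with probability r under the given phase, a parent
## heterozygous at one locus transmits alleles 0/1 with probability 1/2.
pair_class_probs <- function(type_a, type_b, phase_f, phase_m, r) {
  het_a <- seg_parent_het(type_a); het_b <- seg_parent_het(type_b)
  gamete_probs <- function(het1, het2, phase) {
    # returns matrix over (g1 in 0:1, g2 in 0:1) of transmission probabilities
    p <- matrix(0.25, 2, 2)
    if (het1 && het2) {
      same <- (1 - r) / 2; diff <- r / 2
      if (phase == "repulsion") { tmp <- same; same <- diff; diff <- tmp }
      p <- matrix(c(same, diff, diff, same), 2, 2)
    } else if (het1 || het2) {
      p <- matrix(0.25, 2, 2)  # independent halves; marginal 1/2 each
    } else {
      p <- matrix(0.25, 2, 2)  # alleles irrelevant at hom loci
    }
    p
  }
  pf <- gamete_probs(het_a["father"], het_b["father"], phase_f)
  pm <- gamete_probs(het_a["mother"], het_b["mother"], phase_m)
  obs_label <- function(type, f, m) {
    switch(type,
      "nnxnp" = c("nn", "np")[f + 1L],
      "lmxll" = c("ll", "lm")[m + 1L],
      "hkxhk" = c("hh", "hk", "kk")[f + m + 1L])
  }
  out <- list()
  for (fa in 0:1) for (fb in 0:1) for (ma in 0:1) for (mb in 0:1) {
    pr <- pf[fa + 1, fb + 1] * pm[ma + 1, mb + 1]
    key <- paste(obs_label(type_a, fa, ma), obs_label(type_b, fb, mb), sep = ":")
    out[[key]] <- (out[[key]] %||% 0) + pr
  }
  unlist(out)
}

rf_ml_pair <- function(a, b, type_a, type_b, n) {
  counts <- table(paste(a, b, sep = ":"))
  het_a <- seg_parent_het(type_a); het_b <- seg_parent_het(type_b)
  phases_f <- if (het_a["father"] && het_b["father"]) c("coupling", "repulsion") else "coupling"
  phases_m <- if (het_a["mother"] && het_b["mother"]) c("coupling", "repulsion") else "coupling"
  ll <- function(r, pf, pm) {
    p <- pair_class_probs(type_a, type_b, pf, pm, r)
    p <- p[names(counts)]
    if (any(is.na(p) | p <= 0)) return(-Inf)
    sum(counts * log(p))
  }
  best <- list(ll = -Inf, r = 0.5, phase = NA_character_)
  for (pf in phases_f) for (pm in phases_m) {
    opt <- optimize(function(r) ll(r, pf, pm), c(1e-6, 0.5), maximum = TRUE,
                    tol = 1e-6)
    cand <- list(ll = opt$objective, r = opt$maximum, phase = paste(pf, pm, sep = "/"))
    if (cand$ll > best$ll) best <- cand
  }
  ll_null <- ll(0.5, "coupling", "coupling")
  lod <- max((best$ll - ll_null) / log(10), 0)
  r_hat <- min(best$r, 0.5)
  if (lod < 1e-10) { lod <- 0 }
  list(r = r_hat, lod = lod, n = n, phase = best$phase)
}

#' All-pairs two-point table
#'
#' @param geno a [cp_geno] object.
#' @param markers optional subset of marker ids.
#' @param min_lod_keep drop pairs with LOD below this from the returned
#'   table (they carry no linkage signal); default 0 keeps all.
#' @return data.table with columns `a`, `b`, `r`, `lod`, `n`, `phase`.
#' @export
two_point_table <- function(geno, markers = NULL, min_lod_keep = 0) {
  ids <- markers %||% rownames(geno$calls)
  m <- length(ids)
  if (m < 2) return(data.table(a = character(), b = character(),
                               r = numeric(), lod = numeric(),
                               n = integer(), phase = character()))
  calls <- geno$calls[ids, , drop = FALSE]
  types <- setNames(geno$info$seg_type[match(ids, geno$info$marker)], ids)
  res <- vector("list", m * (m - 1) / 2)
  k <- 0L
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      est <- estimate_rf(calls[i, ], calls[j, ], types[[i]], types[[j]])
      k <- k + 1L
      res[[k]] <- data.table(a = ids[i], b = ids[j], r = est$r, lod = est$lod,
                             n = est$n, phase = est$phase)
    }
  }
  tp <- rbindlist(res)
  tp[lod >= min_lod_keep | is.na(r)]
}

## Grouping and ordering ----------------------------------------------------

#' Partition markers into linkage groups
#'
#' Builds a graph with an edge for every marker pair whose two-point LOD and
#' recombination fraction clear the thresholds, and returns its connected
#' components as linkage groups, largest first.
#'
#' @param tp two-point table from [two_point_table()].
#' @param markers character vector of all marker ids under consideration
#'   (needed so fully unlinked markers are reported).
#' @param lod_min minimum LOD for an edge (default 5.0).
#' @param rf_max maximum recombination fraction for an edge (default 0.25).
#' @return A list with `groups` (list of character vectors, size-sorted) and
#'   `unlinked` (singleton markers).
#' @export
group_markers <- function(tp, markers, lod_min = 5.0, rf_max = 0.25) {
  edges <- tp[!is.na(r) & lod >= lod_min & r <= rf_max]
  g <- igraph::graph_from_data_frame(edges[, .(a, b)], directed = FALSE,
                                     vertices = data.frame(name = markers))
  comp <- igraph::components(g)
  groups <- split(names(comp$membership), comp$membership)
  sizes <- vapply(groups, length, integer(1))
  groups <- groups[order(-sizes, vapply(groups, min, character(1)))]
  names(groups) <- NULL
  list(groups = groups[vapply(groups, length, integer(1)) > 1],
       unlinked = unlist(groups[vapply(groups, length, integer(1)) == 1]) %||% character())
}

## Pairwise distance/weight matrices for a marker set.
tp_matrices <- function(tp, ids) {
  m <- length(ids)
  d <- matrix(NA_real_, m, m, dimnames = list(ids, ids))
  w <- matrix(0, m, m, dimnames = list(ids, ids))
  sub <- tp[a %in% ids & b %in% ids & !is.na(r)]
  ai <- match(sub$a, ids); bi <- match(sub$b, ids)
  dv <- kosambi_cm(pmin(sub$r, 0.4999))
  d[cbind(ai, bi)] <- dv; d[cbind(bi, ai)] <- dv
  w[cbind(ai, bi)] <- sub$lod; w[cbind(bi, ai)] <- sub$lod
  list(d = d, w = w)
}

## Weighted least-squares cost of an order: fit non-negative inter-marker
## gaps minimizing sum_w (d_fit - d_obs)^2 over all weighted pairs.
wls_fit <- function(ord_idx, d, w, w_min = 0.1) {
  k <- length(ord_idx)
  if (k < 2) return(list(cost = 0, gaps = numeric(0)))
  dw <- w[ord_idx, ord_idx]; dd <- d[ord_idx, ord_idx]
  ut <- which(upper.tri(dw) & dw > w_min & !is.na(dd), arr.ind = TRUE)
  if (nrow(ut) == 0) return(list(cost = Inf, gaps = rep(1, k - 1)))
  lo <- ut[, 1]; hi <- ut[, 2]
  ngap <- k - 1
  A <- matrix(0, nrow(ut), ngap)
  gseq <- seq_len(ngap)
  A[] <- outer(lo, gseq, "<=") & outer(hi - 1, gseq, ">=")
  wts <- dw[ut]; dv <- dd[ut]
  Aw <- A * sqrt(wts)
  M <- crossprod(Aw) + diag(1e-8, ngap)
  bvec <- crossprod(Aw, sqrt(wts) * dv)
  g <- tryCatch(drop(solve(M, bvec)), error = function(e) rep(mean(dv) / ngap, ngap))
  g[g < 0] <- 0
  resid <- drop(A %*% g) - dv
  list(cost = sum(wts * resid^2), gaps = g)
}

#' Order markers within a linkage group
#'
#' Incremental weighted-least-squares ordering in the style of regression
#' mapping: markers are inserted in decreasing order of total linkage
#' information (sum of LOD over pairs), each at the position minimizing the
#' weighted squared disagreement between fitted additive distances and the
#' observed pairwise Kosambi distances, followed by ripple passes over
#' sliding windows of three accepting improvements. Deterministic for a
#' given two-point table (ties broken by marker id).
#'
#' @param group character vector of marker ids (>= 2).
#' @param tp two-point table covering the group.
#' @param ripple_window window size for the post-insertion ripple (default 3).
#' @return Character vector of marker ids in map order (orientation fixed so
#'   the lexicographically smaller terminal marker comes first).
#' @export
order_group <- function(group, tp, ripple_window = 3) {
  if (length(group) < 2) return(group)
  ids <- sort(group)
  mats <- tp_matrices(tp, ids)
  d <- mats$d; w <- mats$w
  polish <- function(ord) {
    ord <- ripple_order(ord, d, w, window = ripple_window)
    ord <- two_opt(ord, d, w)
    ripple_order(ord, d, w, window = ripple_window)
  }
  # candidate 1: incremental insertion in decreasing information order
  info <- colSums(w, na.rm = TRUE)
  add_order <- ids[order(-info, ids)]
  ord <- match(add_order[1:2], ids)
  for (nxt in add_order[-(1:2)]) {
    ni <- match(nxt, ids)
    best <- list(cost = Inf, ord = NULL)
    for (posn in 0:length(ord)) {
      cand <- append(ord, ni, after = posn)
      fit <- wls_fit(cand, d, w)
      if (fit$cost < best$cost) best <- list(cost = fit$cost, ord = cand)
    }
    ord <- best$ord
  }
  ord1 <- polish(ord)
  # candidate 2: spectral seriation of the LOD affinity graph (robust to
  # the folded local optima greedy insertion can fall into)
  ord2 <- if (length(ids) >= 4) polish(spectral_seed(ids, w)) else ord1
  ord <- if (wls_fit(ord2, d, w)$cost < wls_fit(ord1, d, w)$cost) ord2 else ord1
  out <- ids[ord]
  if (out[1] > out[length(out)]) out <- rev(out)
  out
}

## Fiedler-vector seriation: order markers by the second-smallest
## eigenvector of the Laplacian of the LOD affinity matrix.
spectral_seed <- function(ids, w) {
  A <- w[ids, ids]
  diag(A) <- 0
  L <- diag(rowSums(A)) - A
  ev <- eigen(L, symmetric = TRUE)
  order(ev$vectors[, length(ids) - 1])
}

## Segment-reversal (2-opt) polishing: repairs folded orders that local
## window ripples cannot reach.
two_opt <- function(ord, d, w, max_pass = 5) {
  k <- length(ord)
  if (k < 4) return(ord)
  cur_cost <- wls_fit(ord, d, w)$cost
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        cand <- ord
        cand[i:j] <- rev(ord[i:j])
        cost <- wls_fit(cand, d, w)$cost
        if (cost < cur_cost - 1e-9) {
          ord <- cand; cur_cost <- cost; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

ripple_order <- function(ord, d, w, window = 3, max_pass = 4) {
  if (length(ord) <= window) {
    perms <- perms_of(seq_along(ord))
    costs <- vapply(perms, function(p) wls_fit(ord[p], d, w)$cost, numeric(1))
    return(ord[perms[[which.min(costs)]]])
  }
  cur_cost <- wls_fit(ord, d, w)$cost
  for (pass in seq_len(max_pass)) {
    improved <- FALSE
    for (s in seq_len(length(ord) - window + 1)) {
      idx <- s:(s + window - 1)
      for (p in perms_of(idx)) {
        if (identical(p, idx)) next
        cand <- ord; cand[idx] <- ord[p]
        cost <- wls_fit(cand, d, w)$cost
        if (cost < cur_cost - 1e-9) {
          ord <- cand; cur_cost <- cost; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  ord
}

perms_of <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

#' Assign cM positions along an ordered group
#'
#' Positions are cumulative Kosambi distances over adjacent pairs; when an
#' adjacent pair has no usable two-point estimate the gap is taken as the
#' shortest-path Kosambi distance through intermediate markers.
#'
#' @param ordered_group character vector of marker ids in map order.
#' @param tp two-point table.
#' @return data.table with columns `marker` and `cm` (first marker at 0).
#' @export
map_positions <- function(ordered_group, tp) {
  k <- length(ordered_group)
  if (k == 1) return(data.table(marker = ordered_group, cm = 0))
  sub <- tp[a %in% ordered_group & b %in% ordered_group & !is.na(r) & lod > 0]
  sub[, cm := kosambi_cm(pmin(r, 0.4999))]
  gaps <- numeric(k - 1)
  need_path <- FALSE
  for (i in seq_len(k - 1)) {
    u <- ordered_group[i]; v <- ordered_group[i + 1]
    hit <- sub[(a == u & b == v) | (a == v & b == u)]
    if (nrow(hit) > 0) gaps[i] <- hit$cm[1] else { gaps[i] <- NA; need_path <- TRUE }
  }
  if (need_path) {
    g <- igraph::graph_from_data_frame(sub[, .(a, b, weight = cm)],
                                       directed = FALSE,
                                       vertices = data.frame(name = ordered_group))
    for (i in which(is.na(gaps))) {
      dpath <- igraph::distances(g, v = ordered_group[i], to = ordered_group[i + 1])
      gaps[i] <- if (is.finite(dpath[1, 1])) dpath[1, 1] else 0
    }
  }
  data.table(marker = ordered_group, cm = cumsum(c(0, gaps)))
}

#' Construct a genetic map from CP genotypes
#'
#' Runs two-point estimation, grouping, ordering and positioning for one
#' parental map. Paternal maps use `nnxnp` plus `hkxhk` markers, maternal
#' maps `lmxll` plus `hkxhk` (intercross markers segregate through both
#' parents and contribute to either map).
#'
#' @param geno a [cp_geno] object.
#' @param parent `"paternal"` or `"maternal"`.
#' @param lod_min,rf_max grouping thresholds (defaults 5.0 and 0.25).
#' @param ripple_window ripple window for ordering.
#' @return An object of class `genetic_map`: list with `lgs` (list of
#'   data.tables `marker`, `cm`), `unlinked`, `tp`, `parent` and
#'   `total_cm`.
#' @export
build_genetic_map <- function(geno, parent = c("paternal", "maternal"),
                              lod_min = 5.0, rf_max = 0.25, ripple_window = 3) {
  parent <- match.arg(parent)
  want <- if (parent == "paternal") c("nnxnp", "hkxhk") else c("lmxll", "hkxhk")
  ids <- geno$info$marker[geno$info$seg_type %in% want]
  if (length(ids) < 2) stop_radmap("fewer than 2 informative markers for %s map", parent)
  tp <- two_point_table(geno, markers = as.character(ids))
  grp <- group_markers(tp, as.character(ids), lod_min = lod_min, rf_max = rf_max)
  lgs <- lapply(grp$groups, function(g) {
    ord <- order_group(g, tp, ripple_window = ripple_window)
    map_positions(ord, tp)
  })
  structure(list(lgs = lgs, unlinked = grp$unlinked, tp = tp, parent = parent,
                 total_cm = sum(vapply(lgs, function(x) max(x$cm), numeric(1)))),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %s: %d linkage groups, %d markers, %.1f cM total\n",
              x$parent, length(x$lgs),
              sum(vapply(x$lgs, nrow, integer(1))), x$total_cm))
  for (i in seq_along(x$lgs))
    cat(sprintf("  LG%d: %d markers, %.1f cM\n", i, nrow(x$lgs[[i]]),
                max(x$lgs[[i]]$cm)))
  if (length(x$unlinked)) cat(sprintf("  unlinked: %d\n", length(x$unlinked)))
  invisible(x)
}

#' Flatten a genetic map to a table
#' @param map a `genetic_map`.
#' @return data.table with columns `lg`, `marker`, `cm`.
#' @export
map_table <- function(map) {
  rbindlist(lapply(seq_along(map$lgs), function(i) {
    data.table(lg = i, map$lgs[[i]])
  }))
}
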