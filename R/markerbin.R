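## Recombination-bin collapsing: markers with identical segregation
## patterns (no observed recombinant among the progeny) are mapped as one
## unit, shrinking the ordering problem without losing information.

## Phase flip of a CP call vector (testcross classes swapped; intercross
## homozygote classes swapped, heterozygotes invariant).
flip_calls <- function(calls, seg_type) {
  map <- switch(seg_type,
    "nnxnp" = c(nn = "np", np = "nn"),
    "lmxll" = c(ll = "lm", lm = "ll"),
    "hkxhk" = c(hh = "kk", hk = "hk", kk = "hh"))
  out <- unname(map[calls])
  out[is.na(out)] <- MISSING_CALL
  out
}

#' Similarity score between two markers
#'
#' The score over `n` progeny is the count of progeny where the two calls
#' are identical plus the count where either call is missing; a score of
#' `n` means no observed recombinant on the shared non-missing progeny.
#' Because linkage phase is arbitrary, the score is computed under both
#' phase alignments of the second marker and the maximum is taken.
#'
#' @param a,b character CP call vectors over the same progeny.
#' @param seg_type shared segregation type of the two markers.
#' @return Integer score in `[0, n]`.
#' @export
similarity_score <- function(a, b, seg_type = "nnxnp") {
  if (length(a) != length(b)) stop_radmap("markers cover different progeny sets")
  miss <- a == MISSING_CALL | b == MISSING_CALL
  direct <- sum(a == b & !miss) + sum(miss)
  flipped <- sum(a == flip_calls(b, seg_type) & !miss) + sum(miss)
  max(direct, flipped)
}

#' Collapse co-segregating markers into recombination bins
#'
#' Two markers share a bin only when their similarity score equals the
#' number of progeny (perfect compatibility: zero conflicting calls), and a
#' marker joins a bin only if it is compatible, under one common phase
#' orientation, with every current member (conflict veto). Markers are
#' processed in a canonical order (scaffold, position, id) so the result is
#' invariant to input order. The bin representative is the member with the
#' fewest missing calls, ties broken by smallest genomic coordinate then id.
#'
#' @param geno a [cp_geno] object (markers already quality-filtered; only
#'   markers of the same segregation type can share a bin).
#' @return List with `bins` (data.table `bin_id`, `marker`,
#'   `representative`, `n_members`) and `geno` (a [cp_geno] with one row
#'   per bin, carrying the representative's calls and metadata).
#' @export
collapse_bins <- function(geno) {
  info <- as.data.table(geno$info)
  ord <- order(info$scaffold %||% "", info$pos %||% 0, info$marker)
  ids <- as.character(info$marker[ord])
  n <- ncol(geno$calls)
  bins <- list()  # each: list(type, members, vectors (list, bin orientation))
  for (id in ids) {
    ty <- info$seg_type[info$marker == id]
    v <- geno$calls[id, ]
    placed <- FALSE
    for (bi in seq_along(bins)) {
      bn <- bins[[bi]]
      if (bn$type != ty) next
      for (cand in list(v, flip_calls(v, ty))) {
        ok <- all(vapply(bn$vectors, function(u) {
          miss <- u == MISSING_CALL | cand == MISSING_CALL
          all(u[!miss] == cand[!miss])
        }, logical(1)))
        if (ok) {
          bins[[bi]]$members <- c(bn$members, id)
          bins[[bi]]$vectors <- c(bn$vectors, list(cand))
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      bins[[length(bins) + 1]] <- list(type = ty, members = id, vectors = list(v))
    }
  }
  rep_of <- function(members) {
    sub <- info[match(members, info$marker)]
    nmiss <- vapply(members, function(m) sum(geno$calls[m, ] == MISSING_CALL),
                    integer(1))
    sub$nmiss <- nmiss
    key <- order(sub$nmiss, sub$scaffold %||% "", sub$pos %||% 0, sub$marker)
    as.character(sub$marker[key[1]])
  }
  tab <- rbindlist(lapply(seq_along(bins), function(i) {
    reps <- rep_of(bins[[i]]$members)
    data.table(bin_id = sprintf("bin%04d", i), marker = bins[[i]]$members,
               representative = reps, n_members = length(bins[[i]]$members))
  }))
  reps <- unique(tab[, .(bin_id, representative)])$representative
  bin_geno <- cp_geno(geno$calls[reps, , drop = FALSE],
                      info[match(reps, info$marker)])
  list(bins = tab, geno = bin_geno)
}
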