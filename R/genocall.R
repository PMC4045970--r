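## Marker discovery and genotype calling: per-locus allele identification,
## parental segregation typing, progeny CP calls, and the marker-quality
## filters (depth coverage, integrity, segregation distortion).

#' Call alleles and per-sample genotypes at one locus
#'
#' Distinct tag sequences in a cluster are candidate alleles; a sequence is
#' accepted as an allele when it reaches at least `min_frac` of some
#' sample's reads at the locus (with `min_reads` total support), which
#' discounts singleton sequencing-error variants. A sample is called
#' heterozygous when both alleles each account for at least `min_frac` of
#' that sample's reads; otherwise it is homozygous for its majority allele.
#' Loci presenting more than two alleles violate diploid expectations and
#' are discarded.
#'
#' @param counts data.frame/data.table with columns `sample_id`, `tag`
#'   (sequence) and `n` (reads).
#' @param discovery_samples sample ids forming the allele-discovery panel
#'   (normally the two deeply sequenced parents, whose per-sample
#'   fractions are robust to sequencing error); `NULL` uses every sample.
#' @param min_frac minor-allele fraction threshold (default 0.25).
#' @param min_reads minimum total support for an allele sequence.
#' @return List with `alleles` (character, length <= 2), `genotypes`
#'   (named list per sample: integer allele-index pair, or `NA`), `depth`
#'   (named total reads per sample) and `status`
#'   (`"ok"`, `"monomorphic"` or `"discarded"`).
#' @export
call_locus_alleles <- function(counts, discovery_samples = NULL,
                               min_frac = 0.25, min_reads = 2) {
  counts <- as.data.table(counts)
  tot <- counts[, .(depth = sum(n)), by = sample_id]
  depth <- setNames(tot$depth, tot$sample_id)
  per <- counts[, .(n = sum(n)), by = .(sample_id, tag)]
  per[, frac := n / depth[sample_id]]
  disc <- if (is.null(discovery_samples)) per else
    per[sample_id %in% discovery_samples]
  cand <- disc[, .(support = sum(n), maxfrac = max(frac)), by = tag]
  alleles <- cand[support >= min_reads & maxfrac >= min_frac][order(-support, tag)]$tag
  if (length(alleles) == 0)
    return(list(alleles = character(), genotypes = list(), depth = depth,
                status = "discarded"))
  if (length(alleles) > 2)
    return(list(alleles = alleles, genotypes = list(), depth = depth,
                status = "discarded"))
  gts <- lapply(names(depth), function(s) {
    sub <- per[sample_id == s & tag %in% alleles]
    if (nrow(sub) == 0) return(NA)
    cnt <- setNames(rep(0, length(alleles)), alleles)
    cnt[sub$tag] <- sub$n
    frac <- cnt / sum(cnt)  # over allele-classified reads
    if (length(alleles) == 2 && all(frac >= min_frac)) return(c(1L, 2L))
    i <- unname(which.max(cnt))
    if (frac[i] >= min_frac) c(i, i) else NA
  })
  names(gts) <- names(depth)
  list(alleles = alleles, genotypes = gts, depth = depth,
       status = if (length(alleles) == 1) "monomorphic" else "ok")
}

#' Classify parental segregation type
#'
#' Pseudo-testcross logic for an outbred F1: a locus heterozygous in the
#' father and homozygous in the mother is a paternal testcross (`nnxnp`,
#' segregating 1:1 and mapping on the paternal map); the mirror case is a
#' maternal testcross (`lmxll`); both parents heterozygous for the same
#' allele pair is an intercross (`hkxhk`, 1:2:1); anything else carries no
#' mappable segregation.
#'
#' @param maternal,paternal integer allele-index pairs (e.g. `c(1,2)`) or
#'   `NA` when the parent could not be called.
#' @return One of `"nnxnp"`, `"lmxll"`, `"hkxhk"`, `"uninformative"`.
#' @export
type_parental_segregation <- function(maternal, paternal) {
  het <- function(g) length(g) == 2 && !anyNA(g) && g[1] != g[2]
  if (anyNA(maternal) || anyNA(paternal)) return("uninformative")
  mh <- het(maternal); ph <- het(paternal)
  if (ph && !mh) return("nnxnp")
  if (mh && !ph) return("lmxll")
  if (mh && ph && setequal(maternal, paternal)) return("hkxhk")
  "uninformative"
}

## CP code for one progeny genotype given the segregation type and the
## mother's homozygous allele index (testcross cases).
cp_code_progeny <- function(gt, seg_type, shared_allele = NULL) {
  if (anyNA(gt)) return(MISSING_CALL)
  het <- gt[1] != gt[2]
  switch(seg_type,
    "nnxnp" = if (het) "np" else if (gt[1] == shared_allele) "nn" else MISSING_CALL,
    "lmxll" = if (het) "lm" else if (gt[1] == shared_allele) "ll" else MISSING_CALL,
    "hkxhk" = if (het) "hk" else if (gt[1] == 1L) "hh" else "kk",
    MISSING_CALL)
}

#' Progeny CP calls with the depth-coverage rule
#'
#' Calls each progeny only when its depth at the locus reaches `min_depth`
#' (otherwise missing), and retains the locus only when the fraction of
#' progeny at or above that depth exceeds `min_cover`.
#'
#' @param locus result of [call_locus_alleles()].
#' @param seg_type segregation type from [type_parental_segregation()].
#' @param progeny_ids character vector of progeny sample ids.
#' @param maternal maternal genotype (allele-index pair) for testcross
#'   orientation.
#' @param min_depth minimum per-progeny depth for a call (default 3).
#' @param min_cover minimum fraction of progeny with callable depth
#'   (default 0.90, strict).
#' @return List with `calls` (named CP codes incl. `"--"`), `covered`
#'   (fraction of progeny at depth) and `keep` (coverage rule verdict).
#' @export
genotype_progeny <- function(locus, seg_type, progeny_ids, maternal,
                             min_depth = 3, min_cover = 0.90) {
  shared <- if (seg_type %in% c("nnxnp", "lmxll")) maternal[1] else NULL
  if (seg_type == "nnxnp") shared <- maternal[1]
  depth <- setNames(rep(0, length(progeny_ids)), progeny_ids)
  have <- intersect(progeny_ids, names(locus$depth))
  depth[have] <- locus$depth[have]
  calls <- vapply(progeny_ids, function(s) {
    if (depth[[s]] < min_depth) return(MISSING_CALL)
    gt <- locus$genotypes[[s]]
    if (is.null(gt)) return(MISSING_CALL)
    cp_code_progeny(gt, seg_type, shared)
  }, character(1))
  covered <- mean(depth >= min_depth)
  list(calls = calls, covered = covered, keep = covered > min_cover)
}

#' Marker integrity (missingness) filter
#'
#' @param calls character vector of CP codes.
#' @param max_missing maximum tolerated missing fraction (default 0.10).
#' @return `TRUE` to keep the marker, `FALSE` to drop it.
#' @export
filter_integrity <- function(calls, max_missing = 0.10) {
  mean(calls == MISSING_CALL) <= max_missing
}

#' Segregation distortion filter
#'
#' Testcross markers (expected 1:1) are dropped when the major:minor class
#' ratio exceeds `max_ratio_1to1`; markers with an expected 3:1 ratio
#' (dominant-coded intercross) are dropped when the dominant:recessive
#' ratio exceeds `max_ratio_3to1`. Fully coded intercross markers are
#' checked under both dominant collapses. Markers with fewer than
#' `min_informative` non-missing calls are dropped as unratable.
#'
#' @param calls character vector of CP codes.
#' @param seg_type segregation type.
#' @param max_ratio_1to1 threshold for 1:1 markers (default 3).
#' @param max_ratio_3to1 threshold for 3:1-expected markers (default 10).
#' @param min_informative minimum non-missing calls (default 10).
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
filter_distortion <- function(calls, seg_type, max_ratio_1to1 = 3,
                              max_ratio_3to1 = 10, min_informative = 10) {
  obs <- calls[calls != MISSING_CALL]
  if (length(obs) < min_informative) return(FALSE)
  ratio <- function(x, y) if (y == 0) Inf else x / y
  if (seg_type %in% c("nnxnp", "lmxll")) {
    k <- table(factor(obs, levels = cp_codes(seg_type)))
    return(ratio(max(k), min(k)) <= max_ratio_1to1)
  }
  if (seg_type == "hkxhk") {
    k <- table(factor(obs, levels = c("hh", "hk", "kk")))
    dom1 <- ratio(k[["hh"]] + k[["hk"]], k[["kk"]])
    dom2 <- ratio(k[["kk"]] + k[["hk"]], k[["hh"]])
    return(dom1 <= max_ratio_3to1 && dom2 <= max_ratio_3to1)
  }
  FALSE
}

#' Call CP markers from tag clusters
#'
#' Drives the full marker-discovery stage over a cluster table: allele
#' calling, parental segregation typing, progeny genotyping with the depth
#' coverage rule, and the integrity and distortion filters. Every dropped
#' locus is logged with its first failing reason.
#'
#' @param clusters cluster read table from [build_clusters()]: columns
#'   `locus_id`, `scaffold`, `pos`, `strand`, `sample_id`, `tag`, `n`.
#' @param mother,father sample ids of the two parents.
#' @param progeny_ids character vector of progeny sample ids.
#' @param min_frac heterozygote minor-allele fraction (default 0.25).
#' @param min_depth minimum progeny depth per call (default 3).
#' @param min_cover minimum fraction of covered progeny (default 0.90).
#' @param max_missing integrity threshold (default 0.10).
#' @return List with `geno` (a [cp_geno] of retained markers) and `log`
#'   (data.table `locus_id`, `outcome`).
#' @export
call_markers <- function(clusters, mother, father, progeny_ids,
                         min_frac = 0.25, min_depth = 3, min_cover = 0.90,
                         max_missing = 0.10) {
  cl <- as.data.table(clusters)
  if (nrow(cl) == 0) return(list(geno = NULL, log = data.table()))
  loci <- unique(cl[, .(locus_id, scaffold, pos, strand)])
  dep <- cl[, .(depth = sum(n)), by = .(locus_id, sample_id)]
  par_ids <- c(mother, father)

  # allele discovery on the parental panel: per-sample fraction rule
  disc <- cl[sample_id %in% par_ids,
             .(n = sum(n)), by = .(locus_id, sample_id, tag)]
  disc <- merge(disc, dep, by = c("locus_id", "sample_id"))
  cand <- disc[, .(support = sum(n), maxfrac = max(n / depth)),
               by = .(locus_id, tag)]
  cand <- cand[support >= 2 & maxfrac >= min_frac]
  setorder(cand, locus_id, -support, tag)
  cand[, rank := seq_len(.N), by = locus_id]
  n_alleles <- cand[, .(n_all = .N), by = locus_id]
  outcome <- merge(loci[, .(locus_id)], n_alleles, by = "locus_id", all.x = TRUE)
  outcome[is.na(n_all), n_all := 0]
  outcome[, verdict := fifelse(n_all == 2, "",
                        fifelse(n_all == 1, "monomorphic", "allele_count"))]

  # per (locus, sample) genotypes against the two alleles
  live <- outcome[verdict == ""]$locus_id
  alleles <- cand[rank <= 2 & locus_id %in% live]
  ac <- merge(cl[, .(n = sum(n)), by = .(locus_id, sample_id, tag)],
              alleles[, .(locus_id, tag, rank)], by = c("locus_id", "tag"))
  acw <- dcast(ac, locus_id + sample_id ~ rank, value.var = "n", fill = 0)
  if (!"1" %in% names(acw)) acw[, "1" := 0]
  if (!"2" %in% names(acw)) acw[, "2" := 0]
  setnames(acw, c("1", "2"), c("a1", "a2"))
  gt <- merge(dep[locus_id %in% live], acw,
              by = c("locus_id", "sample_id"), all.x = TRUE)
  gt[is.na(a1), a1 := 0]; gt[is.na(a2), a2 := 0]
  # fractions over allele-classified reads (reads carrying a sequencing
  # error anywhere in the tag match neither allele and are uninformative)
  # 0 = uncallable, 1 = hom allele1, 2 = het, 3 = hom allele2
  gt[, asum := a1 + a2]
  gt[, code := 0L]
  gt[asum > 0 & a1 / asum >= min_frac & a2 / asum >= min_frac, code := 2L]
  gt[code == 0L & asum > 0 & a1 >= a2 & a1 / asum >= min_frac, code := 1L]
  gt[code == 0L & asum > 0 & a2 > a1 & a2 / asum >= min_frac, code := 3L]

  # parental segregation type
  pg <- dcast(gt[sample_id %in% par_ids], locus_id ~ sample_id,
              value.var = "code", fill = 0)
  for (id in par_ids) if (!id %in% names(pg)) pg[, (id) := 0L]
  setnames(pg, par_ids, c("m_code", "f_code"))
  pg[, seg_type := "uninformative"]
  pg[f_code == 2L & m_code %in% c(1L, 3L), seg_type := "nnxnp"]
  pg[m_code == 2L & f_code %in% c(1L, 3L), seg_type := "lmxll"]
  pg[m_code == 2L & f_code == 2L, seg_type := "hkxhk"]
  outcome <- merge(outcome, pg[, .(locus_id, seg_type, m_code, f_code)],
                   by = "locus_id", all.x = TRUE)
  outcome[verdict == "" & (is.na(seg_type) | seg_type == "uninformative"),
          verdict := "uninformative"]

  # progeny CP calls over the full loci x progeny grid; a progeny
  # homozygous for the allele the homozygous parent does NOT carry is
  # inconsistent with the cross and left missing
  live <- outcome[verdict == ""]
  out <- CJ(locus_id = live$locus_id, sample_id = progeny_ids)
  out <- merge(out, gt[, .(locus_id, sample_id, depth, code)],
               by = c("locus_id", "sample_id"), all.x = TRUE)
  out[is.na(depth), depth := 0]
  out[is.na(code), code := 0L]
  out <- merge(out, live[, .(locus_id, seg_type, m_code, f_code)],
               by = "locus_id")
  out[, call := MISSING_CALL]
  out[, ok := depth >= min_depth & code > 0L]
  out[ok & seg_type == "nnxnp" & code == 2L, call := "np"]
  out[ok & seg_type == "nnxnp" & code == m_code, call := "nn"]
  out[ok & seg_type == "lmxll" & code == 2L, call := "lm"]
  out[ok & seg_type == "lmxll" & code == f_code, call := "ll"]
  out[ok & seg_type == "hkxhk" & code == 1L, call := "hh"]
  out[ok & seg_type == "hkxhk" & code == 2L, call := "hk"]
  out[ok & seg_type == "hkxhk" & code == 3L, call := "kk"]

  # coverage, integrity, distortion per locus
  stats <- out[, .(
    covered = mean(depth >= min_depth),
    missing = mean(call == MISSING_CALL)), by = locus_id]
  tall <- out[call != MISSING_CALL, .N, by = .(locus_id, call)]
  tallw <- dcast(tall, locus_id ~ call, value.var = "N", fill = 0)
  for (cc in c("nn", "np", "ll", "lm", "hh", "hk", "kk"))
    if (!cc %in% names(tallw)) tallw[, (cc) := 0L]
  stats <- merge(stats, tallw, by = "locus_id", all.x = TRUE)
  stats <- merge(stats, live[, .(locus_id, seg_type)], by = "locus_id")
  stats[, n_obs := nn + np + ll + lm + hh + hk + kk]
  ratio <- function(x, y) fifelse(y == 0, Inf, x / y)
  stats[, distorted := FALSE]
  stats[seg_type == "nnxnp",
        distorted := ratio(pmax(nn, np), pmin(nn, np)) > 3]
  stats[seg_type == "lmxll",
        distorted := ratio(pmax(ll, lm), pmin(ll, lm)) > 3]
  stats[seg_type == "hkxhk",
        distorted := ratio(hh + hk, kk) > 10 | ratio(kk + hk, hh) > 10]
  stats[, fail := fifelse(covered <= min_cover, "low_coverage",
                   fifelse(missing > max_missing, "integrity",
                    fifelse(n_obs < 10 | distorted, "distortion", "")))]
  outcome <- merge(outcome, stats[, .(locus_id, fail)], by = "locus_id",
                   all.x = TRUE)
  outcome[verdict == "" & !is.na(fail) & fail != "", verdict := fail]
  outcome[verdict == "", verdict := "retained"]
  log <- outcome[, .(locus_id, outcome = verdict)]

  keep <- outcome[verdict == "retained"]$locus_id
  if (length(keep) == 0) return(list(geno = NULL, log = log))
  callw <- dcast(out[locus_id %in% keep], locus_id ~ sample_id,
                 value.var = "call")
  calls <- as.matrix(callw, rownames = "locus_id")[, progeny_ids, drop = FALSE]
  info <- merge(data.table(marker = keep), loci, by.x = "marker",
                by.y = "locus_id", sort = FALSE)
  info <- merge(info, live[, .(marker = locus_id, seg_type)], by = "marker",
                sort = FALSE)
  info[, source := "radseq"]
  setorder(info, scaffold, pos, strand)
  calls <- calls[info$marker, , drop = FALSE]
  list(geno = cp_geno(calls, info), log = log)
}
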