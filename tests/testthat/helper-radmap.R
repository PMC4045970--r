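## Shared fixtures and independent oracles for the test suite.

BASES <- c("A", "C", "G", "T")

rand_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## Build a cp_geno from named character vectors of CP calls.
make_geno <- function(..., seg_type = "nnxnp", scaffold = NULL, pos = NULL) {
  rows <- list(...)
  calls <- do.call(rbind, rows)
  rownames(calls) <- names(rows)
  colnames(calls) <- sprintf("F1_%02d", seq_len(ncol(calls)))
  n <- nrow(calls)
  info <- data.frame(marker = names(rows),
                     seg_type = rep(seg_type, length.out = n),
                     scaffold = scaffold %||% rep("scf1", n),
                     pos = pos %||% seq_len(n))
  cp_geno(calls, info)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## A sequence whose double digest yields exactly one enzyme1-enzyme2
## fragment of the requested length.
fragment_seq <- function(flen, pad = 30) {
  stopifnot(flen >= 3)
  paste0(strrep("G", pad), "ATGCA", "T", strrep("C", flen - 2), "TTAA",
         strrep("G", pad))
}

## Independent brute-force aligner: enumerates every anchor on every
## strand and scores the ungapped alignment plus every single indel event
## of 1..max_indel bases at every split, under the mismatch budget.
## Returns merged hits (within 3 bp per sequence/strand) like the package
## aligner reports loci.
brute_align <- function(ref_seqs, tag, max_mm = 2, max_indel = 2) {
  hits <- list()
  L <- nchar(tag)
  for (si in seq_along(ref_seqs)) {
    rv <- utf8ToInt(ref_seqs[[si]])
    n <- length(rv)
    for (strand in c("+", "-")) {
      tv <- utf8ToInt(if (strand == "+") tag else rc(tag))
      base_at <- function(q) {          # 0-based; out of range never matches
        out <- rep(-1L, length(q))
        okq <- q >= 0 & q < n
        out[okq] <- rv[q[okq] + 1]
        out
      }
      for (s in (-max_indel):(n - L + max_indel)) {
        m0 <- tv != base_at(s + 0:(L - 1))
        best_mm <- sum(m0); best_gap <- 0
        best_score <- if (best_mm <= max_mm) best_mm else Inf
        pre <- cumsum(c(0, m0))
        for (g in seq_len(max_indel)) {
          mg <- tv != base_at(s + g + 0:(L - 1))
          sufg <- rev(cumsum(rev(c(mg, 0))))
          del_mm <- min(pre + sufg)
          if (del_mm <= max_mm && del_mm + 2 * g < best_score) {
            best_score <- del_mm + 2 * g; best_mm <- del_mm; best_gap <- g
          }
          mneg <- tv != base_at(s - g + 0:(L - 1))
          sufneg <- rev(cumsum(rev(c(mneg, 0))))
          p <- 0:(L - g)
          ins_mm <- min(pre[p + 1] + sufneg[p + g + 1])
          if (ins_mm <= max_mm && ins_mm + 2 * g < best_score) {
            best_score <- ins_mm + 2 * g; best_mm <- ins_mm; best_gap <- g
          }
        }
        if (is.finite(best_score)) {
          hits[[length(hits) + 1]] <-
            data.frame(si = si, pos = s, strand = strand, mm = best_mm,
                       gap = best_gap, score = best_score)
        }
      }
    }
  }
  if (length(hits) == 0) return(data.frame())
  h <- do.call(rbind, hits)
  h <- h[order(h$si, h$strand, h$pos), ]
  merged <- h[0, ]
  for (i in seq_len(nrow(h))) {
    j <- nrow(merged)
    if (j > 0 && merged$si[j] == h$si[i] && merged$strand[j] == h$strand[i] &&
        h$pos[i] - merged$pos[j] <= 3) {
      if (h$score[i] < merged$score[j]) merged[j, ] <- h[i, ]
    } else {
      merged <- rbind(merged, h[i, ])
    }
  }
  merged
}

## Independent two-point likelihood for the grid-search oracle: explicit
## enumeration of parental two-locus gametes (fresh implementation, no
## shared code with the package estimator).
oracle_loglik <- function(calls_a, calls_b, type_a, type_b, r,
                          phase_f = "c", phase_m = "c") {
  het <- function(ty, who) {
    switch(ty, nnxnp = who == "f", lmxll = who == "m", hkxhk = TRUE)
  }
  gam <- function(is_het2, phase) {
    # P(g1, g2) over 0/1 alleles at the two loci for one parent
    if (is_het2) {
      ps <- if (phase == "c") (1 - r) / 2 else r / 2
      pd <- if (phase == "c") r / 2 else (1 - r) / 2
      matrix(c(ps, pd, pd, ps), 2, 2)
    } else matrix(0.25, 2, 2)
  }
  gf <- gam(het(type_a, "f") && het(type_b, "f"), phase_f)
  gm <- gam(het(type_a, "m") && het(type_b, "m"), phase_m)
  lab <- function(ty, f, m) {
    switch(ty, nnxnp = c("nn", "np")[f + 1], lmxll = c("ll", "lm")[m + 1],
           hkxhk = c("hh", "hk", "kk")[f + m + 1])
  }
  probs <- new.env()
  for (fa in 0:1) for (fb in 0:1) for (ma in 0:1) for (mb in 0:1) {
    k <- paste(lab(type_a, fa, ma), lab(type_b, fb, mb))
    old <- mget(k, probs, ifnotfound = 0)[[1]]
    assign(k, old + gf[fa + 1, fb + 1] * gm[ma + 1, mb + 1], probs)
  }
  ok <- calls_a != "--" & calls_b != "--"
  keys <- paste(calls_a[ok], calls_b[ok])
  sum(log(vapply(keys, function(k) mget(k, probs, ifnotfound = 1e-300)[[1]],
                 numeric(1))))
}

oracle_grid_r <- function(calls_a, calls_b, type_a, type_b,
                          grid = seq(0.001, 0.5, by = 0.001)) {
  best <- c(r = 0.5, ll = -Inf)
  # phases without effect (parent not doubly heterozygous) collapse to the
  # same likelihood, so enumerating all four is always safe
  for (pf in c("c", "r")) for (pm in c("c", "r")) {
    ll <- vapply(grid, function(r)
      oracle_loglik(calls_a, calls_b, type_a, type_b, r, pf, pm), numeric(1))
    i <- which.max(ll)
    if (ll[i] > best["ll"]) best <- c(r = grid[i], ll = ll[i])
  }
  best[["r"]]
}

## Simulated testcross pair with a given recombination fraction.
sim_tc_pair <- function(n, r, miss = 0) {
  a <- sample(c("nn", "np"), n, replace = TRUE)
  flip <- runif(n) < r
  b <- ifelse(flip, ifelse(a == "nn", "np", "nn"), a)
  if (miss > 0) {
    a[runif(n) < miss] <- "--"
    b[runif(n) < miss] <- "--"
  }
  list(a = a, b = b)
}
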