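## F1 cross simulation: gamete crossover sampling at the sequence level,
## truth genotype bookkeeping, and a marker-level generator for map
## parameter-recovery studies.

#' Simulate F1 gametes
#'
#' Crossovers are drawn as a Poisson process along each scaffold with no
#' interference: the expected number per gamete is
#' `length_Mb * cm_per_mb / 100`. Each progeny receives one independent
#' maternal and one paternal gamete; a gamete is a start haplotype plus a
#' strictly increasing list of breakpoints in reference coordinates. Under
#' this process the recombinant fraction between two truth positions `d`
#' cM apart is the Haldane value `(1 - exp(-2d/100)) / 2`.
#'
#' @param genome an `annotated_genome`.
#' @param parents a `parent_pair` (carried along for truth genotyping).
#' @param cm_per_mb genetic-to-physical calibration (default 0.9 cM/Mb,
#'   i.e. roughly 1.1 Mb per cM).
#' @param n_progeny number of F1 individuals (default 51; must be >= 2).
#' @param seed integer seed.
#' @return Object of class `progeny_set`: list with `n`, `cm_per_mb` and
#'   `gametes` (nested: progeny, parent, scaffold -> `start`, `breaks`).
#' @export
simulate_f1 <- function(genome, parents, cm_per_mb = 0.9, n_progeny = 51,
                        seed = 1) {
  if (n_progeny < 2) stop_radmap("n_progeny must be >= 2")
  set.seed(child_seed(seed, "f1"))
  gametes <- lapply(seq_len(n_progeny), function(i) {
    lapply(c(maternal = "maternal", paternal = "paternal"), function(par) {
      lapply(genome$lengths, function(L) {
        lambda <- (L / 1e6) * cm_per_mb / 100
        k <- rpois(1, lambda)
        list(start = sample(1:2, 1),
             breaks = sort(runif(k, 0, L)))
      })
    })
  })
  structure(list(n = n_progeny, cm_per_mb = cm_per_mb, gametes = gametes,
                 seed = seed), class = "progeny_set")
}

#' Haplotype transmitted at a position
#'
#' @param gamete one scaffold entry of a `progeny_set` gamete
#'   (`list(start, breaks)`).
#' @param pos positions (reference coordinates); vectorized.
#' @return Integer vector of haplotype indices (1 or 2).
#' @export
gamete_hap_at <- function(gamete, pos) {
  1L + (gamete$start - 1L + findInterval(pos, gamete$breaks)) %% 2L
}

#' Truth genotypes at parental heterozygous sites
#'
#' For every variant of the chosen parent, records whether each progeny
#' inherited the variant-bearing haplotype (haplotype 2).
#'
#' @param progeny a `progeny_set`.
#' @param parents a `parent_pair`.
#' @param parent `"maternal"` or `"paternal"`.
#' @return Logical matrix, sites x progeny; rownames are
#'   `scaffold:pos` keys.
#' @export
truth_genotypes <- function(progeny, parents, parent = c("paternal", "maternal")) {
  parent <- match.arg(parent)
  sel <- parents$variants$parent == parent  # outside dt scope ('parent' is a column)
  v <- parents$variants[sel]
  out <- matrix(FALSE, nrow(v), progeny$n,
                dimnames = list(sprintf("%s:%d", v$scaffold, v$pos),
                                sprintf("F1_%02d", seq_len(progeny$n))))
  for (i in seq_len(progeny$n)) {
    gm <- progeny$gametes[[i]][[parent]]
    for (sc in unique(v$scaffold)) {
      idx <- which(v$scaffold == sc)
      out[idx, i] <- gamete_hap_at(gm[[sc]], v$pos[idx]) == 2L
    }
  }
  out
}

#' Evenly spaced truth map for marker-level simulations
#'
#' @param n_lg number of linkage groups (default 5).
#' @param markers_per_lg markers per group (default 40).
#' @param lg_cm genetic length of each group in cM (default 100).
#' @return data.table `lg`, `marker`, `cm`.
#' @export
sim_truth_map <- function(n_lg = 5, markers_per_lg = 40, lg_cm = 100) {
  rbindlist(lapply(seq_len(n_lg), function(g) {
    data.table(lg = g,
               marker = sprintf("m%02d_%03d", g, seq_len(markers_per_lg)),
               cm = seq(0, lg_cm, length.out = markers_per_lg))
  }))
}

#' Simulate testcross genotypes directly from a truth map
#'
#' Marker-level counterpart of the sequence simulator for parameter
#' recovery studies: genotypes along each linkage group follow a Markov
#' chain whose adjacent-marker recombination fractions are the Haldane
#' transform of the truth distances (Poisson crossovers, no interference).
#'
#' @param truth_map data.table from [sim_truth_map()] (`lg`, `marker`, `cm`).
#' @param n_progeny progeny count (default 51).
#' @param seg_type segregation type of all markers (default `"nnxnp"`).
#' @param missing_rate independent per-call missing probability (default 0.05).
#' @param seed integer seed.
#' @return A [cp_geno]; marker `info` carries `truth_lg` and `truth_cm`.
#' @export
sim_f1_genotypes <- function(truth_map, n_progeny = 51, seg_type = "nnxnp",
                             missing_rate = 0.05, seed = 1) {
  set.seed(child_seed(seed, "markersim"))
  truth_map <- as.data.table(truth_map)
  codes <- cp_codes(seg_type)
  calls_list <- list()
  for (g in unique(truth_map$lg)) {
    sub <- truth_map[lg == g]
    m <- nrow(sub)
    r_adj <- haldane_r(diff(sub$cm))
    alle <- matrix(0L, m, n_progeny)
    alle[1, ] <- rbinom(n_progeny, 1, 0.5)
    for (i in seq_len(m - 1)) {
      switch_ <- rbinom(n_progeny, 1, r_adj[i])
      alle[i + 1, ] <- (alle[i, ] + switch_) %% 2L
    }
    calls <- matrix(codes[alle + 1L], m, n_progeny)
    rownames(calls) <- sub$marker
    calls_list[[as.character(g)]] <- calls
  }
  calls <- do.call(rbind, calls_list)
  if (missing_rate > 0) {
    mask <- matrix(runif(length(calls)) < missing_rate, nrow(calls))
    calls[mask] <- MISSING_CALL
  }
  colnames(calls) <- sprintf("F1_%02d", seq_len(n_progeny))
  info <- data.table(marker = truth_map$marker, seg_type = seg_type,
                     scaffold = sprintf("chr%d", truth_map$lg),
                     pos = truth_map$cm * 1e4, truth_lg = truth_map$lg,
                     truth_cm = truth_map$cm)
  cp_geno(calls, info)
}
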