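test_that("simulated genomes hit the requested repeat fraction", {
  g <- simulate_genome(c(a = 1000000L), repeat_fraction = 0.57, seed = 3)
  share <- sum(g$repeats$end - g$repeats$start) / 1e6
  expect_lt(abs(share - 0.57), 0.05)
  # intervals in bounds and non-overlapping after sorting
  iv <- g$repeats[order(g$repeats$start)]
  expect_true(all(iv$start >= 0 & iv$end <= 1e6))
  expect_true(all(iv$start[-1] >= iv$end[-nrow(iv)]))
  # no repeat families -> no repeat intervals
  g0 <- simulate_genome(c(50000L), repeat_fraction = 0, seed = 1)
  expect_equal(nrow(g0$repeats), 0)
  # deterministic under a fixed seed
  g2 <- simulate_genome(c(a = 1000000L), repeat_fraction = 0.57, seed = 3)
  expect_identical(g$seqs, g2$seqs)
  expect_identical(g$repeats, g2$repeats)
  # excessive repeat content is rejected
  expect_error(simulate_genome(c(100000L), repeat_fraction = 0.97),
               "95%")
})

test_that("parental heterozygous site counts follow the requested rate", {
  g <- simulate_genome(c(1000000L), repeat_fraction = 0.3, seed = 5)
  p <- simulate_parents(g, het_rate_maternal = 3e-4,
                        het_rate_paternal = 3.7e-3, conv_frac = 0, seed = 5)
  v <- p$variants
  n_pat <- sum(v$parent == "paternal")
  # binomial 99% interval around 3700 expected sites
  ci <- qbinom(c(0.005, 0.995), 1e6, 3.7e-3)
  expect_gte(n_pat, ci[1])
  expect_lte(n_pat, ci[2])
  # zero rate leaves the haplotypes identical to the reference
  p0 <- simulate_parents(g, 0, 0, conv_frac = 0, seed = 1)
  expect_equal(nrow(p0$variants), 0)
  h <- build_haplotype(g, p0, "maternal", 2)
  expect_identical(h$seqs, g$seqs)
  expect_error(simulate_parents(g, 0.2, 0.2), "0.05")
})

test_that("realized site counts are binomial across seeds", {
  g <- simulate_genome(c(200000L), repeat_fraction = 0.3, seed = 2)
  rate <- 3.7e-3
  counts <- vapply(1:20, function(s)
    sum(simulate_parents(g, 0, rate, conv_frac = 0,
                         seed = s)$variants$parent == "paternal"), numeric(1))
  # chi-square goodness of fit against Binomial(L, rate): the sum of
  # squared standardized counts is ~ chi-square with 20 df
  mu <- 2e5 * rate; sd <- sqrt(2e5 * rate * (1 - rate))
  x2 <- sum(((counts - mu) / sd)^2)
  expect_gt(x2, qchisq(0.005, 20))
  expect_lt(x2, qchisq(0.995, 20))
})

test_that("haplotype variants land where recorded", {
  g <- simulate_genome(c(100000L), repeat_fraction = 0.2, seed = 7)
  p <- simulate_parents(g, 1e-3, 3e-3, conv_frac = 0, seed = 7)
  h <- build_haplotype(g, p, "paternal", 2)
  v <- p$variants[p$variants$parent == "paternal" & p$variants$type == "snp"]
  ind <- p$variants[p$variants$parent == "paternal" & p$variants$type == "indel"]
  before <- if (nrow(ind)) min(ind$pos) else nchar(g$seqs[[1]])
  v <- v[v$pos < before]  # positions before the first indel shift
  got <- substring(h$seqs[[1]], v$pos + 1, v$pos + 1)
  expect_identical(got, v$alt)
})

test_that("crossovers are Poisson with the requested genetic density", {
  g <- structure(list(seqs = c(s = ""), lengths = c(s = 1e8)),
                 class = "annotated_genome")
  p <- structure(list(variants = data.table::data.table(
    parent = character(), scaffold = character(), pos = numeric(),
    ref = character(), alt = character(), type = character(),
    origin = character())), class = "parent_pair")
  pr <- simulate_f1(g, p, cm_per_mb = 1, n_progeny = 500, seed = 9)
  # 100 Mb at 1 cM/Mb -> mean 1 crossover per gamete
  k <- vapply(pr$gametes, function(x)
    length(x$maternal$s$breaks), numeric(1))
  expect_lt(abs(mean(k) - 1), 3 * sqrt(1 / 500))
  # zero genetic length -> no recombination anywhere
  pr0 <- simulate_f1(g, p, cm_per_mb = 0, n_progeny = 5, seed = 1)
  expect_true(all(vapply(pr0$gametes, function(x)
    length(x$maternal$s$breaks) == 0, logical(1))))
  expect_error(simulate_f1(g, p, n_progeny = 1), ">= 2")
})

test_that("recombinant fraction at 10 cM matches the no-interference value", {
  g <- structure(list(seqs = c(s = ""), lengths = c(s = 2e7)),
                 class = "annotated_genome")
  p <- structure(list(variants = data.table::data.table(
    parent = character(), scaffold = character(), pos = numeric(),
    ref = character(), alt = character(), type = character(),
    origin = character())), class = "parent_pair")
  pr <- simulate_f1(g, p, cm_per_mb = 1, n_progeny = 5000, seed = 17)
  # two positions 10 cM apart (10 Mb at 1 cM/Mb)
  rec <- vapply(pr$gametes, function(x) {
    gm <- x$paternal$s
    gamete_hap_at(gm, 5e6) != gamete_hap_at(gm, 1.5e7)
  }, logical(1))
  expected <- 0.5 * (1 - exp(-0.2))  # 0.0906
  se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(mean(rec) - expected), 3 * se)
})

test_that("double digest retains only size-selected two-enzyme fragments", {
  expect_equal(nrow(digest_ddrad(strrep("C", 2000))), 0)
  for (flen in c(200, 300, 500)) {
    fr <- digest_ddrad(fragment_seq(flen))
    expect_equal(nrow(fr), 1)
    expect_equal(fr$length, flen)
    expect_setequal(c(fr$e5, fr$e3), c("e1", "e2"))
  }
  expect_equal(nrow(digest_ddrad(fragment_seq(199))), 0)
  expect_equal(nrow(digest_ddrad(fragment_seq(501))), 0)
  # retained fragments contain no internal cut site: re-digestion finds
  # nothing further to cut (the substance of digest idempotence)
  fr <- digest_ddrad(fragment_seq(300))
  s <- fragment_seq(300)
  inner <- substr(s, fr$start + 1, fr$end)
  redo <- digest_ddrad(inner, keep_all = TRUE)
  expect_equal(nrow(redo), 1)                 # a single uncut piece
  expect_equal(redo$e5, "end")
  expect_equal(redo$e3, "end")
})

test_that("reads carry the barcode then the fragment prefix", {
  set.seed(3)
  frag <- rand_seq(300)
  rd <- generate_reads(frag, "ACGT", 1, error_rate = 0, read_len = 100)
  expect_equal(nrow(rd), 1)
  expect_equal(rd$seq, paste0("ACGT", substr(frag, 1, 96)))
  expect_equal(nchar(rd$qual), 100)
  expect_error(generate_reads(frag, "ACG", 1), "4-8")
  expect_error(generate_reads(frag, "ACGTACGTA", 1), "4-8")
  # zero depth -> no reads
  expect_equal(nrow(generate_reads(frag, "ACGT", 0)), 0)
})

test_that("parent samples are sequenced about twice as deep as progeny", {
  g <- simulate_genome(c(300000L), repeat_fraction = 0.2, seed = 11)
  p <- simulate_parents(g, 3e-4, 3.7e-3, conv_frac = 0, seed = 11)
  pr <- simulate_f1(g, p, n_progeny = 10, seed = 11)
  sim <- sim_radseq_experiment(g, p, pr, mean_depth = 10, seed = 11)
  counts <- table(sim$reads$sample_truth)
  par_mean <- mean(counts[c("P_mother", "P_father")])
  prog_mean <- mean(counts[grep("^F1", names(counts))])
  expect_gt(par_mean / prog_mean, 1.6)
  expect_lt(par_mean / prog_mean, 2.4)
})

test_that("error-free reads from a repeat-free genome align back uniquely", {
  g <- simulate_genome(c(200000L), repeat_fraction = 0, seed = 13)
  p <- simulate_parents(g, 0, 0, conv_frac = 0, seed = 13)
  pr <- simulate_f1(g, p, n_progeny = 3, seed = 13)
  sim <- sim_radseq_experiment(g, p, pr, mean_depth = 4, error_rate = 0,
                               seed = 13)
  idx <- build_reference_index(g, "unmasked")
  prc <- process_reads(sim$reads, sim$samples[, c("sample_id", "barcode")])
  utags <- unique(prc$tags$tag)
  res <- align_tags(idx, utags)
  expect_true(all(res$status == "unique"))
  expect_equal(res$mm, rep(0L, length(utags)))
})
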