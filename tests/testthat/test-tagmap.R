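test_that("reference index modes expose the right searchable bases", {
  g <- simulate_genome(c(100000L, 100000L), repeat_fraction = 0.4,
                       gene_density = 0.05, seed = 29)
  un <- build_reference_index(g, "unmasked")
  expect_equal(un$indexed_bases, 200000)
  ma <- build_reference_index(g, "masked")
  expect_equal(ma$indexed_bases,
               200000 - sum(g$repeats$end - g$repeats$start))
  gm <- build_reference_index(g, "genemodels")
  expect_equal(gm$indexed_bases, sum(g$genes$end - g$genes$start))
  expect_lt(abs(gm$indexed_bases / 200000 - 0.05), 0.02)
  # gene-model mode requires gene intervals
  g0 <- simulate_genome(c(50000L), repeat_fraction = 0, gene_density = 0,
                        seed = 1)
  expect_error(build_reference_index(g0, "genemodels"), "gene interval")
})

test_that("alignment status reflects uniqueness and the edit budget", {
  set.seed(31)
  ref <- rand_seq(6000)
  idx <- build_reference_index(setNames(ref, "s1"), "unmasked")
  tag <- substr(ref, 1001, 1092)
  r <- align_tags(idx, tag)
  expect_equal(r$status, "unique")
  expect_equal(r$pos, 1000)
  expect_equal(r$mm, 0L)
  # reverse strand
  r2 <- align_tags(idx, rc(tag))
  expect_equal(r2$strand, "-")
  expect_equal(r2$pos, 1000)
  # three mismatches exceed the budget
  t3 <- tag
  for (p in c(10, 45, 80))
    substr(t3, p, p) <- setdiff(BASES, substr(tag, p, p))[1]
  expect_equal(align_tags(idx, t3)$status, "unaligned")
  # 1-2 bp indels are within budget, exactly one indel event allowed
  tdel <- paste0(substr(ref, 1001, 1040), substr(ref, 1043, 1094))
  rdel <- align_tags(idx, tdel)
  expect_equal(rdel$status, "unique")
  expect_equal(rdel$indel, 2L)
  expect_error(align_tags(idx, "ACGT"), "exactly 92")
})

test_that("repeat copies are ambiguous unmasked and resolvable masked", {
  set.seed(37)
  unit <- rand_seq(400)
  bg1 <- rand_seq(3000); bg2 <- rand_seq(3000); bg3 <- rand_seq(1000)
  seqs <- c(s1 = paste0(bg1, unit, bg3), s2 = paste0(bg2, unit))
  g <- structure(list(
    seqs = seqs, lengths = nchar(seqs),
    repeats = data.table::data.table(
      scaffold = "s2", start = 3000, end = 3400, family = 1L, copy_id = 1L),
    genes = data.table::data.table(scaffold = character(), start = numeric(),
                                   end = numeric())),
    class = "annotated_genome")
  tag <- substr(unit, 101, 192)
  un <- build_reference_index(g, "unmasked")
  expect_equal(align_tags(un, tag)$status, "ambiguous")
  ma <- build_reference_index(g, "masked")  # the s2 copy is masked away
  rm_ <- align_tags(ma, tag)
  expect_equal(rm_$status, "unique")
  expect_equal(rm_$scaffold, "s1")
  expect_equal(rm_$pos, 3100)
})

test_that("aligner agrees with the brute-force scan over all offsets", {
  set.seed(41)
  refs <- c(s1 = rand_seq(2500), s2 = rand_seq(1500))
  idx <- build_reference_index(refs, "unmasked")
  mutate_tag <- function(window, n_mm = 0, indel = 0) {
    # window: 94 reference bases; returns a 92 bp tag
    tag <- if (indel == 0) substr(window, 1, 92)
    else if (runif(1) < 0.5) {           # deletion in tag (ref longer)
      cut <- sample(20:70, 1)
      substr(paste0(substr(window, 1, cut),
                    substr(window, cut + 1 + indel, 94)), 1, 92)
    } else {                             # insertion in tag
      cut <- sample(20:70, 1)
      substr(paste0(substr(window, 1, cut), rand_seq(indel),
                    substr(window, cut + 1, 92)), 1, 92)
    }
    if (n_mm > 0)
      for (p in sample(10:85, n_mm))
        substr(tag, p, p) <- setdiff(BASES, substr(tag, p, p))[1]
    tag
  }
  tags <- character(0)
  for (i in 1:30) {
    si <- sample(1:2, 1)
    s <- sample(nchar(refs[si]) - 94, 1)
    window <- substr(refs[[si]], s + 1, s + 94)
    tag <- mutate_tag(window, n_mm = sample(0:2, 1),
                      indel = sample(0:2, 1) * (runif(1) < 0.4))
    if (runif(1) < 0.3) tag <- rc(tag)
    tags <- c(tags, tag)
  }
  tags <- c(tags, vapply(1:10, function(i) rand_seq(92), character(1)))
  got <- radmap:::radmap_align_hits(idx$handle, tags)
  for (i in seq_along(tags)) {
    want <- brute_align(refs, tags[i])
    have <- got[got$tag_idx == i, ]
    expect_equal(nrow(have), nrow(want), label = sprintf("tag %d hit count", i))
    if (nrow(want) > 0) {
      o_w <- order(want$si, want$strand, want$pos)
      o_h <- order(have$seq_idx, have$strand, have$pos)
      expect_equal(have$seq_idx[o_h], want$si[o_w])
      expect_equal(have$strand[o_h], want$strand[o_w])
      expect_true(all(abs(have$pos[o_h] - want$pos[o_w]) <= 3))
      expect_equal(have$mm[o_h] + 2 * have$indel[o_h],
                   want$score[o_w], label = sprintf("tag %d scores", i))
    }
  }
})

test_that("masked-index alignments are unmasked alignments at unmasked loci", {
  g <- simulate_genome(c(150000L), repeat_fraction = 0.4, seed = 43)
  p <- simulate_parents(g, 3e-4, 3.7e-3, seed = 43)
  pr <- simulate_f1(g, p, n_progeny = 4, seed = 43)
  sim <- sim_radseq_experiment(g, p, pr, mean_depth = 5, seed = 43)
  prc <- process_reads(sim$reads, sim$samples[, c("sample_id", "barcode")])
  utags <- unique(prc$tags$tag)[1:min(400, data.table::uniqueN(prc$tags$tag))]
  un <- align_tags(build_reference_index(g, "unmasked"), utags)
  ma <- align_tags(build_reference_index(g, "masked"), utags)
  both <- ma$status == "unique"
  # every unique masked hit coincides with the unmasked hit at that locus
  agree <- un$status[both] == "unique" &
    un$pos[both] == ma$pos[both] & un$scaffold[both] == ma$scaffold[both]
  expect_true(all(agree | un$status[both] == "ambiguous"))
})

test_that("cluster depth window bounds are inclusive on the parental panel", {
  mk_aln <- function(n_parent) data.table::data.table(
    status = "unique", scaffold = "s1", pos = 100L, strand = "+",
    sample_id = c(rep("P_mother", n_parent), "F1_01"),
    tag = "X")
  for (k in c(3, 4, 200, 201)) {
    cl <- build_clusters(mk_aln(k), c("P_mother", "P_father"))
    if (k %in% c(4, 200)) {
      expect_equal(nrow(cl$clusters) > 0, TRUE, label = sprintf("depth %d", k))
    } else {
      expect_equal(nrow(cl$clusters), 0, label = sprintf("depth %d", k))
    }
  }
  # empty alignments
  empty <- build_clusters(data.table::data.table(status = character()),
                          "P_mother")
  expect_equal(nrow(empty$clusters), 0)
})

test_that("cluster read totals preserve unique alignment counts", {
  set.seed(47)
  aln <- data.table::data.table(
    status = sample(c("unique", "ambiguous"), 500, replace = TRUE,
                    prob = c(0.8, 0.2)),
    scaffold = "s1",
    pos = sample(c(10L, 50L, 90L), 500, replace = TRUE),
    strand = "+",
    sample_id = sample(c("P_mother", "P_father", "F1_01"), 500, TRUE),
    tag = sample(c("A", "B"), 500, TRUE))
  cl <- build_clusters(aln, c("P_mother", "P_father"), min_depth = 1,
                       max_depth = 1e6)
  expect_equal(sum(cl$clusters$n), sum(aln$status == "unique"))
})
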