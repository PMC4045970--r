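mk_anchor_fixture <- function() {
  mi <- data.frame(
    marker = sprintf("m%02d", 1:16),
    scaffold = c(rep("sA", 6), rep("sB", 5), rep("sC", 4), "sD"),
    pos = c(seq(10000, 60000, length.out = 6),
            seq(90000, 10000, length.out = 5),
            rep(5000, 4), 100))
  tab <- data.table::data.table(
    lg = c(rep(1, 6), rep(1, 5), rep(2, 3), 1, 2),
    marker = mi$marker,
    cm = c(1:6, 10:14, rep(3, 3), 50, 9))
  list(mi = mi, tab = tab,
       lens = c(sA = 100000, sB = 120000, sC = 50000, sD = 2000, sE = 500))
}

test_that("scaffolds are assigned to their modal linkage group", {
  fx <- mk_anchor_fixture()
  asg <- assign_scaffolds(fx$tab, fx$mi)
  a <- asg$anchors
  expect_equal(a[a$scaffold == "sA"]$lg, 1)
  expect_equal(a[a$scaffold == "sC"]$lg, 2)          # 3 of 4 markers on LG2
  expect_equal(a[a$scaffold == "sC"]$n_conflict, 1)  # the LG1 minority marker
  # mean cM uses modal-group markers only
  expect_equal(a[a$scaffold == "sC"]$mean_cm, 3)
  expect_equal(asg$unanchored, character(0))
})

test_that("scaffold orientation follows the physical-genetic correlation", {
  fx <- mk_anchor_fixture()
  asg <- assign_scaffolds(fx$tab, fx$mi)
  meg <- order_orient(asg, fx$tab, fx$mi, fx$lens)
  sc <- meg$scaffolds
  expect_equal(sc[sc$scaffold == "sA"]$orientation, "+")  # increasing
  expect_equal(sc[sc$scaffold == "sB"]$orientation, "-")  # decreasing
  expect_equal(sc[sc$scaffold == "sC"]$orientation, "unoriented")  # one cM
  expect_equal(sc[sc$scaffold == "sD"]$orientation, "unoriented")  # one bin
  # within a group, order follows mean cM
  lg1 <- sc[sc$lg == 1]
  expect_equal(lg1$scaffold[order(lg1$mean_cm)], lg1$scaffold)
})

test_that("AGP round trip reproduces megascaffold lengths exactly", {
  fx <- mk_anchor_fixture()
  asg <- assign_scaffolds(fx$tab, fx$mi)
  meg <- order_orient(asg, fx$tab, fx$mi, fx$lens, gap_len = 100)
  path <- tempfile(fileext = ".agp")
  write_agp(meg, path)
  agp <- read_agp(path)
  for (obj in names(meg$lengths)) {
    rows <- agp[agp$object == obj, ]
    expect_equal(max(rows$object_end), unname(meg$lengths[obj]))
    comp <- rows[rows$component_type == "W", ]
    gaps <- rows[rows$component_type == "U", ]
    expect_equal(sum(comp$object_end - comp$object_beg + 1) +
                   sum(gaps$object_end - gaps$object_beg + 1),
                 unname(meg$lengths[obj]))
    # components strictly ordered and non-overlapping
    expect_true(all(diff(rows$object_beg) > 0))
    expect_true(all(rows$object_beg[-1] == rows$object_end[-nrow(rows)] + 1))
  }
  # megascaffold length = scaffold lengths + gaps
  lg1_scf <- meg$scaffolds[meg$scaffolds$lg == 1]
  expect_equal(unname(meg$lengths["megascaffold1"]),
               sum(fx$lens[lg1_scf$scaffold]) + 100 * (nrow(lg1_scf) - 1))
})

test_that("mapping statistics reproduce the published per-group arithmetic", {
  lg <- paste0("LG", 1:9)
  cm <- c(97.7, 75.8, 69.1, 58.3, 51.1, 48.2, 44.9, 27.7, 21.5)
  markers <- c(203, 79, 114, 83, 61, 80, 33, 32, 13)
  mb <- c(165.9, 59.25, 97.35, 40.61, 47.89, 36.68, 30.01, 44.88, 20.78)
  scf <- c(91, 17, 37, 17, 4, 17, 21, 17, 13)
  st <- map_stats(lg, cm, markers, mb, scaffolds = scf)
  tot <- st[st$lg == "Total"]
  expect_equal(tot$cm, 494.3)
  expect_equal(tot$markers, 698)
  expect_equal(tot$physical_mb, 543.35)
  expect_equal(tot$mb_per_cm, 1.10)
  expect_equal(tot$markers_per_cm, 1.4)
  expect_equal(round(tot$mean_interval_cm, 1), 0.7)
  expect_equal(tot$scaffolds, 234)
  expect_equal(st[st$lg == "LG1"]$mean_interval_cm, 0.48)
  expect_equal(st[st$lg == "LG1"]$markers_per_cm, 2.1)
  expect_equal(st[st$lg == "LG1"]$mb_per_cm, 1.70)
  # anchored fraction of the assembly
  expect_equal(round(100 * tot$physical_mb / 804), 68)
  # empty input -> empty table
  expect_equal(nrow(map_stats(character(), numeric(), integer(), numeric())), 0)
})

test_that("scaffold anchoring recovers truth groups on simulated maps", {
  set.seed(53)
  correct <- 0; total <- 0
  for (trial in 1:3) {
    tm <- sim_truth_map(n_lg = 3, markers_per_lg = 25, lg_cm = 80)
    geno <- sim_f1_genotypes(tm, n_progeny = 51, missing_rate = 0.03,
                             seed = trial + 60)
    # markers already carry a truth scaffold (one per LG) in info
    map <- build_genetic_map(geno, "paternal")
    asg <- assign_scaffolds(map, geno$info)
    truth_of <- function(sc) as.integer(sub("chr", "", sc))
    lg_truth <- vapply(map$lgs, function(x)
      as.integer(names(which.max(table(geno$info$truth_lg[
        match(x$marker, geno$info$marker)])))), integer(1))
    for (i in seq_len(nrow(asg$anchors))) {
      total <- total + 1
      want <- truth_of(asg$anchors$scaffold[i])
      got <- lg_truth[asg$anchors$lg[i]]
      correct <- correct + (want == got)
    }
  }
  expect_gte(correct / total, 0.95)
})
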