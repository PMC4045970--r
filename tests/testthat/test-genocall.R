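mk_counts <- function(...) {
  rows <- list(...)
  data.table::rbindlist(lapply(names(rows), function(s) {
    x <- rows[[s]]
    data.table::data.table(sample_id = s, tag = names(x), n = unname(x))
  }))
}

test_that("locus allele calling follows the 25% minor-fraction rule", {
  # balanced parent: heterozygous
  loc <- call_locus_alleles(mk_counts(P1 = c(AAA = 10, GGG = 10)))
  expect_equal(loc$status, "ok")
  expect_setequal(loc$alleles, c("AAA", "GGG"))
  expect_equal(sort(loc$genotypes$P1), c(1L, 2L))
  # 19:1 -> homozygous, the single read treated as error
  loc2 <- call_locus_alleles(mk_counts(P1 = c(AAA = 19, GGG = 1),
                                       P2 = c(AAA = 5, GGG = 5)))
  expect_equal(loc2$genotypes$P1, c(1L, 1L))
  expect_equal(sort(loc2$genotypes$P2), c(1L, 2L))
  # three substantial alleles violate diploidy
  loc3 <- call_locus_alleles(mk_counts(P1 = c(AAA = 6, GGG = 6, TTT = 6)))
  expect_equal(loc3$status, "discarded")
})

test_that("parental segregation typing follows pseudo-testcross logic", {
  expect_equal(type_parental_segregation(c(1L, 1L), c(1L, 2L)), "nnxnp")
  expect_equal(type_parental_segregation(c(1L, 2L), c(1L, 1L)), "lmxll")
  expect_equal(type_parental_segregation(c(1L, 2L), c(1L, 2L)), "hkxhk")
  expect_equal(type_parental_segregation(c(1L, 1L), c(1L, 1L)), "uninformative")
  expect_equal(type_parental_segregation(NA, c(1L, 2L)), "uninformative")
})

test_that("progeny depth-coverage rule keeps loci above 90% covered", {
  n <- 51
  prog <- sprintf("F1_%02d", 1:n)
  mk_locus <- function(n_covered) {
    depth <- setNames(c(rep(10, n_covered), rep(2, n - n_covered)), prog)
    gts <- setNames(rep(list(c(1L, 2L)), n), prog)
    list(alleles = c("A", "G"), genotypes = gts, depth = depth, status = "ok")
  }
  # 45/51 = 88% -> dropped; 47/51 = 92% -> kept
  expect_false(genotype_progeny(mk_locus(45), "nnxnp", prog, c(1L, 1L))$keep)
  expect_true(genotype_progeny(mk_locus(47), "nnxnp", prog, c(1L, 1L))$keep)
  # a progeny with 2 reads is a missing call
  gp <- genotype_progeny(mk_locus(47), "nnxnp", prog, c(1L, 1L))
  expect_true(all(gp$calls[48:51] == "--"))
  expect_true(all(gp$calls[1:47] == "np"))
})

test_that("integrity filter drops markers over 10% missing", {
  n <- 51
  base <- rep(c("nn", "np"), length.out = n)
  with_missing <- function(k) { x <- base; if (k > 0) x[seq_len(k)] <- "--"; x }
  expect_false(filter_integrity(with_missing(6)))   # 11.8%
  expect_true(filter_integrity(with_missing(5)))    # 9.8%
  expect_true(filter_integrity(with_missing(0)))
})

test_that("distortion filter applies 3:1 and 10:1 ratio rules", {
  tc <- function(nn, np) c(rep("nn", nn), rep("np", np))
  expect_false(filter_distortion(tc(40, 10), "nnxnp"))  # ratio 4
  expect_true(filter_distortion(tc(30, 15), "nnxnp"))   # ratio 2
  expect_true(filter_distortion(tc(30, 10), "nnxnp"))   # ratio exactly 3
  expect_false(filter_distortion(tc(31, 10), "nnxnp"))
  hk <- function(hh, hk_, kk) c(rep("hh", hh), rep("hk", hk_), rep("kk", kk))
  expect_false(filter_distortion(hk(24, 20, 4), "hkxhk"))  # 44:4 = 11
  expect_true(filter_distortion(hk(20, 20, 4), "hkxhk"))   # 40:4 = 10
  # fewer than 10 informative calls is unratable
  expect_false(filter_distortion(tc(4, 4), "nnxnp"))
})

test_that("filter pipeline verdict is order-stable for per-locus predicates", {
  set.seed(13)
  n <- 51
  for (i in 1:20) {
    calls <- sample(c("nn", "np", "--"), n, replace = TRUE,
                    prob = c(0.45, 0.4, 0.15))
    f1 <- filter_integrity(calls)
    f2 <- filter_distortion(calls, "nnxnp")
    # predicates are independent of application order
    expect_identical(f1 && f2, f2 && f1)
  }
})

test_that("called genotypes equal truth on clean deep data", {
  # constructed clusters: 2 parents + 12 progeny, depth 10, no errors
  prog <- sprintf("F1_%02d", 1:12)
  truth_np <- c(rep(TRUE, 6), rep(FALSE, 6))
  rows <- list(P_mother = c(REF = 20))
  rows$P_father <- c(REF = 10, ALT = 10)
  for (i in seq_along(prog))
    rows[[prog[i]]] <- if (truth_np[i]) c(REF = 5, ALT = 5) else c(REF = 10)
  cl <- mk_counts <- data.table::rbindlist(lapply(names(rows), function(s)
    data.table::data.table(locus_id = "scf1:100:+", scaffold = "scf1",
                           pos = 100L, strand = "+", sample_id = s,
                           tag = names(rows[[s]]), n = unname(rows[[s]]))))
  res <- call_markers(cl, "P_mother", "P_father", prog, min_cover = 0.5)
  expect_equal(res$log$outcome, "retained")
  expect_equal(res$geno$info$seg_type, "nnxnp")
  expect_identical(unname(res$geno$calls[1, ]),
                   ifelse(truth_np, "np", "nn"))
})
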