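## In-silico ddRAD: double restriction digest with size selection, and
## barcoded single-end read generation with depth overdispersion and
## sequencing error.

#' Double-digest a sequence and size-select fragments
#'
#' Simultaneous digestion with two restriction enzymes on the forward
#' strand (both default sites are palindromic, so forward-strand search is
#' complete): NsiI `ATGCA/T` (cut after base 5 of the site) and MseI
#' `T/TAA` (cut after base 1). Retained fragments are flanked by one cut
#' of each enzyme and fall inside the size-selection window.
#'
#' @param sequence a character string or `DNAString`.
#' @param enzyme1_site,cut_after1 first (rare-cutter) recognition site and
#'   cut offset within it.
#' @param enzyme2_site,cut_after2 second (frequent-cutter) site and offset.
#' @param min_len,max_len size-selection window (defaults 200 and 500 bp).
#' @param keep_all return all fragments with a `retained` flag instead of
#'   only the retained ones.
#' @return data.table with columns `start`, `end` (0-based half-open),
#'   `length`, `e5`, `e3` (enzyme at each end: `"e1"`, `"e2"` or `"end"`
#'   for a sequence terminus) and, if `keep_all`, `retained`.
#' @export
digest_ddrad <- function(sequence, enzyme1_site = "ATGCAT", cut_after1 = 5,
                         enzyme2_site = "TTAA", cut_after2 = 1,
                         min_len = 200, max_len = 500, keep_all = FALSE) {
  s <- if (inherits(sequence, "DNAString")) sequence else
    Biostrings::DNAString(sequence)
  hits1 <- Biostrings::start(Biostrings::matchPattern(enzyme1_site, s))
  hits2 <- Biostrings::start(Biostrings::matchPattern(enzyme2_site, s))
  cuts <- data.table(pos = c(hits1 - 1 + cut_after1, hits2 - 1 + cut_after2),
                     enz = rep(c("e1", "e2"), c(length(hits1), length(hits2))))
  setorder(cuts, pos)
  bounds <- data.table(pos = c(0, cuts$pos, length(s)),
                       enz = c("end", cuts$enz, "end"))
  n <- nrow(bounds) - 1
  if (n < 1) return(data.table(start = numeric(), end = numeric(),
                               length = numeric(), e5 = character(),
                               e3 = character()))
  fr <- data.table(start = bounds$pos[-nrow(bounds)], end = bounds$pos[-1],
                   e5 = bounds$enz[-nrow(bounds)], e3 = bounds$enz[-1])
  fr <- fr[end > start]
  fr[, length := end - start]
  fr[, retained := length >= min_len & length <= max_len &
       ((e5 == "e1" & e3 == "e2") | (e5 == "e2" & e3 == "e1"))]
  if (keep_all) return(fr[])
  fr[retained == TRUE][, retained := NULL][]
}

#' Generate barcoded reads from fragments
#'
#' Reads start at the rare-cutter (enzyme 1) end of each fragment; the read
#' is the sample barcode followed by genomic bases, truncated to
#' `read_len`. Base-call errors are i.i.d. substitutions at `error_rate`
#' over the whole read (so barcode errors produce realistic ambiguous
#' reads); qualities are drawn from a fixed discrete Phred distribution.
#'
#' @param fragment_seqs character vector of fragment sequences, already
#'   oriented with the enzyme-1 end first.
#' @param barcode sample barcode (4-8 bases).
#' @param depths integer read count per fragment (recycled if length 1).
#' @param error_rate per-base substitution error probability.
#' @param read_len total read length (default 100).
#' @param q_levels,q_probs Phred quality distribution.
#' @return data.table with columns `frag_idx`, `seq`, `qual`.
#' @export
generate_reads <- function(fragment_seqs, barcode, depths, error_rate = 0.001,
                           read_len = 100,
                           q_levels = c(40, 38, 35, 30, 15),
                           q_probs = c(0.40, 0.30, 0.20, 0.08, 0.02)) {
  if (nchar(barcode) < 4 || nchar(barcode) > 8)
    stop_radmap("barcode length must be 4-8 bases (got %d)", nchar(barcode))
  if (length(depths) == 1) depths <- rep(depths, length(fragment_seqs))
  idx <- rep(seq_along(fragment_seqs), depths)
  if (length(idx) == 0)
    return(data.table(frag_idx = integer(), seq = character(), qual = character()))
  tmpl <- substr(paste0(barcode, fragment_seqs[idx]), 1, read_len)
  if (error_rate > 0) {
    nerr <- rbinom(length(tmpl), nchar(tmpl), error_rate)
    bases <- c("A", "C", "G", "T")
    for (i in which(nerr > 0)) {
      r <- charToRaw(tmpl[i])
      at <- sample.int(length(r), nerr[i])
      for (p in at) r[p] <- charToRaw(sample(setdiff(bases, rawToChar(r[p])), 1))
      tmpl[i] <- rawToChar(r)
    }
  }
  # per-base i.i.d. qualities, drawn as a pool of read-length patterns
  widths <- unique(nchar(tmpl))
  qual <- character(length(tmpl))
  for (w in widths) {
    at <- which(nchar(tmpl) == w)
    npool <- min(length(at), 2048L)
    pool <- vapply(seq_len(npool), function(i)
      rawToChar(as.raw(sample(q_levels + 33L, w, replace = TRUE,
                              prob = q_probs))), character(1))
    qual[at] <- pool[sample.int(npool, length(at), replace = TRUE)]
  }
  data.table(frag_idx = idx, seq = tmpl, qual = qual)
}

## Digest one haplotype of one parent; returns oriented fragment table
## with reference-coordinate locus keys. The locus key position is the
## leftmost reference coordinate of the tag window (92 bp from the
## rare-cutter end), matching the aligner's cluster convention.
digest_haplotype <- function(genome, hapinfo, parent, hap, tag_len = 92, ...) {
  rows <- list()
  for (sc in names(hapinfo$seqs)) {
    fr <- digest_ddrad(hapinfo$seqs[[sc]], ...)
    if (nrow(fr) == 0) next
    fr[, scaffold := sc]
    seqs <- substring(hapinfo$seqs[[sc]], fr$start + 1, fr$end)
    flip <- fr$e3 == "e1"
    seqs[flip] <- revcomp(seqs[flip])
    fr[, seq := seqs]
    fr[, strand := fifelse(flip, "-", "+")]
    ref_start <- hap_to_ref(hapinfo$offsets, sc, fr$start)
    ref_end <- hap_to_ref(hapinfo$offsets, sc, fr$end)
    fr[, ref_cut := fifelse(flip, ref_end - tag_len, ref_start)]
    fr[, ref_mid := (ref_start + ref_end) / 2]
    rows[[length(rows) + 1]] <- fr
  }
  out <- rbindlist(rows)
  if (nrow(out) > 0) { out[, parent := parent]; out[, hap := hap] }
  out
}

#' Prefix-free sample barcodes
#'
#' @param n number of barcodes.
#' @param lengths barcode lengths to cycle through (default 4:8).
#' @param seed integer seed.
#' @return Character vector of distinct barcodes, none a prefix of another.
#' @export
make_barcodes <- function(n, lengths = 4:8, seed = 1) {
  set.seed(child_seed(seed, "barcodes"))
  out <- character(0)
  lens <- rep(lengths, length.out = n)
  while (length(out) < n) {
    cand <- random_dna(lens[length(out) + 1])
    clash <- any(startsWith(cand, out) | startsWith(out, cand))
    if (!clash) out <- c(out, cand)
  }
  out
}

#' Simulate a full ddRAD sequencing experiment
#'
#' Digests all four parental haplotypes, transmits fragments to progeny
#' according to their gametes, and generates barcoded reads. Depth is
#' drawn once per (sample, locus) as a negative binomial — capturing
#' locus- and sample-level amplification variation — and split
#' binomially between the individual's two chromosomes, since both
#' alleles of one locus share fragment length and context and are
#' amplified together; a chromosome whose cut site was destroyed by a
#' variant contributes no reads (allele dropout). Parent samples receive
#' `parent_depth_mult` times the progeny depth, as in standard ddRAD
#' library designs where the discovery panel is sequenced deeper.
#'
#' @param genome an `annotated_genome`.
#' @param parents a `parent_pair`.
#' @param progeny a `progeny_set`.
#' @param mean_depth expected reads per locus per progeny (default 30).
#' @param dispersion negative-binomial size parameter (default 10; smaller
#'   is more overdispersed).
#' @param error_rate per-base substitution error (default 0.001).
#' @param read_len read length (default 100).
#' @param parent_depth_mult parental depth multiplier (default 2).
#' @param seed integer seed.
#' @param ... passed to [digest_ddrad()] (enzyme sites, size window).
#' @return List with `reads` (data.table `read_id`, `seq`, `qual`,
#'   `sample_truth`, `locus_truth`), `samples` (data.table `sample_id`,
#'   `barcode`, `role`) and `fragments` (per-haplotype fragment tables).
#' @export
sim_radseq_experiment <- function(genome, parents, progeny, mean_depth = 30,
                                  dispersion = 10, error_rate = 0.001,
                                  read_len = 100, parent_depth_mult = 2,
                                  seed = 1, ...) {
  set.seed(child_seed(seed, "reads"))
  frags <- list()
  for (par in c("maternal", "paternal")) {
    for (hp in 1:2) {
      hapinfo <- build_haplotype(genome, parents, par, hp)
      fd <- digest_haplotype(genome, hapinfo, par, hp, ...)
      if (nrow(fd) > 0)
        fd[, key := sprintf("%s:%d:%s", scaffold, round(ref_cut), strand)]
      frags[[paste(par, hp, sep = "_")]] <- fd
    }
  }
  n_prog <- progeny$n
  samples <- data.table(
    sample_id = c("P_mother", "P_father", sprintf("F1_%02d", seq_len(n_prog))),
    role = c("mother", "father", rep("progeny", n_prog)))
  samples[, barcode := make_barcodes(.N, seed = seed)]

  # fragments carried by one inherited chromosome of one progeny
  inherited <- function(par, pi) {
    gm <- progeny$gametes[[pi]][[par]]
    picked <- lapply(1:2, function(hp) {
      fd <- frags[[paste(par, hp, sep = "_")]]
      if (nrow(fd) == 0) return(fd)
      keep <- logical(nrow(fd))
      for (sc in unique(fd$scaffold)) {
        at <- which(fd$scaffold == sc)
        keep[at] <- gamete_hap_at(gm[[sc]], fd$ref_mid[at]) == hp
      }
      fd[keep]
    })
    rbindlist(picked)
  }
  read_rows <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    sm <- samples[si]
    if (sm$role %in% c("mother", "father")) {
      par <- if (sm$role == "mother") "maternal" else "paternal"
      chrom1 <- frags[[paste(par, 1, sep = "_")]]
      chrom2 <- frags[[paste(par, 2, sep = "_")]]
      mu <- parent_depth_mult * mean_depth
    } else {
      chrom1 <- inherited("maternal", si - 2L)
      chrom2 <- inherited("paternal", si - 2L)
      mu <- mean_depth
    }
    keys <- union(chrom1$key, chrom2$key)
    if (length(keys) == 0) next
    tot <- rnbinom(length(keys), size = dispersion, mu = mu)
    x1 <- rbinom(length(keys), tot, 0.5)        # chromosome-1 share
    names(tot) <- names(x1) <- keys
    seqs <- c(chrom1$seq, chrom2$seq)
    dkey <- c(chrom1$key, chrom2$key)
    depths <- c(x1[chrom1$key], (tot - x1)[chrom2$key])
    rd <- generate_reads(seqs, sm$barcode, depths, error_rate = error_rate,
                         read_len = read_len)
    if (nrow(rd) == 0) next
    rd[, sample_truth := sm$sample_id]
    rd[, locus_truth := dkey[frag_idx]]
    rd[, frag_idx := NULL]
    read_rows[[si]] <- rd
  }
  reads <- rbindlist(read_rows)
  reads[, read_id := sprintf("r%07d", seq_len(.N))]
  list(reads = reads[], samples = samples, fragments = frags)
}

#' Write reads as FASTQ (Phred+33)
#' @param reads data.table with `read_id`, `seq`, `qual`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dna <- Biostrings::DNAStringSet(reads$seq)
  names(dna) <- reads$read_id
  qs <- Biostrings::BStringSet(reads$qual)
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(
      dna, Biostrings::PhredQuality(qs)), path)
  invisible(path)
}

#' Read a FASTQ file into a read table
#' @param path FASTQ file (Phred+33).
#' @return data.table with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.table(read_id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities))
}
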