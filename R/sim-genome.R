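## Synthetic annotated genomes: background sequence tiled with diverged
## repeat-family copies and gene-model intervals, the substrate for the
## ddRAD marker-discovery pipeline and its reference-strategy comparison.

## Repeat-family consensus with one implanted ddRAD locus: a rare-cutter
## site and a frequent-cutter site a retained-fragment length apart, with
## no competing internal site between them. Real repeat families carry
## restriction-fragment loci in essentially every element, which is what
## makes repeats a source of colliding RAD markers.
make_family_unit <- function(len, e1 = "ATGCAT", e2 = "TTAA",
                             span_range = c(260, 450)) {
  s <- random_dna(len)
  if (len < max(span_range) + 20) return(s)
  span <- sample(span_range[1]:span_range[2], 1)
  u <- sample.int(len - span - nchar(e2) - 1, 1)
  substr(s, u, u + nchar(e1) - 1) <- e1
  substr(s, u + span, u + span + nchar(e2) - 1) <- e2
  inner <- substr(s, u + nchar(e1), u + span - 1)
  for (site in c(e1, e2)) {
    repeat {
      p <- regexpr(site, inner, fixed = TRUE)[1]
      if (p < 0) break
      cur <- substr(inner, p, p)
      substr(inner, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  substr(s, u + nchar(e1), u + span - 1) <- inner
  s
}

mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  k <- rbinom(1, n, rate)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  r <- charToRaw(seq)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    cur <- rawToChar(r[p])
    r[p] <- charToRaw(sample(setdiff(bases, cur), 1))
  }
  rawToChar(r)
}

#' Simulate an annotated genome
#'
#' Builds scaffold sequences by tiling random background with copies of a
#' small number of repeat families (each copy independently diverged from
#' its family consensus), then places gene-model intervals in the
#' non-repetitive gaps. Repeat and gene intervals are recorded as 0-based
#' half-open coordinates and are non-overlapping by construction.
#'
#' @param scaffold_lengths integer vector of scaffold lengths (>= 10 kb
#'   each); names become scaffold ids (default `scf1..scfN`).
#' @param repeat_fraction target fraction of bases in repeat copies
#'   (default 0.4; must be <= 0.95).
#' @param repeat_families optional data.frame with columns `unit_len`,
#'   `n_copies`, `divergence` giving explicit family specs; otherwise
#'   `n_families` families with unit lengths in `unit_len_range` and
#'   per-copy divergence `divergence` are derived from `repeat_fraction`.
#' @param n_families,unit_len_range,divergence family derivation controls.
#' @param gene_density target fraction of bases inside gene intervals
#'   (default 0.05).
#' @param gene_len_range gene interval length range (default 500-2500 bp).
#' @param seed integer seed; the result is fully reproducible.
#' @return An object of class `annotated_genome`: list with `seqs` (named
#'   character vector), `lengths`, `repeats` (data.table `scaffold`,
#'   `start`, `end`, `family`, `copy_id`), `genes` (data.table `scaffold`,
#'   `start`, `end`) and `families` (consensus sequences).
#' @export
simulate_genome <- function(scaffold_lengths, repeat_fraction = 0.4,
                            repeat_families = NULL, n_families = 6,
                            unit_len_range = c(800, 2500), divergence = 0.01,
                            gene_density = 0.05, gene_len_range = c(500, 2500),
                            seed = 1) {
  if (any(scaffold_lengths < 10000)) stop_radmap("scaffold lengths must be >= 10 kb")
  set.seed(child_seed(seed, "genome"))
  total_len <- sum(scaffold_lengths)
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- sprintf("scf%d", seq_along(scaffold_lengths))
  if (is.null(repeat_families)) {
    unit_lens <- round(runif(n_families, unit_len_range[1], unit_len_range[2]))
    target_bases <- repeat_fraction * total_len
    n_copies_total <- max(0, round(target_bases / mean(unit_lens)))
    fam_of_copy <- if (n_copies_total > 0)
      sample(seq_len(n_families), n_copies_total, replace = TRUE) else integer()
    repeat_families <- data.table(
      unit_len = unit_lens,
      n_copies = tabulate(fam_of_copy, n_families),
      divergence = divergence)
  } else {
    repeat_families <- as.data.table(repeat_families)
  }
  rep_bases <- sum(repeat_families$unit_len * repeat_families$n_copies)
  if (rep_bases > 0.95 * total_len)
    stop_radmap("requested repeat content (%.0f%%) exceeds 95%% of genome",
                100 * rep_bases / total_len)
  fam_seqs <- vapply(repeat_families$unit_len, make_family_unit, character(1))

  # one shuffled global list of copy instances, then dealt to scaffolds
  copies <- data.table(
    family = rep(seq_len(nrow(repeat_families)), repeat_families$n_copies))
  if (nrow(copies) > 0) {
    copies <- copies[sample(.N)]
    copies[, copy_id := seq_len(.N)]
    copies[, scaffold := sample(names(scaffold_lengths), .N, replace = TRUE,
                                prob = scaffold_lengths)]
  }
  seqs <- character(0); rep_rows <- list(); gene_rows <- list()
  for (sc in names(scaffold_lengths)) {
    L <- scaffold_lengths[[sc]]
    cps <- if (nrow(copies) > 0) copies[scaffold == sc] else copies
    lens <- repeat_families$unit_len[cps$family]
    # drop copies that cannot fit
    while (sum(lens) > 0.95 * L) { cps <- cps[-.N]; lens <- lens[-length(lens)] }
    k <- nrow(cps)
    gap_total <- L - sum(lens)
    gw <- rexp(k + 1) + 0.02
    gaps <- floor(gap_total * gw / sum(gw))
    gaps[1] <- gaps[1] + (gap_total - sum(gaps))
    pieces <- character(2 * k + 1)
    cursor <- 0
    for (i in seq_len(k)) {
      pieces[2 * i - 1] <- random_dna(gaps[i])
      cursor <- cursor + gaps[i]
      unit <- mutate_seq(fam_seqs[cps$family[i]],
                         repeat_families$divergence[cps$family[i]])
      pieces[2 * i] <- unit
      rep_rows[[length(rep_rows) + 1]] <- data.table(
        scaffold = sc, start = cursor, end = cursor + lens[i],
        family = cps$family[i], copy_id = cps$copy_id[i])
      cursor <- cursor + lens[i]
    }
    pieces[2 * k + 1] <- random_dna(gaps[k + 1])
    seqs[sc] <- paste(pieces, collapse = "")
    # gene intervals inside non-repeat gaps
    gap_start <- cumsum(c(0, lens + gaps[seq_len(k)]))
    gap_dt <- data.table(start = gap_start, end = gap_start + gaps)
    gap_dt <- gap_dt[end - start >= 200]
    target <- gene_density * L
    placed <- 0
    for (gi in sample(seq_len(nrow(gap_dt)))) {
      if (placed >= target) break
      glen <- min(round(runif(1, gene_len_range[1], gene_len_range[2])),
                  gap_dt$end[gi] - gap_dt$start[gi])
      gstart <- gap_dt$start[gi] +
        floor(runif(1, 0, gap_dt$end[gi] - gap_dt$start[gi] - glen + 1))
      gene_rows[[length(gene_rows) + 1]] <- data.table(
        scaffold = sc, start = gstart, end = gstart + glen)
      placed <- placed + glen
    }
  }
  empty_iv <- data.table(scaffold = character(), start = numeric(), end = numeric())
  structure(list(
    seqs = seqs, lengths = scaffold_lengths,
    repeats = if (length(rep_rows)) rbindlist(rep_rows) else
      data.table(empty_iv, family = integer(), copy_id = integer()),
    genes = if (length(gene_rows)) {
      g <- rbindlist(gene_rows); setorder(g, scaffold, start); g
    } else empty_iv,
    families = fam_seqs, seed = seed), class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %d scaffolds, %.2f Mb; repeats %.1f%%, genes %.1f%%\n",
              length(x$seqs), sum(x$lengths) / 1e6,
              100 * sum(x$repeats$end - x$repeats$start) / sum(x$lengths),
              100 * sum(x$genes$end - x$genes$start) / sum(x$lengths)))
  invisible(x)
}

#' Simulate parental haplotypes over a reference genome
#'
#' Places heterozygous variants (SNPs and 1-2 bp indels) uniformly along
#' the genome for each parent, on one haplotype (the other haplotype is the
#' reference itself). For the paternal parent, a fraction of repeat copies
#' additionally receives a non-allelic gene-conversion tract on the variant
#' haplotype: the tract is overwritten with a donor copy's sequence from
#' the same family plus one novel substitution. Converted tracts are the
#' simulator's model of repeat-driven alignment collisions: their reads
#' align best to the donor copy and create markers at the wrong physical
#' position when repeats are not masked.
#'
#' @param genome an `annotated_genome`.
#' @param het_rate_maternal,het_rate_paternal heterozygous variants per
#'   base (defaults 3e-4 and 3.7e-3; must lie in `[0, 0.05]`).
#' @param indel_frac fraction of variants that are 1-2 bp indels
#'   (default 0.1; the rest are SNPs).
#' @param conv_frac fraction of multi-copy repeat copies receiving a
#'   paternal conversion tract (default 0.5; set 0 to disable).
#' @param conv_tract_len maximum conversion tract length (default 1500 bp,
#'   i.e. usually the whole repeat copy).
#' @param seed integer seed.
#' @return Object of class `parent_pair`: list with `variants` (data.table
#'   `parent`, `scaffold`, `pos`, `ref`, `alt`, `type`, `origin`), and
#'   `rates` (requested rates).
#' @export
simulate_parents <- function(genome, het_rate_maternal = 3e-4,
                             het_rate_paternal = 3.7e-3, indel_frac = 0.1,
                             conv_frac = 0.5, conv_tract_len = 1500, seed = 1) {
  rates <- c(maternal = het_rate_maternal, paternal = het_rate_paternal)
  if (any(rates < 0 | rates > 0.05)) stop_radmap("het rates must lie in [0, 0.05]")
  set.seed(child_seed(seed, "parents"))
  total_len <- sum(genome$lengths)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (par in names(rates)) {
    if (rates[[par]] > 0 && rates[[par]] * total_len < 1)
      warning(sprintf("expected < 1 heterozygous site for %s parent", par))
    n_sites <- rbinom(1, total_len, rates[[par]])
    if (n_sites > 0) {
      gpos <- sort(sample.int(total_len, n_sites))
      cuts <- cumsum(as.numeric(genome$lengths))
      sc_idx <- findInterval(gpos - 1, c(0, cuts), rightmost.closed = FALSE)
      pos <- gpos - c(0, cuts)[sc_idx] - 1  # 0-based within scaffold
      sc <- names(genome$lengths)[sc_idx]
      is_indel <- runif(n_sites) < indel_frac
      refb <- substring(genome$seqs[sc], pos + 1, pos + 1)
      alt <- character(n_sites); ref <- refb; type <- ifelse(is_indel, "indel", "snp")
      for (i in seq_len(n_sites)) {
        if (!is_indel[i]) {
          alt[i] <- sample(setdiff(bases, refb[i]), 1)
        } else if (runif(1) < 0.5) {      # insertion after pos
          alt[i] <- paste0(refb[i], random_dna(sample(1:2, 1)))
        } else {                          # deletion of 1-2 bases after pos
          dl <- sample(1:2, 1)
          ref[i] <- substring(genome$seqs[sc[i]], pos[i] + 1, pos[i] + 1 + dl)
          alt[i] <- refb[i]
        }
      }
      out[[par]] <- data.table(parent = par, scaffold = sc, pos = pos,
                               ref = ref, alt = alt, type = type,
                               origin = "mutation")
    } else {
      out[[par]] <- data.table(parent = character(), scaffold = character(),
                               pos = numeric(), ref = character(),
                               alt = character(), type = character(),
                               origin = character())
    }
  }
  # paternal non-allelic gene conversion within repeat families
  if (conv_frac > 0 && nrow(genome$repeats) > 0) {
    reps <- as.data.table(genome$repeats)
    fam_sizes <- reps[, .N, by = family]
    multi <- fam_sizes[N >= 2]$family
    cand <- reps[family %in% multi]
    n_conv <- rbinom(1, nrow(cand), conv_frac)
    if (n_conv > 0) {
      conv_rows <- list()
      picks <- cand[sample(.N, n_conv)]
      for (i in seq_len(n_conv)) {
        acc <- picks[i]
        donors <- reps[family == acc$family & copy_id != acc$copy_id]
        don <- donors[sample(.N, 1)]
        ulen <- min(acc$end - acc$start, don$end - don$start)
        tlen <- min(conv_tract_len, ulen)
        off <- floor(runif(1, 0, ulen - tlen + 1))
        acc_seq <- substring(genome$seqs[acc$scaffold], acc$start + off + 1,
                             acc$start + off + tlen)
        don_seq <- substring(genome$seqs[don$scaffold], don$start + off + 1,
                             don$start + off + tlen)
        av <- strsplit(acc_seq, "")[[1]]; dv <- strsplit(don_seq, "")[[1]]
        diffs <- which(av != dv)
        if (length(diffs) > 0) {
          conv_rows[[length(conv_rows) + 1]] <- data.table(
            parent = "paternal", scaffold = acc$scaffold,
            pos = acc$start + off + diffs - 1, ref = av[diffs], alt = dv[diffs],
            type = "snp", origin = "conversion")
        }
        novel_at <- sample.int(tlen, 1)
        cur <- dv[novel_at]
        conv_rows[[length(conv_rows) + 1]] <- data.table(
          parent = "paternal", scaffold = acc$scaffold,
          pos = acc$start + off + novel_at - 1, ref = av[novel_at],
          alt = sample(setdiff(bases, c(cur, av[novel_at])), 1),
          type = "snp", origin = "conversion_novel")
      }
      out$paternal <- rbindlist(list(out$paternal, rbindlist(conv_rows)))
    }
  }
  variants <- rbindlist(out)
  # unique positions per parent (later variant at a duplicated position dropped)
  variants <- variants[!duplicated(variants[, .(parent, scaffold, pos)])]
  setorder(variants, parent, scaffold, pos)
  structure(list(variants = variants, rates = rates, seed = seed),
            class = "parent_pair")
}

#' @export
print.parent_pair <- function(x, ...) {
  cat(sprintf("<parent_pair> maternal %d, paternal %d heterozygous sites\n",
              sum(x$variants$parent == "maternal"),
              sum(x$variants$parent == "paternal")))
  invisible(x)
}

#' Realize a parental haplotype sequence
#'
#' Haplotype 1 of each parent is the reference itself; haplotype 2 carries
#' the parent's variants. Returns the sequences together with the indel
#' offset table needed to lift haplotype coordinates back to the reference.
#'
#' @param genome an `annotated_genome`.
#' @param parents a `parent_pair`.
#' @param parent `"maternal"` or `"paternal"`.
#' @param hap 1 or 2.
#' @return List with `seqs` (named character) and `offsets` (data.table
#'   `scaffold`, `ref_pos`, `shift`: cumulative hap-minus-ref shift for
#'   positions after `ref_pos`).
#' @export
build_haplotype <- function(genome, parents, parent = c("maternal", "paternal"),
                            hap = 1) {
  parent <- match.arg(parent)
  if (hap == 1)
    return(list(seqs = genome$seqs,
                offsets = data.table(scaffold = character(), ref_pos = numeric(),
                                     shift = numeric())))
  sel <- parents$variants$parent == parent  # evaluated outside dt scope:
  v <- parents$variants[sel]                # 'parent' is also a column name
  seqs <- genome$seqs
  off_rows <- list()
  for (sc in names(seqs)) {
    vs <- v[scaffold == sc]
    if (nrow(vs) == 0) next
    r <- charToRaw(seqs[[sc]])
    snps <- vs[type == "snp"]
    if (nrow(snps) > 0) r[snps$pos + 1] <- charToRaw(paste(snps$alt, collapse = ""))
    s <- rawToChar(r)
    ind <- vs[type == "indel"]
    if (nrow(ind) > 0) {
      setorder(ind, pos)
      pieces <- character(2 * nrow(ind) + 1)
      prev <- 0; shift <- 0; shifts <- numeric(nrow(ind))
      for (i in seq_len(nrow(ind))) {
        pieces[2 * i - 1] <- substring(s, prev + 1, ind$pos[i])
        pieces[2 * i] <- ind$alt[i]
        prev <- ind$pos[i] + nchar(ind$ref[i])
        shift <- shift + nchar(ind$alt[i]) - nchar(ind$ref[i])
        shifts[i] <- shift
      }
      pieces[2 * nrow(ind) + 1] <- substring(s, prev + 1, nchar(s))
      s <- paste(pieces, collapse = "")
      off_rows[[length(off_rows) + 1]] <- data.table(
        scaffold = sc, ref_pos = ind$pos, shift = shifts)
    }
    seqs[[sc]] <- s
  }
  list(seqs = seqs,
       offsets = if (length(off_rows)) rbindlist(off_rows) else
         data.table(scaffold = character(), ref_pos = numeric(), shift = numeric()))
}

## Lift a haplotype coordinate back to the reference (approximate within
## 2 bp across indels, exact elsewhere).
hap_to_ref <- function(offsets, sc, hap_pos) {
  o <- offsets[scaffold == sc]
  if (nrow(o) == 0) return(hap_pos)
  hp <- o$ref_pos + o$shift
  idx <- findInterval(hap_pos, hp)
  hap_pos - c(0, o$shift)[idx + 1]
}

#' Write genome FASTA and interval BED files
#'
#' @param genome an `annotated_genome`.
#' @param dir output directory (created if needed).
#' @param masked also write a repeat-masked FASTA (repeat bases as `N`).
#' @return Named character vector of written paths.
#' @export
write_genome_files <- function(genome, dir, masked = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "genome.fa"),
             repeats = file.path(dir, "repeats.bed"),
             genes = file.path(dir, "genes.bed"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$seqs), paths["fasta"])
  write_bed <- function(iv, path) {
    df <- data.frame(iv$scaffold, format(iv$start, scientific = FALSE, trim = TRUE),
                     format(iv$end, scientific = FALSE, trim = TRUE))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_bed(genome$repeats, paths["repeats"])
  write_bed(genome$genes, paths["genes"])
  if (masked) {
    paths["masked_fasta"] <- file.path(dir, "genome.masked.fa")
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(mask_sequences(genome)), paths["masked_fasta"])
  }
  paths
}

#' Write parental haplotype FASTA files
#'
#' @param genome an `annotated_genome`.
#' @param parents a `parent_pair`.
#' @param dir output directory.
#' @return Named character vector of written paths (one per parent and
#'   haplotype; scaffold names are suffixed with the haplotype).
#' @export
write_haplotype_fasta <- function(genome, parents, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (par in c("maternal", "paternal")) {
    for (hp in 1:2) {
      h <- build_haplotype(genome, parents, par, hp)
      seqs <- Biostrings::DNAStringSet(h$seqs)
      names(seqs) <- sprintf("%s_hap%d", names(h$seqs), hp)
      key <- sprintf("%s_hap%d", par, hp)
      paths[key] <- file.path(dir, paste0(key, ".fa"))
      Biostrings::writeXStringSet(seqs, paths[key])
    }
  }
  paths
}

## Repeat-masked copies of the scaffold sequences (repeat bases -> N).
mask_sequences <- function(genome) {
  seqs <- genome$seqs
  for (sc in unique(genome$repeats$scaffold)) {
    iv <- genome$repeats[scaffold == sc]
    r <- charToRaw(seqs[[sc]])
    for (i in seq_len(nrow(iv))) r[(iv$start[i] + 1):iv$end[i]] <- charToRaw("N")
    seqs[[sc]] <- rawToChar(r)
  }
  seqs
}
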