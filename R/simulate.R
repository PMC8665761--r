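## Synthetic data: generational SNP accumulation on a reference, paired-end
## read simulation with truth alignments, the packaged worked-example
## fixture, and a unit-cost edit distance for sequence-level evaluation.

#' Simulate generational single-nucleotide mutation accumulation
#'
#' Starting from one genome equal to the reference, every generation doubles
#' the population; each child inherits its parent's substitutions and adds
#' new ones: every locus mutates independently with probability
#' `mutation_rate`, the new base drawn uniformly from the three
#' alternatives of the current base (a locus may mutate repeatedly along a
#' lineage; the final base is what is reported, and a reversion to the
#' reference base drops out of the VCF).
#'
#' @param reference reference sequence (string, `DNAStringSet` or FASTA
#'   path).
#' @param mutation_rate per-locus per-generation substitution probability.
#' @param generations number of generations (final population `2^g`).
#' @param seed RNG seed (mandatory; no hidden global state is consumed).
#' @return object of class `generational_panel`: list with `reference`,
#'   `generations`, `mutation_rate`, `seed`, `labels`, `mutations` (per
#'   genome, a named character vector position -> base) and `genomes`
#'   (character vector of the final-generation sequences).
#' @export
simulate_generations <- function(reference, mutation_rate, generations,
                                 seed) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, generations >= 0)
  reference <- load_sequences(reference)[[1L]]
  R <- nchar(reference)
  set.seed(seed)
  ref_chars <- chars(reference)
  pop <- list(character(0))         # mutation maps: names = positions
  if (generations > 0) {
    for (g in seq_len(generations)) {
      nxt <- vector("list", 2L * length(pop))
      for (i in seq_along(pop)) {
        for (c in 1:2) {
          muts <- pop[[i]]
          nmut <- rbinom(1L, R, mutation_rate)
          if (nmut > 0L) {
            loci <- sample.int(R, nmut)
            for (p in loci) {
              key <- as.character(p)
              cur <- if (key %in% names(muts)) muts[[key]] else ref_chars[p]
              newb <- sample(setdiff(c("A", "C", "G", "T"), cur), 1L)
              if (newb == ref_chars[p]) muts <- muts[names(muts) != key]
              else muts[key] <- newb
            }
          }
          nxt[[2L * (i - 1L) + c]] <- muts
        }
      }
      pop <- nxt
    }
  }
  labels <- sprintf("g%d_%d", generations, seq_along(pop))
  genomes <- vapply(pop, function(muts) {
    s <- ref_chars
    if (length(muts) > 0L) s[as.integer(names(muts))] <- muts
    paste(s, collapse = "")
  }, "")
  structure(list(reference = reference, generations = generations,
                 mutation_rate = mutation_rate, seed = seed,
                 labels = labels, mutations = setNames(pop, labels),
                 genomes = setNames(genomes, labels)),
            class = "generational_panel")
}

#' @export
print.generational_panel <- function(x, ...) {
  cat(sprintf("generational_panel: %d genome(s) after %d generation(s), rate %g, seed %d\n",
              length(x$genomes), x$generations, x$mutation_rate, x$seed))
  invisible(x)
}

#' Write a panel as a haploid multi-sample VCF
#'
#' One record per mutated locus; alternative alleles are the distinct
#' non-reference bases observed across the panel at that locus, and every
#' genome's haploid genotype is the index of its base (0 = reference).
#'
#' @param panel a [simulate_generations()] result.
#' @param path output VCF path.
#' @param chrom chromosome name to write.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path, chrom = "sim") {
  allpos <- sort(unique(as.integer(unlist(lapply(panel$mutations, names)))))
  n <- length(allpos)
  recs <- data.frame(pos = integer(0), ref = character(0),
                     alt = character(0), stringsAsFactors = FALSE)
  gtm <- NULL
  if (n > 0L) {
    ref_chars <- chars(panel$reference)
    rows <- vector("list", n)
    gtm <- matrix("0", nrow = n, ncol = length(panel$labels),
                  dimnames = list(NULL, panel$labels))
    for (i in seq_len(n)) {
      p <- allpos[i]
      key <- as.character(p)
      bases <- vapply(panel$mutations, function(m)
        if (key %in% names(m)) m[[key]] else ref_chars[p], "")
      alts <- sort(setdiff(unique(bases), ref_chars[p]))
      rows[[i]] <- data.frame(pos = p, ref = ref_chars[p],
                              alt = paste(alts, collapse = ","),
                              stringsAsFactors = FALSE)
      gtm[i, ] <- as.character(match(bases, alts, nomatch = 0L))
    }
    recs <- do.call(rbind, rows)
  }
  for (s in panel$labels)
    recs[[paste0("gt.", s)]] <- if (n > 0L) gtm[, s] else character(0)
  write_simple_vcf(recs, path, chrom = chrom,
                   contig_length = nchar(panel$reference),
                   samples = panel$labels)
  invisible(path)
}

#' Simulate paired-end reads with truth alignments
#'
#' Fragments are drawn uniformly along the sequence with normally
#' distributed insert sizes; both mates carry independent per-base
#' substitution errors at `error_rate`.  Constant quality strings are
#' written, and a truth SAM (proper-pair flags, ungapped CIGAR) records
#' where each mate came from, so downstream support accumulation needs no
#' external aligner.
#'
#' @param sequence template sequence (string / `DNAStringSet` / FASTA
#'   path).
#' @param read_length read length in bases (default 100).
#' @param error_rate per-base substitution error probability (default
#'   0.01).
#' @param coverage target mean coverage.
#' @param insert_mean,insert_sd insert size distribution (outer distance);
#'   inserts shorter than the read length are clamped with a warning.
#' @param seed RNG seed (mandatory).
#' @param rname reference name recorded in the truth alignments.
#' @return object of class `read_set`: list with `reads1`, `reads2` (named
#'   character vectors, mate 2 reverse-complemented as sequenced), `truth`
#'   (data frame: `qname`, `pos1`, `pos2`, `insert`), `read_length`,
#'   `error_rate`, `rname`, `seq_length`, `seed`.
#' @export
simulate_reads <- function(sequence, read_length = 100L, error_rate = 0.01,
                           coverage, insert_mean = 300L, insert_sd = 25L,
                           seed, rname = "ref") {
  sequence <- load_sequences(sequence)[[1L]]
  len <- nchar(sequence)
  stopifnot(read_length <= len, coverage >= 0, error_rate >= 0,
            error_rate <= 1)
  set.seed(seed)
  n <- max(0L, round(coverage * len / (2L * read_length)))
  qname <- character(n); pos1 <- integer(n); pos2 <- integer(n)
  ins <- integer(n)
  reads1 <- character(n); reads2 <- character(n)
  clamped <- FALSE
  add_errors <- function(r) {
    cc <- chars(r)
    hit <- which(runif(length(cc)) < error_rate)
    for (h in hit) cc[h] <- sample(setdiff(c("A", "C", "G", "T"), cc[h]), 1L)
    paste(cc, collapse = "")
  }
  for (i in seq_len(n)) {
    insert <- round(rnorm(1L, insert_mean, insert_sd))
    if (insert < read_length) { insert <- read_length; clamped <- TRUE }
    if (insert > len) insert <- len
    start <- sample.int(len - insert + 1L, 1L)
    frag_end <- start + insert - 1L
    qname[i] <- sprintf("read%06d", i)
    pos1[i] <- start
    pos2[i] <- frag_end - read_length + 1L
    ins[i] <- insert
    r1 <- substring(sequence, start, start + read_length - 1L)
    r2 <- revcomp(substring(sequence, pos2[i], frag_end))
    reads1[i] <- add_errors(r1)
    reads2[i] <- add_errors(r2)
  }
  if (clamped) warning("insert size(s) below read length; clamped")
  nm1 <- if (n > 0L) paste0(qname, "/1") else character(0)
  nm2 <- if (n > 0L) paste0(qname, "/2") else character(0)
  structure(list(reads1 = setNames(reads1, nm1),
                 reads2 = setNames(reads2, nm2),
                 truth = data.frame(qname = qname, pos1 = pos1, pos2 = pos2,
                                    insert = ins, stringsAsFactors = FALSE),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, rname = rname,
                 seq_length = len, seed = seed),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d pair(s) of %d bp from %s (error rate %g)\n",
              nrow(x$truth), x$read_length, x$rname, x$error_rate))
  invisible(x)
}

#' Write simulated reads as paired FASTQ
#'
#' @param reads a [simulate_reads()] result.
#' @param path1,path2 output FASTQ paths for mates 1 and 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq <- function(reads, path1, path2) {
  wr <- function(seqs, path) {
    set <- Biostrings::DNAStringSet(unname(seqs))
    names(set) <- names(seqs)
    quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(set, path, format = "fastq",
                                qualities = quals)
  }
  wr(reads$reads1, path1)
  wr(reads$reads2, path2)
  invisible(c(path1, path2))
}

#' Write the truth alignments of simulated reads as SAM
#'
#' Proper-pair records with MAPQ 60 and ungapped CIGAR; mate 2 is stored
#' forward-strand (reverse flag set), as an aligner would emit it.
#'
#' @param reads a [simulate_reads()] result.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_truth_sam <- function(reads, path) {
  rl <- reads$read_length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", reads$rname, reads$seq_length)),
             con)
  t <- reads$truth
  qual <- strrep("I", rl)
  cigar <- sprintf("%dM", rl)
  for (i in seq_len(nrow(t))) {
    seq2_fwd <- revcomp(reads$reads2[[i]])
    writeLines(c(
      paste(t$qname[i], 99L, reads$rname, t$pos1[i], 60L, cigar, "=",
            t$pos2[i], t$insert[i], reads$reads1[[i]], qual, sep = "\t"),
      paste(t$qname[i], 147L, reads$rname, t$pos2[i], 60L, cigar, "=",
            t$pos1[i], -t$insert[i], seq2_fwd, qual, sep = "\t")), con)
  }
  invisible(path)
}

#' The packaged worked-example fixture
#'
#' Five artificial variant records over the 18 bp reference
#' `TTCTGGGAGGCAGTTACC` with five haploid samples `s1..s5`; the running
#' example used throughout the documentation and tests.  The same data
#' ships as plain files under `inst/extdata/` (`table1.fa`, `table1.vcf`).
#'
#' @return list with `reference` (string) and `variants` (a
#'   [variant_set()]).
#' @export
table1_fixture <- function() {
  reference <- "TTCTGGGAGGCAGTTACC"
  geno <- matrix(
    c(0L, 0L, 1L, 1L, 0L,   # a
      1L, 1L, 0L, 0L, 1L,   # b
      0L, 0L, 1L, 1L, 0L,   # c
      0L, 0L, 0L, 1L, 1L,   # d
      0L, 1L, 2L, 0L, 0L),  # e
    nrow = 5L, byrow = TRUE,
    dimnames = list(c("a", "b", "c", "d", "e"),
                    paste0("s", 1:5)))
  variants <- variant_set(
    pos = c(1L, 4L, 5L, 12L, 16L),
    id = c("a", "b", "c", "d", "e"),
    ref = c("T", "TGG", "G", "AGTTA", "AC"),
    alt = list("TAA", "AAAAAA", "CC", "T", c("T", "A")),
    geno = geno, reference = reference, chrom = "example")
  list(reference = reference, variants = variants)
}

#' Unit-cost edit (Levenshtein) distance
#'
#' Dynamic-programming distance used to score predicted sequences against
#' the simulated truth.
#'
#' @param a,b nucleotide strings.
#' @return integer distance.
#' @export
edit_distance <- function(a, b) {
  edit_distance_cpp(as.character(a), as.character(b))
}
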