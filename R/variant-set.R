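## Phased variant records plus the per-haplotype allele matrix: the lightweight
## in-memory form of one chromosome of a phased VCF.

#' Construct a phased variant set
#'
#' A `variant_set` holds one chromosome's variant records together with the
#' allele index chosen by every sample chromosome copy (0 = reference).
#' It is the common input of [build_variant_graph()] and the founder
#' reconstruction functions.
#'
#' @param pos integer vector of 1-based reference start positions.
#' @param id character vector of record labels (unique).
#' @param ref character vector of reference alleles.
#' @param alt list of character vectors, the alternative alleles per record.
#' @param geno integer matrix, records x haplotypes; entry `[i, h]` is the
#'   allele index haplotype `h` carries at record `i` (0 = reference allele,
#'   `k` = `alt[[i]][k]`).  Column names are the haplotype labels.
#' @param reference the reference sequence (string) the records refer to.
#' @param chrom chromosome name (metadata only).
#' @return an object of class `variant_set`.
#' @export
variant_set <- function(pos, id, ref, alt, geno, reference, chrom = "chr") {
  reference <- load_sequences(reference)[[1L]]
  n <- length(pos)
  stopifnot(length(id) == n, length(ref) == n, length(alt) == n,
            nrow(geno) == n, !anyDuplicated(id))
  if (!is.list(alt)) alt <- as.list(alt)
  storage.mode(geno) <- "integer"
  R <- nchar(reference)
  check_alphabet(reference, "reference")
  check_alphabet(ref, "REF allele")
  check_alphabet(unlist(alt), "ALT allele")
  if (n == 0L) {
    return(structure(
      list(chrom = chrom, reference = reference, pos = integer(0),
           id = character(0), ref = character(0), alt = list(),
           geno = geno, labels = colnames(geno)),
      class = "variant_set"))
  }
  if (any(pos < 1L)) stop("variant position < 1")
  ends <- pos + nchar(ref)
  if (any(ends > R + 1L)) {
    stop("variant end exceeds reference length at record ",
         id[which(ends > R + 1L)[1L]])
  }
  obs <- substring(reference, pos, ends - 1L)
  if (any(obs != ref)) {
    i <- which(obs != ref)[1L]
    stop("REF allele mismatch with reference at position ", pos[i],
         " (VCF says ", ref[i], ", reference has ", obs[i], ")")
  }
  nalt <- lengths(alt)
  if (any(geno > nalt)) {
    i <- which(rowSums(geno > nalt) > 0L)[1L]
    stop("allele index exceeds ALT count at record ", id[i])
  }
  ## deterministic record order: (start, end, first alt)
  ord <- order(pos, ends, vapply(alt, `[`, "", 1L))
  structure(
    list(chrom = chrom, reference = reference,
         pos = as.integer(pos[ord]), id = id[ord], ref = ref[ord],
         alt = alt[ord], geno = geno[ord, , drop = FALSE],
         labels = colnames(geno)),
    class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d record(s) on %s (R = %d), %d haplotype(s)\n",
              length(x$pos), x$chrom, nchar(x$reference),
              length(x$labels)))
  invisible(x)
}

#' Read phased haplotypes from a VCF file
#'
#' Parses the data lines of one chromosome of a phased VCF into a
#' [variant_set()], expanding every sample's genotype into one allele index
#' per chromosome copy.  Variant end positions are taken as the start plus
#' the REF allele length.
#'
#' @param vcf_path path to a VCF 4.x file (plain or bgzipped).
#' @param chromosome chromosome to extract; `NULL` uses the only chromosome
#'   present (an error if the file has several).
#' @param reference reference sequence: FASTA path, `DNAStringSet` or plain
#'   string.  With a multi-sequence FASTA the `chromosome` record is used.
#' @param strict_phasing if `TRUE` (default), an unphased `/` separator in a
#'   multi-copy genotype is an error; if `FALSE` it is accepted as phased
#'   with a warning.
#' @return a `variant_set`; its `reference` element carries the reference
#'   sequence.
#' @export
read_vcf_haplotypes <- function(vcf_path, chromosome = NULL, reference,
                                strict_phasing = TRUE) {
  refs <- load_sequences(reference)
  vcf <- VariantAnnotation::readVcf(vcf_path)
  seqn <- as.character(GenomicRanges::seqnames(SummarizedExperiment::rowRanges(vcf)))
  if (is.null(chromosome)) {
    chromosome <- unique(seqn)
    if (length(chromosome) > 1L)
      stop("VCF has several chromosomes; pass `chromosome`")
    if (length(chromosome) == 0L) chromosome <- names(refs)[1L] %||% "chr"
  }
  refseq <- if (length(refs) == 1L && is.null(names(refs))) refs[[1L]]
            else if (chromosome %in% names(refs)) refs[[chromosome]]
            else if (length(refs) == 1L) refs[[1L]]
            else stop("chromosome ", chromosome, " not found in reference FASTA")
  keep <- seqn == chromosome
  vcf <- vcf[keep, ]
  n <- nrow(vcf)

  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  if (n == 0L) {
    geno <- matrix(integer(0), nrow = 0L, ncol = length(samples),
                   dimnames = list(NULL, samples))
    return(variant_set(integer(0), character(0), character(0), list(),
                       geno, refseq, chrom = chromosome))
  }

  rr <- SummarizedExperiment::rowRanges(vcf)
  pos <- GenomicRanges::start(rr)
  refa <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt <- lapply(seq_len(n), function(i) {
    a <- as.character(altl[[i]])
    if (any(grepl("[<>\\[\\]]", a)))
      stop("unsupported allele (symbolic/breakend) at position ", pos[i])
    a
  })
  ids <- rownames(gt)
  if (is.null(ids) || anyDuplicated(ids))
    ids <- sprintf("v%d", seq_len(n))

  ## expand genotypes: one integer column per chromosome copy
  warned_unphased <- FALSE
  split_gt <- function(g, record_id) {
    if (is.na(g) || g %in% c(".", "")) return(0L)
    if (grepl("/", g, fixed = TRUE)) {
      if (strict_phasing)
        stop("unphased genotype '", g, "' at record ", record_id,
             " (use strict_phasing = FALSE to accept)")
      if (!warned_unphased) {
        warning("treating unphased genotype '", g, "' at record ", record_id,
                " (and any later ones) as phased", call. = FALSE)
        warned_unphased <<- TRUE
      }
    }
    parts <- strsplit(g, "[|/]")[[1L]]
    parts[parts == "."] <- "0"
    as.integer(parts)
  }
  first <- lapply(samples, function(s) split_gt(gt[1L, s], ids[1L]))
  ploidy <- lengths(first)
  hap_labels <- unlist(lapply(seq_along(samples), function(k) {
    if (ploidy[k] == 1L) samples[k]
    else paste0(samples[k], ".", seq_len(ploidy[k]))
  }))
  geno <- matrix(0L, nrow = n, ncol = length(hap_labels),
                 dimnames = list(ids, hap_labels))
  for (i in seq_len(n)) {
    col0 <- 0L
    for (k in seq_along(samples)) {
      v <- split_gt(gt[i, samples[k]], ids[i])
      if (length(v) != ploidy[k])
        stop("inconsistent ploidy for sample ", samples[k], " at record ", ids[i])
      geno[i, col0 + seq_len(ploidy[k])] <- v
      col0 <- col0 + ploidy[k]
    }
  }
  variant_set(pos, ids, refa, alt, geno, refseq, chrom = chromosome)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
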