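## Projection of variants called against the ad hoc reference back to
## original reference coordinates, plus reporting of the differences the
## ad hoc reference itself embeds, with ploidy-aware genotype arithmetic.

## Internal record form: data frame with columns pos (int), id, ref, alt
## (comma-joined string), gt (character matrix column per sample stored as
## a plain data frame column named gt.<sample>), origin.

gt_nonzero <- function(gt) {
  if (is.na(gt) || gt %in% c(".", "")) return(0L)
  sum(as.integer(strsplit(gt, "[|/]")[[1L]]) > 0L, na.rm = TRUE)
}

format_gt <- function(n_nonzero, ploidy) {
  v <- c(rep(0L, ploidy - n_nonzero), rep(1L, n_nonzero))
  paste(v, collapse = "/")
}

## VCF-convention normalization: trim shared suffix/prefix, shifting left
## through the reference when an allele would empty out.
normalize_variant <- function(pos, ref, alts, reference) {
  repeat {
    lens <- nchar(c(ref, alts))
    lasts <- substring(c(ref, alts), lens, lens)
    if (length(unique(lasts)) == 1L && all(lens > 0L) &&
        (all(lens > 1L) || pos > 1L)) {
      if (all(lens > 1L)) {
        ref <- substring(ref, 1L, nchar(ref) - 1L)
        alts <- substring(alts, 1L, nchar(alts) - 1L)
      } else {
        pos <- pos - 1L
        base <- substring(reference, pos, pos)
        ref <- paste0(base, substring(ref, 1L, nchar(ref) - 1L))
        alts <- paste0(base, substring(alts, 1L, nchar(alts) - 1L))
      }
    } else break
  }
  while (nchar(ref) > 1L && all(nchar(alts) > 1L)) {
    firsts <- substring(c(ref, alts), 1L, 1L)
    if (length(unique(firsts)) != 1L) break
    ref <- substring(ref, 2L)
    alts <- substring(alts, 2L)
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alts = alts)
}

#' Project one called record to original reference coordinates
#'
#' Maps the record's ad hoc interval to MSA columns through the ad hoc map,
#' reads the original reference characters across those columns, and
#' rewrites POS/REF accordingly; ALT and genotypes are kept as called.  A
#' record falling entirely in a region with no reference image (an
#' insertion relative to the reference) is anchored to the preceding
#' reference base, VCF-style.
#'
#' @param pos,ref,alt called record: 1-based ad hoc position, REF string
#'   (ad hoc characters), character vector of ALT strings.
#' @param map an `adhoc_map`.
#' @param reference the original reference sequence (string).
#' @return list with `pos`, `ref`, `alt` (rewritten, left-aligned and
#'   trimmed) and `anchored` (TRUE when insertion anchoring was applied).
#' @export
project_record <- function(pos, ref, alt, map, reference) {
  cols <- map$columns
  p2 <- pos + nchar(ref) - 1L
  if (pos < 1L || p2 > max(cols$adhoc_pos, na.rm = TRUE))
    stop("record at ad hoc position ", pos, " outside the ad hoc reference")
  c1 <- match(pos, cols$adhoc_pos)
  c2 <- match(p2, cols$adhoc_pos)
  span <- cols[c1:c2, , drop = FALSE]
  ref_img <- span$ref_char[span$ref_char != GAP]
  anchored <- FALSE
  if (length(ref_img) == 0L) {
    ## pure insertion relative to the reference: anchor on the left
    before <- cols$ref_pos[seq_len(c1 - 1L)]
    before <- before[!is.na(before)]
    if (length(before) == 0L)
      stop("cannot anchor record at ad hoc position ", pos,
           ": no preceding reference base")
    new_pos <- before[length(before)]
    base <- substring(reference, new_pos, new_pos)
    new_ref <- base
    alt <- paste0(base, alt)
    anchored <- TRUE
  } else {
    new_pos <- span$ref_pos[!is.na(span$ref_pos)][1L]
    new_ref <- paste(ref_img, collapse = "")
  }
  norm <- normalize_variant(new_pos, new_ref, alt, reference)
  list(pos = norm$pos, ref = norm$ref, alt = norm$alts, anchored = anchored)
}

## MSA columns where the ad hoc character differs from the reference,
## converted to normalized VCF-style records.  Column-aligned substitutions
## are reported one SNP per column; runs of gap columns (insertions or
## deletions relative to the reference) are merged into single anchored
## indel records.
adhoc_reference_diffs <- function(map, reference) {
  cols <- map$columns
  diff <- cols$ref_char != cols$adhoc_char
  if (!any(diff)) {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  indel <- diff & (cols$ref_char == GAP | cols$adhoc_char == GAP)
  sub <- diff & !indel
  r <- rle(indel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  runs <- rbind(runs, cbind(which(sub), which(sub)))
  if (nrow(runs) > 1L) runs <- runs[order(runs[, 1L]), , drop = FALSE]
  out <- lapply(seq_len(nrow(runs)), function(k) {
    span <- cols[runs[k, 1L]:runs[k, 2L], , drop = FALSE]
    ref_str <- paste(span$ref_char[span$ref_char != GAP], collapse = "")
    alt_str <- paste(span$adhoc_char[span$adhoc_char != GAP], collapse = "")
    refp <- span$ref_pos[!is.na(span$ref_pos)]
    if (nchar(ref_str) == 0L || nchar(alt_str) == 0L) {
      ## indel: anchor on the preceding reference base
      before <- cols$ref_pos[seq_len(runs[k, 1L] - 1L)]
      before <- before[!is.na(before)]
      if (length(before) == 0L) {
        ## run at the very start: anchor on the following base instead
        after <- cols$ref_pos[runs[k, 2L]:nrow(cols)]
        after <- after[!is.na(after)]
        apos <- after[1L]
        base <- substring(reference, apos, apos)
        pos <- if (length(refp) > 0L) refp[1L] else apos
        ref_str <- paste0(ref_str, base)
        alt_str <- paste0(alt_str, base)
      } else {
        pos <- before[length(before)]
        base <- substring(reference, pos, pos)
        ref_str <- paste0(base, ref_str)
        alt_str <- paste0(base, alt_str)
      }
    } else {
      pos <- refp[1L]
    }
    norm <- normalize_variant(pos, ref_str, alt_str, reference)
    data.frame(pos = norm$pos, ref = norm$ref, alt = norm$alts,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Report variants embedded in the ad hoc reference
#'
#' Every difference between the ad hoc reference and the original reference
#' that is not already explained by a projected caller record is emitted
#' with all chromosome copies set to the alternative.  Where a caller
#' record overlaps the difference, the caller's non-zero genotype values
#' are counted and subtracted from the ploidy; the embedded record gets
#' that many non-zero genotype values (per sample).
#'
#' @param map an `adhoc_map`.
#' @param projected data frame of projected caller records (columns `pos`,
#'   `ref`, `alt`, one `gt.<sample>` column per sample), as produced inside
#'   [project_vcf()]; may be `NULL` or empty.
#' @param reference original reference sequence (string).
#' @param ploidy number of chromosome copies (1 = haploid, 2 = diploid).
#' @param samples sample names; defaults to those of `projected`, or
#'   `"SAMPLE"` when there are none.
#' @return data frame of embedded records (`pos`, `ref`, `alt`,
#'   `gt.<sample>` columns, `origin = "embedded"`).
#' @export
emit_embedded_variants <- function(map, projected, reference, ploidy = 2L,
                                   samples = NULL) {
  diffs <- adhoc_reference_diffs(map, reference)
  if (is.null(samples)) {
    samples <- if (!is.null(projected))
      sub("^gt\\.", "", grep("^gt\\.", names(projected), value = TRUE))
    else character(0)
    if (length(samples) == 0L) samples <- "SAMPLE"
  }
  if (nrow(diffs) == 0L) {
    out <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
    for (s in samples) out[[paste0("gt.", s)]] <- character(0)
    out$origin <- character(0)
    return(out)
  }
  gts <- matrix("", nrow = nrow(diffs), ncol = length(samples),
                dimnames = list(NULL, samples))
  for (i in seq_len(nrow(diffs))) {
    iv <- c(diffs$pos[i], diffs$pos[i] + nchar(diffs$ref[i]) - 1L)
    for (s in samples) {
      nz <- 0L
      if (!is.null(projected) && nrow(projected) > 0L) {
        ov <- projected$pos <= iv[2L] &
          (projected$pos + nchar(projected$ref) - 1L) >= iv[1L]
        if (any(ov)) {
          col <- paste0("gt.", s)
          vals <- if (col %in% names(projected)) projected[[col]][ov] else character(0)
          nz <- sum(vapply(vals, gt_nonzero, 0L))
        }
      }
      gts[i, s] <- format_gt(max(ploidy - nz, 0L), ploidy)
    }
  }
  out <- diffs
  for (s in samples) out[[paste0("gt.", s)]] <- gts[, s]
  out$origin <- "embedded"
  out
}

## Parse a called VCF (path or data frame) into the internal record form.
read_call_records <- function(calls) {
  if (is.data.frame(calls)) return(calls)
  vcf <- VariantAnnotation::readVcf(calls)
  n <- nrow(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  samples <- colnames(gt)
  if (n == 0L) {
    out <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE)
    for (s in samples) out[[paste0("gt.", s)]] <- character(0)
    return(out)
  }
  out <- data.frame(
    pos = GenomicRanges::start(SummarizedExperiment::rowRanges(vcf)),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = vapply(seq_len(n), function(i)
      paste(as.character(VariantAnnotation::alt(vcf)[[i]]), collapse = ","),
      ""),
    stringsAsFactors = FALSE)
  for (s in samples) out[[paste0("gt.", s)]] <- as.character(gt[, s])
  out
}

#' Project a called VCF to original reference coordinates
#'
#' Projects every caller record through the ad hoc map, appends the
#' embedded ad hoc/reference differences with ploidy-subtraction genotypes,
#' and returns (and optionally writes) the merged, coordinate-sorted set.
#'
#' @param calls called VCF: a path or a record data frame (columns `pos`,
#'   `ref`, `alt`, `gt.<sample>` ...), with coordinates on the ad hoc
#'   reference.
#' @param map an `adhoc_map` (or path to one written by
#'   [write_adhoc_map()]).
#' @param reference original reference (string, `DNAStringSet` or FASTA
#'   path).
#' @param ploidy chromosome copies per sample (default 2; use 1 for
#'   haploid data).
#' @param out optional output VCF path.
#' @param chrom chromosome name for the output VCF.
#' @return data frame of projected caller records plus embedded records,
#'   sorted by position, with an `origin` column.
#' @export
project_vcf <- function(calls, map, reference, ploidy = 2L, out = NULL,
                        chrom = "chr") {
  reference <- load_sequences(reference)[[1L]]
  if (is.character(map)) map <- read_adhoc_map(map)
  recs <- read_call_records(calls)
  gt_cols <- grep("^gt\\.", names(recs), value = TRUE)
  projected <- recs[0, , drop = FALSE]
  if (nrow(recs) > 0L) {
    if (is.unsorted(recs$pos)) {
      warning("called records not coordinate-sorted; sorting")
      recs <- recs[order(recs$pos), , drop = FALSE]
    }
    plist <- lapply(seq_len(nrow(recs)), function(i) {
      alts <- strsplit(recs$alt[i], ",", fixed = TRUE)[[1L]]
      pr <- project_record(recs$pos[i], recs$ref[i], alts, map, reference)
      row <- data.frame(pos = pr$pos, ref = pr$ref,
                        alt = paste(pr$alt, collapse = ","),
                        stringsAsFactors = FALSE)
      for (col in gt_cols) row[[col]] <- recs[[col]][i]
      row
    })
    projected <- do.call(rbind, plist)
  }
  if (nrow(projected) > 0L) projected$origin <- "caller"
  embedded <- emit_embedded_variants(map, projected, reference, ploidy,
                                     samples = if (length(gt_cols))
                                       sub("^gt\\.", "", gt_cols) else NULL)
  common <- union(names(projected), names(embedded))
  for (col in setdiff(common, names(projected))) projected[[col]] <- character(0)
  merged <- rbind(projected[, common, drop = FALSE],
                  embedded[, common, drop = FALSE])
  merged <- merged[order(merged$pos, merged$ref, merged$alt), , drop = FALSE]
  rownames(merged) <- NULL
  if (!is.null(out)) {
    write_simple_vcf(merged, out, chrom = chrom,
                     contig_length = nchar(reference),
                     samples = sub("^gt\\.", "",
                                   grep("^gt\\.", names(merged), value = TRUE)),
                     info = paste0("ORIGIN=", merged$origin))
  }
  merged
}
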