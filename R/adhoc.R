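## Support-matrix accumulation from read alignments and heaviest-path ad hoc
## reference extraction.  Row 1 of the founder MSA must be the gapped
## original reference ("REF"): with zero support the per-column argmax tie
## rule (lowest row index) then reproduces the reference exactly.

#' Map an ungapped founder position to its MSA column
#'
#' @param msa a `ref_msa` (founder alignment, typically from
#'   [emit_founders()] with `include_reference = TRUE`).
#' @param row row label or index.
#' @param position 1-based position in the row's ungapped sequence.
#' @return 1-based MSA column of that position's character.
#' @export
founder_to_msa_column <- function(msa, row, position) {
  cc <- chars(msa$rows[[row]])
  ng <- which(cc != GAP)
  if (any(position < 1L | position > length(ng)))
    stop("position out of range for row ", row)
  ng[position]
}

#' Map an MSA column to an ungapped row position
#'
#' Inverse of [founder_to_msa_column()].
#'
#' @inheritParams founder_to_msa_column
#' @param column 1-based MSA column.
#' @return 1-based ungapped position, or `NA` if the row has a gap there.
#' @export
msa_column_to_position <- function(msa, row, column) {
  cc <- chars(msa$rows[[row]])
  if (any(column < 1L | column > length(cc)))
    stop("column out of range")
  pos <- cumsum(cc != GAP)
  ifelse(cc[column] == GAP, NA_integer_, pos[column])
}

#' Read best alignments from a SAM/BAM file
#'
#' Keeps one best alignment per read (per mate for paired data): unmapped,
#' secondary and supplementary records are dropped, then the record with the
#' highest aligner score (`AS` tag), breaking ties by mapping quality and
#' then file order, is retained.
#'
#' @param path SAM or BAM file (SAM is converted in a temporary directory).
#' @return data frame with columns `qname`, `rname`, `pos`, `end`
#'   (reference-space interval from the CIGAR), `mapq`, `score`.
#' @export
read_best_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "AS")
  b <- Rsamtools::scanBam(path, param = p)[[1L]]
  score <- b$tag$AS
  if (is.null(score)) score <- rep(NA_integer_, length(b$qname))
  df <- data.frame(qname = b$qname, flag = b$flag,
                   rname = as.character(b$rname), pos = b$pos,
                   mapq = b$mapq, cigar = b$cigar, score = score,
                   stringsAsFactors = FALSE)
  keep <- !bitwAnd(df$flag, 4L) & !bitwAnd(df$flag, 256L) &
    !bitwAnd(df$flag, 2048L)
  df <- df[keep & !is.na(df$pos), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(qname = character(0), rname = character(0),
                      pos = integer(0), end = integer(0),
                      mapq = integer(0), score = integer(0)))
  }
  mate <- ifelse(bitwAnd(df$flag, 64L) > 0L, "/1",
                 ifelse(bitwAnd(df$flag, 128L) > 0L, "/2", ""))
  df$read <- paste0(df$qname, mate)
  df$width <- GenomicAlignments::cigarWidthAlongReferenceSpace(df$cigar)
  ## best per read: score desc, then mapq desc, then file order
  df$ord <- seq_len(nrow(df))
  df <- df[order(df$read, -ifelse(is.na(df$score), -Inf, df$score),
                 -df$mapq, df$ord), ]
  df <- df[!duplicated(df$read), ]
  df <- df[order(df$ord), ]
  data.frame(qname = df$read, rname = df$rname, pos = df$pos,
             end = df$pos + df$width - 1L, mapq = df$mapq,
             score = df$score, stringsAsFactors = FALSE)
}

#' Accumulate the support matrix from best alignments
#'
#' For every read whose best alignment spans founder positions `p..q` on
#' row `i`, the MSA columns `col(p)..col(q)` of row `i` are incremented
#' (gap columns inside the range included).  Alignments to kernel pieces
#' are first lifted to founder coordinates through the kernel map.
#'
#' @param alignments data frame from [read_best_alignments()] (or any data
#'   frame with `rname`, `pos`, `end`).
#' @param msa founder `ref_msa` whose first row is the gapped reference.
#' @param kernel_map optional [build_kernel()] result (or
#'   [read_kernel_map()] output) when the alignments target kernel pieces;
#'   piece provenance indexes the founder rows *after* the reference row,
#'   i.e. kernel founder `k` is MSA row `k + 1`.
#' @return integer matrix, rows = MSA rows (named), columns = MSA columns.
#' @export
accumulate_support <- function(alignments, msa, kernel_map = NULL) {
  m <- length(msa$rows)
  n <- msa$width
  M <- matrix(0L, nrow = m, ncol = n, dimnames = list(msa$labels, NULL))
  if (is.null(alignments) || nrow(alignments) == 0L) return(M)
  piece_ids <- if (!is.null(kernel_map)) {
    if (!is.null(kernel_map$provenance$piece_id)) kernel_map$provenance$piece_id
    else kernel_piece_ids(kernel_map)
  }
  ng_cols <- lapply(msa$rows, function(r) which(chars(r) != GAP))
  for (i in seq_len(nrow(alignments))) {
    rn <- alignments$rname[i]
    p <- alignments$pos[i]; q <- alignments$end[i]
    if (!is.null(kernel_map) && rn %in% piece_ids) {
      k <- match(rn, piece_ids)
      pr <- kernel_map$provenance
      if (q > pr$length[k]) q <- pr$length[k]   # clamp to the piece
      row <- pr$seq[k] + 1L                      # reference is row 1
      p <- pr$start[k] + p - 1L
      q <- pr$start[k] + q - 1L
    } else {
      row <- match(rn, msa$labels)
      if (is.na(row)) stop("alignment to unknown sequence: ", rn)
    }
    if (q < p) { warning("zero-length alignment span ignored"); next }
    ng <- ng_cols[[row]]
    if (p < 1L || q > length(ng)) { warning("alignment beyond row length ignored"); next }
    M[row, ng[p]:ng[q]] <- M[row, ng[p]:ng[q]] + 1L
  }
  M
}

#' Extract the heaviest-path ad hoc reference
#'
#' For every MSA column the row with maximal support is chosen (ties go to
#' the lowest row index, so the original reference wins at zero coverage)
#' and its character appended to the ad hoc reference unless it is a gap.
#' The result carries the three-way coordinate map between ad hoc
#' positions, MSA columns and original reference positions.
#'
#' @param M support matrix from [accumulate_support()].
#' @param msa founder `ref_msa` whose first row (`"REF"`) is the gapped
#'   original reference.
#' @return object of class `adhoc_map`: list with `sequence` (the ad hoc
#'   reference), and `columns` (data frame: `column`, `chosen_row`,
#'   `ref_pos`, `adhoc_pos`, `ref_char`, `adhoc_char`; positions are `NA`
#'   where the respective row has a gap).
#' @export
heaviest_path <- function(M, msa) {
  stopifnot(nrow(M) == length(msa$rows), ncol(M) == msa$width)
  if (msa$labels[1L] != "REF")
    stop("the first MSA row must be the reference (label 'REF')")
  chosen <- apply(M, 2L, which.max)           # first max = lowest row index
  row_chars <- lapply(msa$rows, chars)
  adhoc_char <- vapply(seq_len(msa$width),
                       function(j) row_chars[[chosen[j]]][j], "")
  ref_char <- row_chars[[1L]]
  adhoc_pos <- ifelse(adhoc_char == GAP, NA_integer_,
                      cumsum(adhoc_char != GAP))
  ref_pos <- ifelse(ref_char == GAP, NA_integer_, cumsum(ref_char != GAP))
  structure(
    list(sequence = paste(adhoc_char[adhoc_char != GAP], collapse = ""),
         columns = data.frame(column = seq_len(msa$width),
                              chosen_row = as.integer(chosen),
                              ref_pos = as.integer(ref_pos),
                              adhoc_pos = as.integer(adhoc_pos),
                              ref_char = ref_char,
                              adhoc_char = adhoc_char,
                              stringsAsFactors = FALSE)),
    class = "adhoc_map")
}

#' @export
print.adhoc_map <- function(x, ...) {
  cat(sprintf("adhoc_map: %d MSA column(s), ad hoc length %d\n",
              nrow(x$columns), nchar(x$sequence)))
  invisible(x)
}

#' Write / read the ad hoc coordinate map (TSV)
#'
#' @param map an `adhoc_map`.
#' @param path tab-separated file (column, chosen_row, ref_pos, adhoc_pos,
#'   ref_char, adhoc_char).
#' @return `path` (writer) or the reconstructed `adhoc_map` (reader).
#' @export
write_adhoc_map <- function(map, path) {
  utils::write.table(map$columns, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_adhoc_map
#' @export
read_adhoc_map <- function(path) {
  cols <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = ".")
  cols$ref_char[is.na(cols$ref_char)] <- GAP
  cols$adhoc_char[is.na(cols$adhoc_char)] <- GAP
  structure(
    list(sequence = paste(cols$adhoc_char[cols$adhoc_char != GAP],
                          collapse = ""),
         columns = cols),
    class = "adhoc_map")
}

#' Write the ad hoc reference FASTA
#' @param map an `adhoc_map`.
#' @param path output FASTA.
#' @param name FASTA record name.
#' @return `path`, invisibly.
#' @export
write_adhoc_fasta <- function(map, path, name = "adhoc") {
  write_fasta(setNames(map$sequence, name), path)
}
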