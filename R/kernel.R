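## LZ77-compatible parsing of the founder set and kernel construction: the
## middles of long copying phrases are excised, keeping only the first and
## last P characters, because any read of length <= P overlapping the
## excised middle also occurs at the phrase's earlier source.

#' LZ77-compatible parse of a sequence set
#'
#' Greedy left-to-right factorization of the concatenation: at each position
#' the longest substring with an occurrence starting strictly earlier is
#' taken as a copying phrase (sources may not overlap their target nor cross
#' a sequence boundary); positions with no earlier occurrence become
#' literals, with adjacent single-character literals merged into runs.
#'
#' @param sequences character vector (or `DNAStringSet`) over `{A,C,G,T,N}`.
#' @return data frame of class `lz_parse` with columns `kind`
#'   (`"literal"`/`"copy"`), `seq` (1-based input sequence index), `start`
#'   (1-based position within that sequence), `length`, and `src` (1-based
#'   position of the copy source in the boundary-free concatenation; NA for
#'   literals).
#' @export
lz_parse <- function(sequences) {
  sequences <- unname(load_sequences(sequences))
  if (length(sequences) == 0L || all(nchar(sequences) == 0L)) {
    out <- data.frame(kind = character(0), seq = integer(0),
                      start = integer(0), length = integer(0),
                      src = integer(0))
    class(out) <- c("lz_parse", "data.frame")
    return(out)
  }
  m <- lz_parse_cpp(sequences)
  out <- data.frame(kind = c("literal", "copy")[m[, "kind"]],
                    seq = m[, "seq"], start = m[, "start"],
                    length = m[, "length"], src = m[, "src"])
  attr(out, "sequences") <- sequences
  class(out) <- c("lz_parse", "data.frame")
  out
}

#' Decode an LZ parse back to the input sequences
#'
#' @param parse an [lz_parse()] result.
#' @param sequences the original sequences (only literal text and copy
#'   sources are read from them; defaults to the set stored on the parse).
#' @return character vector of decoded sequences.
#' @export
lz_decode <- function(parse, sequences = attr(parse, "sequences")) {
  if (nrow(parse) == 0L) return(character(0))
  concat <- paste(sequences, collapse = "")
  offs <- cumsum(c(0L, nchar(sequences)))  # global offset of each sequence
  out <- rep("", length(sequences))
  decoded <- ""
  for (i in seq_len(nrow(parse))) {
    s <- parse$seq[i]
    g <- offs[s] + parse$start[i]          # global target start
    piece <- if (parse$kind[i] == "literal") {
      substring(concat, g, g + parse$length[i] - 1L)
    } else {
      substring(decoded, parse$src[i], parse$src[i] + parse$length[i] - 1L)
    }
    decoded <- paste0(decoded, piece)
    out[s] <- paste0(out[s], piece)
  }
  out
}

#' Build the kernel sequence with the 2P excision rule
#'
#' Literal phrases and copying phrases of length at most `2 * P` are
#' retained whole; a longer copying phrase contributes only its first and
#' last `P` characters as detached pieces.  A phrase whose copy source is
#' not fully intact in the retained text (because an earlier excision cut
#' through it) is kept whole, so that every substring of length at most `P`
#' of every input sequence survives in some kernel piece.  Contiguous
#' retained runs are merged into single pieces with provenance.
#'
#' @param parse an [lz_parse()] result (with its sequences attribute).
#' @param P read length parameter (>= 1).
#' @return object of class `kernel_map`: list with `P`, `pieces` (character
#'   vector of kernel pieces in input order), and `provenance` (data frame
#'   `piece`, `seq`, `start`, `length`: each piece's source founder index
#'   and 1-based start offset).  `sum(nchar(pieces))` never exceeds the
#'   total input length.
#' @export
build_kernel <- function(parse, P) {
  stopifnot(P >= 1)
  sequences <- attr(parse, "sequences")
  offs <- cumsum(c(0L, nchar(sequences)))
  n_total <- sum(nchar(sequences))
  if (nrow(parse) == 0L) {
    return(structure(list(P = as.integer(P), pieces = character(0),
                          provenance = data.frame(piece = integer(0),
                                                  seq = integer(0),
                                                  start = integer(0),
                                                  length = integer(0)),
                          sequences = sequences),
                     class = "kernel_map"))
  }

  ## retained intervals in global coordinates; breaks mark detachment points
  retained <- logical(n_total)
  broken_after <- logical(n_total)   # piece boundary after this position
  for (i in seq_len(nrow(parse))) {
    g <- offs[parse$seq[i]] + parse$start[i]
    len <- parse$length[i]
    excise <- FALSE
    if (parse$kind[i] == "copy" && len > 2L * P) {
      src <- parse$src[i]
      src_range <- src:(src + len - 1L)
      source_intact <- all(retained[src_range]) &&
        !any(broken_after[src_range[-length(src_range)]])
      excise <- source_intact
    }
    if (excise) {
      retained[g:(g + P - 1L)] <- TRUE
      retained[(g + len - P):(g + len - 1L)] <- TRUE
      broken_after[g + P - 1L] <- TRUE
      broken_after[g + len - P - 1L] <- TRUE
    } else {
      retained[g:(g + len - 1L)] <- TRUE
    }
  }
  ## sequence boundaries always detach
  broken_after[offs[-1L][offs[-1L] >= 1L & offs[-1L] <= n_total]] <- TRUE

  ## enumerate maximal retained runs not crossing a break
  runs <- list()
  i <- 1L
  while (i <= n_total) {
    if (!retained[i]) { i <- i + 1L; next }
    j <- i
    while (j < n_total && retained[j + 1L] && !broken_after[j]) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(i, j)
    i <- j + 1L
  }
  concat <- paste(sequences, collapse = "")
  pieces <- vapply(runs, function(r) substring(concat, r[1L], r[2L]), "")
  prov <- do.call(rbind, lapply(seq_along(runs), function(k) {
    r <- runs[[k]]
    s <- max(which(offs < r[1L]))  # sequence index of the run start
    data.frame(piece = k, seq = s, start = r[1L] - offs[s],
               length = r[2L] - r[1L] + 1L)
  }))
  structure(list(P = as.integer(P), pieces = pieces, provenance = prov,
                 sequences = sequences),
            class = "kernel_map")
}

#' @export
print.kernel_map <- function(x, ...) {
  cat(sprintf("kernel_map: P = %d, %d piece(s), kernel length %d / input %d\n",
              x$P, length(x$pieces), sum(nchar(x$pieces)),
              sum(nchar(x$sequences))))
  invisible(x)
}

#' Lift a kernel position back to its founder position
#'
#' Inverse of the piece construction: maps a 1-based offset within a kernel
#' piece to the (founder index, founder position) it was copied from.
#'
#' @param map a [build_kernel()] result.
#' @param piece piece index (or piece id string `"piece<k>_..."`).
#' @param offset 1-based offset within the piece.
#' @return list with `seq` (founder index) and `pos` (1-based founder
#'   position).
#' @export
lift_kernel_position <- function(map, piece, offset) {
  if (is.character(piece)) piece <- match(piece, kernel_piece_ids(map))
  pr <- map$provenance
  if (is.na(piece) || piece < 1L || piece > nrow(pr)) stop("unknown kernel piece")
  if (offset < 1L || offset > pr$length[piece])
    stop("offset out of range for kernel piece ", piece)
  list(seq = pr$seq[piece], pos = pr$start[piece] + offset - 1L)
}

kernel_piece_ids <- function(map) {
  sprintf("piece%d_f%d_%d_%d", map$provenance$piece, map$provenance$seq,
          map$provenance$start, map$provenance$length)
}

#' Write kernel pieces as multi-record FASTA
#'
#' One record per detached piece; record ids encode provenance as
#' `piece<k>_f<founder>_<start>_<length>`.
#'
#' @param map a `kernel_map`.
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_kernel_fasta <- function(map, path) {
  write_fasta(setNames(map$pieces, kernel_piece_ids(map)), path)
}

#' Write / read the kernel provenance map (TSV)
#'
#' @param map a `kernel_map`.
#' @param path tab-separated file with columns piece id, founder index,
#'   start, length (plus P on the first comment line).
#' @return `path` (writer) or a reduced `kernel_map` (reader: no piece
#'   strings, provenance only).
#' @export
write_kernel_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#P=%d", map$P), con)
  utils::write.table(
    data.frame(piece_id = kernel_piece_ids(map), seq = map$provenance$seq,
               start = map$provenance$start, length = map$provenance$length),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel_map
#' @export
read_kernel_map <- function(path) {
  first <- readLines(path, n = 1L)
  P <- as.integer(sub("#P=", "", first))
  tab <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  structure(list(P = P, pieces = NULL,
                 provenance = data.frame(piece = seq_len(nrow(tab)),
                                         seq = tab$seq, start = tab$start,
                                         length = tab$length,
                                         piece_id = tab$piece_id),
                 sequences = NULL),
            class = "kernel_map")
}
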