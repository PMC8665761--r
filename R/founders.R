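## Founder reconstruction: bridge detection, minimum-founder segmentation by
## dynamic programming over bridge nodes, and greedy bipartite joining of
## per-segment distinct subsequences into founder rows.

#' Find bridge edges and bridge nodes
#'
#' A bridge is a reference edge shared by every path from the first node to
#' the last; equivalently, no alternative edge spans across it.  A bridge
#' node has a bridge as in-edge or out-edge; bridge nodes are the only legal
#' segmentation cut points.
#'
#' @param graph a `variant_graph`.
#' @return list with `bridges` (data frame `from`, `to`) and `nodes`
#'   (ordered integer vector Q of bridge-node coordinates).
#' @export
find_bridge_nodes <- function(graph) {
  e <- graph$edges
  re <- e[e$kind == "reference", c("from", "to")]
  alt <- e[e$kind == "alternative", c("from", "to")]
  spanned <- vapply(seq_len(nrow(re)), function(i) {
    any(alt$from < re$to[i] & alt$to > re$from[i])
  }, TRUE)
  bridges <- re[!spanned, , drop = FALSE]
  rownames(bridges) <- NULL
  list(bridges = bridges,
       nodes = sort(unique(c(bridges$from, bridges$to))))
}

## Restrict an edge path to the half-open node interval [a, b); because cuts
## are bridge nodes, no edge crosses a or b.
restrict_path <- function(graph, path, a, b) {
  from <- graph$edges$from[path]
  path[from >= a & from < b]
}

restricted_string <- function(graph, path, a, b) {
  paste(graph$edges$label[restrict_path(graph, path, a, b)], collapse = "")
}

#' Distinct subsequences of a segment with occurrence counts
#'
#' Restricts every input path (reference included) to the node interval
#' `[a, b)` and tallies the distinct label concatenations; the table size is
#' the segment's unique path count `d(a, b)`.
#'
#' @param graph a `variant_graph`.
#' @param paths named list of edge paths as from [haplotype_paths()]
#'   (include the reference path to match the founder-counting convention).
#' @param a,b bridge-node (or boundary) coordinates, `a < b`.
#' @return named integer vector: distinct subsequence -> occurrence count,
#'   sorted by decreasing count, ties broken lexicographically.
#' @export
distinct_segment_paths <- function(graph, paths, a, b) {
  stopifnot(a < b)
  cuts_ok <- c(1L, find_bridge_nodes(graph)$nodes, graph$R + 1L)
  if (!(a %in% cuts_ok) || !(b %in% cuts_ok))
    stop("segment boundaries must be bridge nodes or the graph boundaries")
  s <- vapply(paths, restricted_string, "", graph = graph, a = a, b = b)
  tab <- table(s)
  cnt <- as.integer(tab)
  nm <- names(tab)
  ord <- order(-cnt, nm)
  setNames(cnt[ord], nm[ord])
}

## d(a, b) without the bridge-boundary check (internal, used by the DP).
d_count <- function(graph, paths, a, b) {
  length(unique(vapply(paths, restricted_string, "", graph = graph,
                       a = a, b = b)))
}

#' Optimal bridge-node segmentation
#'
#' Chooses cut positions among the bridge nodes so that every segment spans
#' at least `L` reference positions and the maximum per-segment number of
#' distinct subsequences is minimized:
#' `D(r) = min over q in Q with r - q >= L, q - 1 >= L of max(D(q), d(q, r))`,
#' with the no-cut single segment always available as a fallback.  Among
#' segmentations of equal value the one whose final segment was cut most
#' recently (rightmost last cut) is chosen, applied recursively.
#'
#' @param graph a `variant_graph`.
#' @param paths named list of edge paths (reference included), as from
#'   [haplotype_paths()].
#' @param L minimum segment size in reference positions (>= 1).
#' @return object of class `segmentation`: list with `L`, `cuts` (ordered
#'   bridge-node coordinates; may be empty), `segments` (data frame `start`,
#'   `end`, `size`, `d`; half-open `[start, end)` intervals partitioning
#'   `[1, R + 1)`) and `D_value` (the minimized objective).
#' @export
optimal_segmentation <- function(graph, paths, L) {
  stopifnot(L >= 1)
  Rp1 <- graph$R + 1L
  Q <- find_bridge_nodes(graph)$nodes
  cand <- Q[Q > 1L & Q < Rp1]                 # interior cut candidates
  targets <- sort(unique(c(cand, Rp1)))

  dmemo <- new.env(parent = emptyenv())
  dval <- function(a, b) {
    key <- paste(a, b)
    if (is.null(dmemo[[key]])) dmemo[[key]] <- d_count(graph, paths, a, b)
    dmemo[[key]]
  }

  D <- setNames(rep(NA_integer_, length(targets)), targets)
  lastcut <- setNames(rep(1L, length(targets)), targets)  # 1 = no cut
  for (r in targets) {
    best_val <- dval(1L, r)                   # no-cut fallback
    best_q <- 1L
    qs <- cand[cand < r & (r - cand) >= L & (cand - 1L) >= L]
    for (q in qs) {
      val <- max(D[[as.character(q)]], dval(q, r))
      ## strict improvement, or tie with a more recent (larger) last cut
      if (val < best_val || (val == best_val && q > best_q)) {
        best_val <- val
        best_q <- q
      }
    }
    D[[as.character(r)]] <- best_val
    lastcut[[as.character(r)]] <- best_q
  }

  cuts <- integer(0)
  r <- Rp1
  while (lastcut[[as.character(r)]] > 1L) {
    q <- lastcut[[as.character(r)]]
    cuts <- c(q, cuts)
    r <- q
  }
  bounds <- c(1L, cuts, Rp1)
  segments <- data.frame(
    start = bounds[-length(bounds)], end = bounds[-1L])
  segments$size <- segments$end - segments$start
  segments$d <- mapply(dval, segments$start, segments$end)
  structure(list(L = L, cuts = cuts, segments = segments,
                 D_value = unname(D[[as.character(Rp1)]])),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: L = %d, D = %d, cuts at {%s}\n", x$L, x$D_value,
              paste(x$cuts, collapse = ", ")))
  print(x$segments)
  invisible(x)
}

## Distinct-subsequence table of one segment with a representative edge path
## per distinct string (first path observed, REF-first order).
segment_table <- function(graph, paths, a, b) {
  s <- vapply(paths, restricted_string, "", graph = graph, a = a, b = b)
  counts <- distinct_segment_paths(graph, paths, a, b)
  rep_paths <- lapply(names(counts), function(str) {
    restrict_path(graph, paths[[which(s == str)[1L]]], a, b)
  })
  list(strings = names(counts), counts = unname(counts), paths = rep_paths)
}

#' Greedily join segment paths into founder slot chains
#'
#' Processes consecutive segment pairs left to right.  For each pair a
#' bipartite graph with `f` slots per side is built: each distinct
#' subsequence of either segment occupies one slot, remaining slots are
#' available.  Distinct subsequences of the concatenated window are visited
#' in descending occurrence order (ties broken lexicographically); a window
#' joins its two slots when both are unconnected, is rerouted to an
#' available slot when one side is taken, and is skipped otherwise.
#' Leftover slots are paired in ascending index.  Slots still without a
#' subsequence are filled by cyclic duplication in descending count order
#' (`fill = "duplicate"`, default) or left for N-fill (`fill = "N"`).
#'
#' @param graph a `variant_graph`.
#' @param paths named list of edge paths (reference included).
#' @param segmentation a [optimal_segmentation()] result.
#' @param f founder count; default and minimum is the maximum per-segment
#'   distinct-subsequence count (the segmentation's `D_value` bound).
#' @param fill `"duplicate"` or `"N"`.
#' @return object of class `founder_set`: list with `f`, `fill`,
#'   `segments`, `tables` (per-segment distinct subsequences, counts and
#'   representative paths) and `assignment` (f x n_segments integer matrix
#'   of indices into each segment's table; NA = N-fill slot).
#' @export
greedy_join <- function(graph, paths, segmentation, f = NULL,
                        fill = c("duplicate", "N")) {
  fill <- match.arg(fill)
  segs <- segmentation$segments
  ns <- nrow(segs)
  tables <- lapply(seq_len(ns), function(k)
    segment_table(graph, paths, segs$start[k], segs$end[k]))
  dmax <- max(vapply(tables, function(t) length(t$strings), 0L))
  if (is.null(f)) f <- dmax
  if (f < dmax)
    stop("f = ", f, " is below the minimum founder count ", dmax,
         " (the segmentation's distinct-subsequence bound)")

  ## per-haplotype restriction strings per segment, for window counting
  hap_strings <- vapply(seq_len(ns), function(k) {
    vapply(paths, restricted_string, "", graph = graph,
           a = segs$start[k], b = segs$end[k])
  }, character(length(paths)))
  if (length(paths) == 1L)
    hap_strings <- matrix(hap_strings, nrow = 1L,
                          dimnames = list(names(paths), NULL))

  assignment <- matrix(NA_integer_, nrow = f, ncol = ns)
  assignment[seq_along(tables[[1L]]$strings), 1L] <-
    seq_along(tables[[1L]]$strings)

  fill_column <- function(col, k) {
    nas <- which(is.na(col))
    if (fill == "duplicate" && length(nas) > 0L) {
      nd <- length(tables[[k]]$strings)
      col[nas] <- ((seq_along(nas) - 1L) %% nd) + 1L
    }
    col
  }

  if (ns > 1L) {
    for (k in seq_len(ns - 1L)) {
      S <- assignment[, k]                 # slot -> index into tables[[k]]
      Tn <- rep(NA_integer_, f)            # slot -> index into tables[[k+1]]
      dT <- length(tables[[k + 1L]]$strings)
      Tn[seq_len(dT)] <- seq_len(dT)
      Sconn <- logical(f); Tconn <- logical(f)
      match_to <- rep(NA_integer_, f)      # S slot -> T slot

      ## windows: distinct (left, right) string pairs with counts
      ws <- hap_strings[, k]; wt <- hap_strings[, k + 1L]
      key <- paste(ws, wt, sep = "\x01")
      tab <- table(key)
      ord <- order(-as.integer(tab), names(tab))
      wins <- strsplit(names(tab)[ord], "\x01", fixed = TRUE)

      pick_slot <- function(side_assign, conn, idx) {
        ## unconnected slot already holding the string, else available slot
        hit <- which(!conn & !is.na(side_assign) & side_assign == idx)
        if (length(hit) > 0L) return(list(slot = hit[1L], assign = FALSE))
        avail <- which(!conn & is.na(side_assign))
        if (length(avail) > 0L) return(list(slot = avail[1L], assign = TRUE))
        NULL
      }

      for (w in wins) {
        si_idx <- match(w[1L], tables[[k]]$strings)
        ti_idx <- match(w[2L], tables[[k + 1L]]$strings)
        ps <- pick_slot(S, Sconn, si_idx)
        pt <- pick_slot(Tn, Tconn, ti_idx)
        if (is.null(ps) || is.null(pt)) next
        if (ps$assign) S[ps$slot] <- si_idx
        if (pt$assign) Tn[pt$slot] <- ti_idx
        Sconn[ps$slot] <- TRUE; Tconn[pt$slot] <- TRUE
        match_to[ps$slot] <- pt$slot
      }
      ## remaining slots connected deterministically in ascending index
      match_to[which(!Sconn)] <- which(!Tconn)

      assignment[, k] <- fill_column(S, k)
      ## permute the T side so that chains align row-wise
      nxt <- rep(NA_integer_, f)
      nxt[seq_len(f)] <- Tn[match_to]
      assignment[, k + 1L] <- nxt
    }
  }
  assignment[, ns] <- fill_column(assignment[, ns], ns)
  if (ns == 1L) assignment[, 1L] <- fill_column(assignment[, 1L], 1L)

  structure(list(f = f, fill = fill, segments = segs, tables = tables,
                 assignment = assignment),
            class = "founder_set")
}

#' @export
print.founder_set <- function(x, ...) {
  cat(sprintf("founder_set: f = %d over %d segment(s), fill = %s\n",
              x$f, nrow(x$segments), x$fill))
  invisible(x)
}

#' Emit founder sequences as a gapped MSA
#'
#' Each founder row is assembled segment by segment with the same gap rule
#' as the haplotype MSA, so founder rows have exactly the width of the full
#' haplotype alignment.  N-fill slots are rendered as runs of `N` spanning
#' the segment's columns.
#'
#' @param founder_set a [greedy_join()] result.
#' @param graph the `variant_graph` the founders were derived from.
#' @param include_reference prepend the gapped reference row, labeled
#'   `"REF"` (used by the ad hoc extraction, which needs the reference as
#'   row 1).
#' @return a `ref_msa` with rows `founder1..founderf` (ungapped sequences
#'   via [ungap()]).
#' @export
emit_founders <- function(founder_set, graph, include_reference = FALSE) {
  segs <- founder_set$segments
  ap <- graph$aligned_pos
  seg_width <- ap[as.character(segs$end)] - ap[as.character(segs$start)]
  rows <- vapply(seq_len(founder_set$f), function(i) {
    blocks <- vapply(seq_len(nrow(segs)), function(k) {
      idx <- founder_set$assignment[i, k]
      if (is.na(idx)) return(strrep("N", seg_width[k]))
      gapped_row(graph, founder_set$tables[[k]]$paths[[idx]])
    }, "")
    paste(blocks, collapse = "")
  }, "")
  names(rows) <- paste0("founder", seq_len(founder_set$f))
  if (include_reference) {
    rows <- c(REF = gapped_row(graph, haplotype_path(graph, "REF")), rows)
  }
  new_ref_msa(rows)
}

#' Write the JSON segmentation report
#'
#' @param segmentation a `segmentation`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_segmentation_report <- function(segmentation, path) {
  jsonlite::write_json(
    list(L = segmentation$L, D = segmentation$D_value,
         cuts = segmentation$cuts,
         segments = segmentation$segments),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
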