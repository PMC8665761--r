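## The per-chromosome directed acyclic variant graph: nodes are reference
## coordinates (every unique variant start and end, plus 1 and R+1),
## reference edges connect consecutive nodes and carry the intervening
## reference substring, and each alternative allele contributes one labeled
## edge from its start node to its end node.  Aligned positions (MSA
## columns) are the longest label-length path from the first node.

#' Build the variant graph for one chromosome
#'
#' Nodes are created at every unique variant start and end position plus the
#' boundary nodes 1 and R+1, consecutive nodes are joined by reference
#' edges labeled with the intervening reference substring, and every
#' alternative allele adds one edge from the variant's start node to its end
#' node (start plus REF length).  Duplicate alternative edges (same source,
#' target and label) are merged.
#'
#' @param reference reference sequence (string, `DNAStringSet` or FASTA path).
#' @param variants a [variant_set()] validated against `reference`.
#' @return an object of class `variant_graph` with elements `reference`,
#'   `R`, `nodes` (increasing integer vector), `edges` (data frame with
#'   columns `from`, `to`, `label`, `kind`, `id`) and `aligned_pos` (named
#'   integer vector, node -> 1-based MSA coordinate).
#' @export
build_variant_graph <- function(reference, variants) {
  reference <- load_sequences(reference)[[1L]]
  stopifnot(inherits(variants, "variant_set"))
  if (variants$reference != reference)
    stop("variant_set was validated against a different reference")
  R <- nchar(reference)
  starts <- variants$pos
  ends <- variants$pos + nchar(variants$ref)
  if (any(ends > R + 1L))
    stop("variant end exceeds R + 1 at record ",
         variants$id[which(ends > R + 1L)[1L]])
  nodes <- sort(unique(c(1L, R + 1L, starts, ends)))

  k <- length(nodes)
  ref_edges <- data.frame(
    from = nodes[-k], to = nodes[-1L],
    label = substring(reference, nodes[-k], nodes[-1L] - 1L),
    kind = "reference", id = NA_character_,
    stringsAsFactors = FALSE)

  alt_edges <- NULL
  if (length(starts) > 0L) {
    alt_edges <- do.call(rbind, lapply(seq_along(starts), function(i) {
      data.frame(from = starts[i], to = ends[i], label = variants$alt[[i]],
                 kind = "alternative", id = variants$id[i],
                 stringsAsFactors = FALSE)
    }))
    alt_edges <- alt_edges[order(alt_edges$from, alt_edges$to, alt_edges$label), ]
    dup <- duplicated(alt_edges[, c("from", "to", "label")])
    alt_edges <- alt_edges[!dup, ]
  }
  edges <- rbind(ref_edges, alt_edges)
  rownames(edges) <- NULL

  g <- structure(
    list(reference = reference, R = R, nodes = nodes, edges = edges,
         variants = variants, aligned_pos = NULL),
    class = "variant_graph")
  g$aligned_pos <- aligned_positions(g)
  g
}

#' Aligned (MSA) position of every graph node
#'
#' The aligned position of the first node is 1; for every other node it is
#' the maximum over its in-edges of the source node's aligned position plus
#' the label length (a longest-path dynamic program in node order).  The MSA
#' width is `aligned_positions(g)[R + 1] - 1`.
#'
#' @param graph a `variant_graph`.
#' @return named integer vector, node coordinate -> MSA coordinate.
#' @export
aligned_positions <- function(graph) {
  nodes <- graph$nodes
  ap <- setNames(rep(NA_integer_, length(nodes)), nodes)
  ap[1L] <- 1L
  e <- graph$edges
  for (i in seq_along(nodes)[-1L]) {
    r <- nodes[i]
    inn <- e[e$to == r, , drop = FALSE]
    ap[i] <- max(ap[as.character(inn$from)] + nchar(inn$label))
  }
  ap
}

#' MSA width of a variant graph
#' @param graph a `variant_graph`.
#' @return integer: number of columns of the reference-guided MSA.
#' @export
msa_width <- function(graph) {
  unname(graph$aligned_pos[as.character(graph$R + 1L)] - 1L)
}

## Resolve a haplotype label to an edge-index path from node 1 to node R+1.
## "REF" follows reference edges only.
haplotype_path <- function(graph, haplotype, drop_conflicts = FALSE) {
  e <- graph$edges
  v <- graph$variants
  if (identical(haplotype, "REF")) {
    return(which(e$kind == "reference"))
  }
  if (!haplotype %in% v$labels) stop("unknown haplotype: ", haplotype)
  alle <- v$geno[, haplotype]
  chosen <- which(alle > 0L)
  if (length(chosen) > 1L) {
    ends <- v$pos[chosen] + nchar(v$ref[chosen])
    keep <- logical(length(chosen))
    keep[1L] <- TRUE
    last_end <- ends[1L]
    for (j in seq_along(chosen)[-1L]) {
      if (v$pos[chosen[j]] < last_end) {
        if (!drop_conflicts)
          stop("overlapping variants on haplotype ", haplotype, ": records ",
               v$id[chosen[j - 1L]], " and ", v$id[chosen[j]])
        warning("dropping record ", v$id[chosen[j]],
                " overlapping an earlier variant on ", haplotype,
                call. = FALSE)
      } else {
        keep[j] <- TRUE
        last_end <- ends[j]
      }
    }
    chosen <- chosen[keep]
  }
  ref_idx <- which(e$kind == "reference")
  ref_from <- e$from[ref_idx]
  path <- integer(0)
  cur <- 1L
  for (j in chosen) {
    start <- v$pos[j]; end <- v$pos[j] + nchar(v$ref[j])
    path <- c(path, ref_idx[ref_from >= cur & ref_from < start])
    lab <- v$alt[[j]][alle[j]]
    ei <- which(e$kind == "alternative" & e$from == start & e$to == end &
                e$label == lab)
    path <- c(path, ei[1L])
    cur <- end
  }
  c(path, ref_idx[ref_from >= cur])
}

#' Edge paths through the graph for a set of haplotypes
#'
#' @param graph a `variant_graph`.
#' @param haplotypes haplotype labels (default: all in the variant set).
#' @param include_reference prepend the reference path, labeled `"REF"`.
#' @param drop_conflicts if `TRUE`, a haplotype carrying two overlapping
#'   variants keeps the earlier-starting one and drops the later with a
#'   warning; the default is an error naming the conflicting records.
#' @return named list of integer vectors (row indices into `graph$edges`).
#' @export
haplotype_paths <- function(graph, haplotypes = NULL, include_reference = TRUE,
                            drop_conflicts = FALSE) {
  if (is.null(haplotypes)) haplotypes <- graph$variants$labels
  if (include_reference) haplotypes <- c("REF", setdiff(haplotypes, "REF"))
  setNames(lapply(haplotypes, haplotype_path, graph = graph,
                  drop_conflicts = drop_conflicts), haplotypes)
}

#' Predicted haplotype sequence
#'
#' Concatenates the edge labels along a haplotype's path through the graph.
#'
#' @inheritParams haplotype_paths
#' @param haplotype haplotype label (or `"REF"`).
#' @return ungapped sequence string.
#' @export
haplotype_sequence <- function(graph, haplotype, drop_conflicts = FALSE) {
  path <- haplotype_path(graph, haplotype, drop_conflicts = drop_conflicts)
  paste(graph$edges$label[path], collapse = "")
}

## Gap-fill rule: after each traversed edge (q, r, label), append
## aligned_pos(r) - aligned_pos(q) - nchar(label) gap characters.
gapped_row <- function(graph, path) {
  e <- graph$edges[path, , drop = FALSE]
  ap <- graph$aligned_pos
  gaps <- ap[as.character(e$to)] - ap[as.character(e$from)] - nchar(e$label)
  paste(paste0(e$label, strrep(GAP, gaps)), collapse = "")
}

#' Emit the reference-guided multiple alignment
#'
#' Every haplotype row is written by walking its path and appending, after
#' each edge label, enough gap characters to reach the target node's aligned
#' position.  All rows have identical width `aligned_pos(R+1) - 1`.
#'
#' @inheritParams haplotype_paths
#' @return an object of class `ref_msa`: list with `labels`, `rows` (named
#'   character vector of equal-length gapped strings) and `width`.
#' @export
emit_msa <- function(graph, haplotypes = NULL, include_reference = TRUE,
                     drop_conflicts = FALSE) {
  paths <- haplotype_paths(graph, haplotypes, include_reference,
                           drop_conflicts)
  rows <- vapply(paths, function(p) gapped_row(graph, p), "")
  new_ref_msa(rows)
}

new_ref_msa <- function(rows) {
  w <- unique(nchar(rows))
  stopifnot(length(w) == 1L)
  structure(list(labels = names(rows), rows = rows, width = w),
            class = "ref_msa")
}

#' @export
print.ref_msa <- function(x, ...) {
  cat(sprintf("ref_msa: %d row(s) x %d column(s)\n", length(x$rows), x$width))
  show <- utils::head(x$rows, 8L)
  cat(sprintf("  %-10s %s\n", names(show),
              ifelse(nchar(show) > 60, paste0(substr(show, 1, 57), "..."), show)),
      sep = "")
  invisible(x)
}

#' Write a gapped MSA to FASTA
#' @param msa a `ref_msa`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) write_fasta(msa$rows, path)

#' Write the node/aligned-position sidecar table
#' @param graph a `variant_graph`.
#' @param path output file (tab-separated: node, aligned_pos).
#' @return `path`, invisibly.
#' @export
write_node_table <- function(graph, path) {
  write.table(
    data.frame(node = graph$nodes, aligned_pos = unname(graph$aligned_pos)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.variant_graph <- function(x, ...) {
  cat(sprintf("variant_graph: R = %d, %d node(s), %d edge(s) (%d alternative), MSA width %d\n",
              x$R, length(x$nodes), nrow(x$edges),
              sum(x$edges$kind == "alternative"), msa_width(x)))
  invisible(x)
}
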