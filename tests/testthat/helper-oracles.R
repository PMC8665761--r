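## Independent oracles and random-input generators used across the suite.
## Oracles are deliberately naive (splicing, exhaustive enumeration,
## quadratic scans) and share no code with the implementation paths they
## check.

## Apply a haplotype's variants to the reference by direct splicing.
oracle_splice <- function(reference, vs, hap) {
  alle <- vs$geno[, hap]
  chosen <- which(alle > 0L)
  ## apply right-to-left so earlier coordinates stay valid
  out <- reference
  for (j in rev(chosen)) {
    a <- vs$pos[j]
    b <- a + nchar(vs$ref[j]) - 1L
    out <- paste0(substring(out, 1L, a - 1L), vs$alt[[j]][alle[j]],
                  substring(out, b + 1L, nchar(out)))
  }
  out
}

## All source-to-sink paths of a variant graph as edge-index vectors.
oracle_all_paths <- function(graph) {
  e <- graph$edges
  sink <- graph$R + 1L
  out <- list()
  recurse <- function(node, path) {
    if (node == sink) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (i in which(e$from == node)) recurse(e$to[i], c(path, i))
  }
  recurse(1L, integer(0))
  out
}

## Aligned positions by exhaustive all-paths longest-path enumeration.
oracle_aligned_positions <- function(graph) {
  e <- graph$edges
  ap <- setNames(rep(1L, length(graph$nodes)), graph$nodes)
  for (p in oracle_all_paths(graph)) {
    tot <- 0L
    for (i in p) {
      tot <- tot + nchar(e$label[i])
      key <- as.character(e$to[i])
      ap[key] <- max(ap[key], 1L + tot)
    }
  }
  ap
}

## Bridges by intersecting the edge sets of all source-to-sink paths.
oracle_bridges <- function(graph) {
  paths <- oracle_all_paths(graph)
  shared <- Reduce(intersect, paths)
  shared <- shared[graph$edges$kind[shared] == "reference"]
  out <- graph$edges[shared, c("from", "to")]
  rownames(out) <- NULL
  out
}

## Optimal segmentation objective by exhaustive search over all subsets of
## interior bridge nodes satisfying the length constraints.
oracle_segmentation_D <- function(graph, paths, L) {
  Rp1 <- graph$R + 1L
  cand <- find_bridge_nodes(graph)$nodes
  cand <- cand[cand > 1L & cand < Rp1]
  dval <- function(a, b)
    length(unique(vapply(paths, function(p) {
      idx <- p[graph$edges$from[p] >= a & graph$edges$from[p] < b]
      paste(graph$edges$label[idx], collapse = "")
    }, "")))
  best <- dval(1L, Rp1)  # no-cut fallback
  if (length(cand) > 0L) {
    for (mask in seq_len(2L^length(cand)) - 1L) {
      cuts <- cand[bitwAnd(mask, 2L^(seq_along(cand) - 1L)) > 0L]
      bounds <- c(1L, cuts, Rp1)
      sizes <- diff(bounds)
      if (length(cuts) > 0L && any(sizes < L)) next
      if (length(cuts) == 0L) next
      val <- max(mapply(dval, bounds[-length(bounds)], bounds[-1L]))
      best <- min(best, val)
    }
  }
  best
}

## Naive quadratic longest-previous-factor parse (same dialect as lz_parse:
## greedy, non-overlapping source, no boundary crossing, merged literals).
oracle_lz <- function(seqs) {
  text <- character(0); sid <- integer(0); loc <- integer(0)
  for (s in seq_along(seqs)) {
    cc <- strsplit(seqs[s], "")[[1]]
    text <- c(text, cc); sid <- c(sid, rep(s, length(cc)))
    loc <- c(loc, seq_along(cc))
  }
  n <- length(text)
  rows <- list()
  i <- 1L
  while (i <= n) {
    best <- 0L; bestj <- NA_integer_
    j <- 1L
    while (j < i) {
      l <- 0L
      while (j + l < i && i + l <= n && text[j + l] == text[i + l] &&
             sid[j + l] == sid[j] && sid[i + l] == sid[i]) l <- l + 1L
      if (l > best) { best <- l; bestj <- j }
      j <- j + 1L
    }
    if (best >= 1L) {
      rows[[length(rows) + 1L]] <-
        data.frame(kind = "copy", seq = sid[i], start = loc[i],
                   length = best, src = bestj)
      i <- i + best
    } else {
      last <- if (length(rows) > 0L) rows[[length(rows)]] else NULL
      if (!is.null(last) && last$kind == "literal" && last$seq == sid[i] &&
          last$start + last$length == loc[i]) {
        rows[[length(rows)]]$length <- last$length + 1L
      } else {
        rows[[length(rows) + 1L]] <-
          data.frame(kind = "literal", seq = sid[i], start = loc[i],
                     length = 1L, src = NA_integer_)
      }
      i <- i + 1L
    }
  }
  do.call(rbind, rows)
}

## Random test inputs ------------------------------------------------------

random_reference <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

## Random non-overlapping variant set (SNPs, insertions, deletions; some
## records multi-allelic) with haploid samples h1..n_hap.
random_variant_set <- function(reference, n_var, seed, n_hap = 4L) {
  set.seed(seed)
  R <- nchar(reference)
  bases <- c("A", "C", "G", "T")
  taken <- logical(R)
  pos <- integer(0); refa <- character(0); alt <- list()
  tries <- 0L
  while (length(pos) < n_var && tries < 200L) {
    tries <- tries + 1L
    type <- sample(c("snp", "ins", "del"), 1L)
    w <- switch(type, snp = 1L, ins = 1L, del = sample(2:4, 1L))
    p <- sample.int(R - w + 1L, 1L)
    if (any(taken[p:(p + w - 1L)])) next
    taken[p:(p + w - 1L)] <- TRUE
    r <- substring(reference, p, p + w - 1L)
    a <- switch(type,
      snp = sample(setdiff(bases, r), sample(1:2, 1L)),
      ins = paste0(r, paste(sample(bases, sample(1:5, 1L), replace = TRUE),
                            collapse = "")),
      del = substring(r, 1L, 1L))
    pos <- c(pos, p); refa <- c(refa, r); alt <- c(alt, list(a))
  }
  n <- length(pos)
  geno <- matrix(0L, nrow = n, ncol = n_hap,
                 dimnames = list(NULL, paste0("h", seq_len(n_hap))))
  for (i in seq_len(n)) {
    carriers <- runif(n_hap) < 0.5
    geno[i, carriers] <- sample.int(length(alt[[i]]), sum(carriers),
                                    replace = TRUE)
  }
  variant_set(pos, sprintf("r%d", seq_len(n)), refa, alt, geno, reference)
}

table1_graph <- function() {
  fx <- table1_fixture()
  g <- build_variant_graph(fx$reference, fx$variants)
  list(fixture = fx, graph = g, paths = haplotype_paths(g))
}
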