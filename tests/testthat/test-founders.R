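# Bridge detection, optimal segmentation and greedy founder joining.

test_that("bridges match the worked example and the all-paths oracle", {
  tg <- table1_graph()
  br <- find_bridge_nodes(tg$graph)
  expect_equal(paste(br$bridges$from, br$bridges$to),
               c("2 4", "7 12", "18 19"))
  expect_equal(br$nodes, c(2L, 4L, 7L, 12L, 18L, 19L))
  expect_equal(br$bridges, oracle_bridges(tg$graph))
  for (seed in 1:8) {
    ref <- random_reference(50L, seed + 60L)
    vs <- random_variant_set(ref, 5L, seed + 700L)
    g <- build_variant_graph(ref, vs)
    expect_equal(find_bridge_nodes(g)$bridges, oracle_bridges(g),
                 info = paste("seed", seed))
  }
})

test_that("bridge trivia: no variants, single SNP", {
  ref <- "ACGTAC"
  empty <- variant_set(integer(0), character(0), character(0), list(),
                       matrix(integer(0), 0, 0), ref)
  g0 <- build_variant_graph(ref, empty)
  br0 <- find_bridge_nodes(g0)
  expect_equal(nrow(br0$bridges), 1L)   # the single reference edge

  vs <- variant_set(3L, "s", "G", list("A"),
                    matrix(1L, 1, 1, dimnames = list(NULL, "h1")), ref)
  g1 <- build_variant_graph(ref, vs)
  br1 <- find_bridge_nodes(g1)
  ## all reference edges except the one spanned by the SNP are bridges
  expect_false(any(br1$bridges$from == 3L & br1$bridges$to == 4L))
  re <- g1$edges[g1$edges$kind == "reference", ]
  expect_equal(nrow(br1$bridges), nrow(re) - 1L)
})

test_that("distinct segment paths reproduce the worked-example counts", {
  tg <- table1_graph()
  d17 <- distinct_segment_paths(tg$graph, tg$paths, 1, 7)
  expect_equal(d17, c(TTCAAAAAA = 3L, TAATCTCCG = 2L, TTCTGG = 1L))
  expect_equal(length(distinct_segment_paths(tg$graph, tg$paths, 12, 19)), 4L)
  d712 <- distinct_segment_paths(tg$graph, tg$paths, 7, 12)
  expect_equal(d712, c(GAGGC = 6L))
  ## the reference path contributes exactly one occurrence per segment
  expect_equal(sum(d17), length(tg$paths))
  expect_error(distinct_segment_paths(tg$graph, tg$paths, 1, 5), "bridge")
})

test_that("optimal segmentation reproduces the worked example at L = 4", {
  tg <- table1_graph()
  seg <- optimal_segmentation(tg$graph, tg$paths, L = 4)
  expect_equal(seg$cuts, c(7L, 12L))
  expect_equal(seg$segments$size, c(6L, 5L, 7L))
  expect_equal(seg$D_value, 4L)
  expect_equal(seg$segments$d, c(3L, 1L, 4L))
})

test_that("infeasible L falls back to a single segment", {
  tg <- table1_graph()
  seg <- optimal_segmentation(tg$graph, tg$paths, L = 100)
  expect_equal(seg$cuts, integer(0))
  expect_equal(nrow(seg$segments), 1L)
  expect_equal(seg$segments$start, 1L)
  expect_equal(seg$segments$end, 19L)
})

test_that("segmentation DP attains the exhaustive-search optimum", {
  for (seed in 1:8) {
    ref <- random_reference(80L, seed + 80L)
    vs <- random_variant_set(ref, 7L, seed + 900L)
    g <- build_variant_graph(ref, vs)
    paths <- haplotype_paths(g)
    for (L in c(1L, 5L, 12L)) {
      seg <- optimal_segmentation(g, paths, L)
      expect_equal(seg$D_value, oracle_segmentation_D(g, paths, L),
                   info = paste("seed", seed, "L", L))
      if (length(seg$cuts) > 0L)
        expect_true(all(seg$segments$size >= L))
      expect_equal(seg$segments$start[1L], 1L)
      expect_equal(seg$segments$end[nrow(seg$segments)], nchar(ref) + 1L)
    }
  }
})

test_that("single-SNP graph at L = 1: D = 2 with the rightmost-last-cut rule", {
  ref <- "ACGTACGT"
  vs <- variant_set(4L, "s", "T", list("G"),
                    matrix(1L, 1, 1, dimnames = list(NULL, "h1")), ref)
  g <- build_variant_graph(ref, vs)
  paths <- haplotype_paths(g)
  seg <- optimal_segmentation(g, paths, 1L)
  expect_equal(seg$D_value, 2L)
  ## ties resolved toward the most recent (rightmost) last cut
  cand <- find_bridge_nodes(g)$nodes
  cand <- cand[cand > 1L & cand < nchar(ref) + 1L]
  if (length(seg$cuts) > 0L)
    expect_equal(seg$cuts[length(seg$cuts)], max(cand))
})

test_that("greedy join duplicates a subsequence when f exceeds the distinct
           count, and every distinct subsequence is kept", {
  tg <- table1_graph()
  seg <- optimal_segmentation(tg$graph, tg$paths, 4L)
  fs <- greedy_join(tg$graph, tg$paths, seg, f = 4L)
  seg1 <- fs$tables[[1L]]$strings[fs$assignment[, 1L]]
  expect_equal(sort(table(seg1), decreasing = TRUE)[[1L]], 2L)  # one duplicate
  expect_setequal(unique(seg1), c("TTCAAAAAA", "TAATCTCCG", "TTCTGG"))
  ## default f is the max distinct count; lower f errors
  expect_equal(greedy_join(tg$graph, tg$paths, seg)$f, 4L)
  expect_error(greedy_join(tg$graph, tg$paths, seg, f = 3L), "below the minimum")
})

test_that("single segment with f = distinct count returns exactly the
           distinct subsequences", {
  tg <- table1_graph()
  seg <- optimal_segmentation(tg$graph, tg$paths, 100L)  # one segment
  fs <- greedy_join(tg$graph, tg$paths, seg)
  msa <- emit_founders(fs, tg$graph)
  expect_setequal(unname(ungap(msa$rows)),
                  ungap(fs$tables[[1L]]$strings))
})

test_that("every haplotype's segment subsequence occurs in some founder", {
  for (seed in 1:5) {
    ref <- random_reference(100L, seed + 120L)
    vs <- random_variant_set(ref, 8L, seed + 1100L, n_hap = 5L)
    g <- build_variant_graph(ref, vs)
    paths <- haplotype_paths(g)
    seg <- optimal_segmentation(g, paths, 6L)
    fs <- greedy_join(g, paths, seg)
    for (k in seq_len(nrow(seg$segments))) {
      chosen <- fs$tables[[k]]$strings[fs$assignment[, k]]
      expect_true(all(fs$tables[[k]]$strings %in% chosen),
                  info = paste("seed", seed, "segment", k))
    }
  }
})

test_that("founder MSA has full alignment width and honors the join", {
  tg <- table1_graph()
  seg <- optimal_segmentation(tg$graph, tg$paths, 4L)
  fs <- greedy_join(tg$graph, tg$paths, seg, f = 4L)
  msa <- emit_founders(fs, tg$graph)
  expect_equal(msa$width, 23L)
  expect_equal(length(msa$rows), 4L)
  ## second segment spans MSA columns 12..16; every founder shows GAGGC there
  expect_true(all(substring(msa$rows, 12L, 16L) == "GAGGC"))
  ## with the reference row prepended the first row ungaps to the reference
  msar <- emit_founders(fs, tg$graph, include_reference = TRUE)
  expect_equal(msar$labels[1L], "REF")
  expect_equal(ungap(msar$rows[[1L]]), tg$fixture$reference)
})

test_that("N-fill mode pads leftover slots with N instead of duplicating", {
  tg <- table1_graph()
  seg <- optimal_segmentation(tg$graph, tg$paths, 4L)
  fs <- greedy_join(tg$graph, tg$paths, seg, f = 5L, fill = "N")
  msa <- emit_founders(fs, tg$graph)
  nfilled <- grepl("N", msa$rows)
  expect_true(any(nfilled))
  ## N runs span whole segment column blocks
  expect_true(all(substring(msa$rows[nfilled], 1L, 11L) %in%
                    c(strrep("N", 11L),
                      substring(msa$rows[!nfilled], 1L, 11L))))
})

test_that("founder output is independent of haplotype input order", {
  tg <- table1_graph()
  seg <- optimal_segmentation(tg$graph, tg$paths, 4L)
  fs1 <- greedy_join(tg$graph, tg$paths, seg, f = 4L)
  perm <- tg$paths[c("REF", "s5", "s3", "s1", "s4", "s2")]
  seg2 <- optimal_segmentation(tg$graph, perm, 4L)
  fs2 <- greedy_join(tg$graph, perm, seg2, f = 4L)
  m1 <- sort(unname(ungap(emit_founders(fs1, tg$graph)$rows)))
  m2 <- sort(unname(ungap(emit_founders(fs2, tg$graph)$rows)))
  expect_equal(m1, m2)
})
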