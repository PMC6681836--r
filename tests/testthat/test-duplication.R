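test_that("the tandem proximity window switches at 200 Mb", {
  expect_identical(tandem_window(150e6), 100000)   # small genome
  expect_identical(tandem_window(200e6), 350000)   # boundary: "remaining"
  expect_identical(tandem_window(3e9), 350000)
})

fake_annotation <- function(genome_size = 150e6) {
  # 30 genes, 2 kb each, 3 kb gaps, single chromosome
  starts <- seq(1e6, by = 5000, length.out = 30)
  genome_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:30), chrom = "chr1",
    start = starts, end = starts + 1999, strand = "+"),
    genome_size = genome_size)
}

fake_alignment <- function(identity, coverage, evalue = 1e-6) {
  structure(list(query_id = "child", subject_id = "parent",
                 aligned_query = "", aligned_subject = "",
                 score = 100, identity = identity,
                 query_coverage = coverage, evalue = evalue, n_columns = 0L),
            class = "pairwise_alignment")
}

test_that("tandem verdict follows the three-rule conjunction", {
  ann <- fake_annotation()
  # adjacent near-identical genes: all rules pass
  call <- call_tandem("g02", "g01", fake_alignment(1.0, 1.0), ann)
  expect_true(call$verdict)
  # identity below 0.70 with everything else passing
  call <- call_tandem("g02", "g01", fake_alignment(0.65, 1.0), ann)
  expect_false(call$verdict)
  expect_false(call$rule_flags[["identity"]])
  expect_true(call$rule_flags[["coverage"]])
  expect_true(call$rule_flags[["proximity"]])
  # rank distance 11 with everything else passing
  call <- call_tandem("g12", "g01", fake_alignment(0.9, 0.9), ann)
  expect_equal(call$rank_distance, 11)
  expect_false(call$verdict)
  # rank distance exactly 10 passes
  call <- call_tandem("g11", "g01", fake_alignment(0.9, 0.9), ann)
  expect_true(call$verdict)
  # non-significant alignment zeroes the sequence evidence
  call <- call_tandem("g02", "g01", fake_alignment(0.9, 0.9, evalue = 0.5), ann)
  expect_false(call$verdict)
})

test_that("different chromosomes fail proximity without erroring", {
  starts <- seq(1e6, by = 5000, length.out = 4)
  ann <- genome_annotation(data.frame(
    gene_id = c("a1", "a2", "b1", "b2"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    start = starts, end = starts + 1999, strand = "+"),
    genome_size = 150e6)
  call <- call_tandem("b1", "a1", fake_alignment(1.0, 1.0), ann)
  expect_false(call$rule_flags[["proximity"]])
  expect_false(call$verdict)
})

test_that("tandem calls equal brute-force predicate evaluation (10k cases)", {
  window <- tandem_window(150e6)
  set.seed(202)
  n_genes <- 40
  starts <- cumsum(sample(3000:120000, n_genes, replace = TRUE))
  ann <- genome_annotation(data.frame(
    gene_id = sprintf("g%02d", 1:n_genes), chrom = "chr1",
    start = starts, end = starts + 1999, strand = "+"),
    genome_size = 150e6)
  g <- ann$genes
  for (i in 1:10000) {
    pair <- sample(n_genes, 2)
    identity <- runif(1, 0.4, 1)
    coverage <- runif(1, 0.1, 1)
    al <- fake_alignment(identity, coverage)
    call <- call_tandem(g$gene_id[pair[1]], g$gene_id[pair[2]], al, ann)
    a <- g[pair[1], ]; b <- g[pair[2], ]
    want <- coverage >= 0.30 && identity >= 0.70 &&
      abs(a$rank - b$rank) <= 10 &&
      abs((a$start + a$end) / 2 - (b$start + b$end) / 2) <= window
    if (call$verdict != want) {
      fail(sprintf("mismatch at case %d (pair %s-%s)", i,
                   g$gene_id[pair[1]], g$gene_id[pair[2]]))
      break
    }
  }
  succeed()
})

test_that("anchor chaining respects the five-pair block minimum", {
  collinear <- function(n) data.frame(
    geneA = sprintf("a%d", 1:n), geneB = sprintf("b%d", 1:n),
    posA = 1:n * 10, posB = 1:n * 10 + 3)
  expect_length(chain_anchors(collinear(5), max_gap = 20), 1)
  expect_identical(nrow(chain_anchors(collinear(5), max_gap = 20)[[1]]$anchor_pairs), 5L)
  expect_length(chain_anchors(collinear(4), max_gap = 20), 0)
  expect_length(chain_anchors(collinear(0)[0, ], max_gap = 20), 0)
})

test_that("chaining equals the exhaustive increasing-subsequence oracle", {
  brute_best <- function(anchors, max_gap, anchor_score = 1,
                         gap_penalty = 0.05) {
    n <- nrow(anchors)
    best <- 0
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      for (orient in c(1, -1)) {
        a <- anchors$posA[idx]; b <- orient * anchors$posB[idx]
        ord <- order(a)
        a <- a[ord]; b <- b[ord]
        if (length(idx) > 1) {
          da <- diff(a); db <- diff(b)
          if (any(da <= 0 | db <= 0 | da > max_gap | db > max_gap)) next
          sc <- length(idx) - gap_penalty * sum(da + db - 2)
        } else sc <- 1
        best <- max(best, sc)
      }
    }
    best
  }
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(6:9, 1)
    anchors <- data.frame(geneA = sprintf("a%d", 1:n),
                          geneB = sprintf("b%d", 1:n),
                          posA = sample(1:30, n), posB = sample(1:30, n))
    got <- chain_anchors(anchors, max_gap = 12, min_pairs = 1)
    got_best <- if (length(got)) max(vapply(got, `[[`, 0, "chain_score")) else 0
    expect_equal(got_best, brute_best(anchors, max_gap = 12),
                 info = paste("rep", rep))
  }
})

test_that("chaining is invariant under coordinate translation", {
  set.seed(9)
  n <- 8
  anchors <- data.frame(geneA = sprintf("a%d", 1:n),
                        geneB = sprintf("b%d", 1:n),
                        posA = sample(1:40, n), posB = sample(1:40, n))
  b1 <- chain_anchors(anchors, max_gap = 15, min_pairs = 2)
  shifted <- transform(anchors, posA = posA + 1000, posB = posB + 500)
  b2 <- chain_anchors(shifted, max_gap = 15, min_pairs = 2)
  expect_identical(lapply(b1, function(x) x$anchor_pairs),
                   lapply(b2, function(x) x$anchor_pairs))
  expect_equal(vapply(b1, `[[`, 0, "chain_score"),
               vapply(b2, `[[`, 0, "chain_score"))
})

test_that("planted tandem and segmental truth is recovered exactly", {
  layout <- generate_genome_layout(n_tandem_arrays = 3, array_size = 2,
                                   n_blocks = 1, block_pairs = 6,
                                   genome_size = 150e6, seed = 42)
  prots <- generate_family_proteins(layout, seed = 43)
  truth <- layout$truth
  family <- c(truth$tandem_pairs$parent, truth$tandem_pairs$child,
              truth$control_pairs$parent, truth$control_pairs$child)
  calls <- tandem_scan(family, layout$annotation, prots)
  # sensitivity 1.0 on planted pairs
  for (r in seq_len(nrow(truth$tandem_pairs))) {
    v <- calls$verdict[calls$child == truth$tandem_pairs$child[r] &
                       calls$parent == truth$tandem_pairs$parent[r]]
    expect_true(v, label = paste("planted pair", r))
  }
  # specificity 1.0 on rule-violating controls
  for (r in seq_len(nrow(truth$control_pairs))) {
    v <- calls$verdict[calls$child == truth$control_pairs$child[r] &
                       calls$parent == truth$control_pairs$parent[r]]
    expect_false(v, label = paste("control", truth$control_pairs$violated[r]))
  }
  # segmental blocks: chain on gene ranks, compare anchor pair sets
  g <- layout$annotation$genes
  pairs <- truth$blocks[[1]]
  noise <- data.frame(geneA = "blk1_noiseA", geneB = "blk1_noiseB")
  anchors <- rbind(pairs, noise)
  anchors$posA <- g$rank[match(anchors$geneA, g$gene_id)]
  anchors$posB <- g$rank[match(anchors$geneB, g$gene_id)]
  blocks <- chain_anchors(anchors, max_gap = 10, min_pairs = 5)
  expect_length(blocks, 1)
  expect_setequal(paste(blocks[[1]]$anchor_pairs$geneA,
                        blocks[[1]]$anchor_pairs$geneB),
                  paste(pairs$geneA, pairs$geneB))
})

test_that("element overlap relations follow interval arithmetic", {
  ann <- genome_annotation(data.frame(
    gene_id = "g1", chrom = "chr1", start = 100000L, end = 102000L,
    strand = "+"), genome_size = 1e6)
  el <- function(s, e) data.frame(chrom = "chr1", start = s, end = e,
                                  feature_type = "LTR_retrotransposon")
  expect_identical(flank_overlap("g1", ann, el(95000, 105000))$relation,
                   "contained")
  expect_identical(flank_overlap("g1", ann, el(99000, 100500))$relation,
                   "partial")
  expect_identical(flank_overlap("g1", ann, el(60000, 65000))$relation,
                   "flank_only")
  # 60 kb upstream: outside the 50 kb window
  expect_identical(flank_overlap("g1", ann, el(30000, 39999))$relation,
                   "none")
  expect_identical(flank_overlap("g1", ann, el(30000, 39999)[0, ])$relation,
                   "none")
  # element on another chromosome is ignored
  other <- el(95000, 105000); other$chrom <- "chr2"
  expect_identical(flank_overlap("g1", ann, other)$relation, "none")
})
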