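test_that("3-taxon NJ matches the closed-form three-point formulas", {
  d <- matrix(c(0, 5, 9,
                5, 0, 8,
                9, 8, 0), 3, 3, dimnames = list(c("a", "b", "c"),
                                                c("a", "b", "c")))
  tree <- nj_tree(d)
  # x = (dab + dac - dbc)/2, etc.
  want <- c(a = (5 + 9 - 8) / 2, b = (5 + 8 - 9) / 2, c = (9 + 8 - 5) / 2)
  got <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                         tree$edge[, 2])], tree$tip.label)
  expect_equal(got[names(want)], want)
})

test_that("NJ recovers additive 4- and 5-taxon trees exactly", {
  # fixed 4-taxon tree: ((a:2,b:3):1,(c:4,d:5));  (unrooted internal 1)
  d4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  bl <- c(a = 2, b = 3, c = 4, d = 5)
  path <- function(x, y) {
    same <- (x %in% c("a", "b")) == (y %in% c("a", "b"))
    bl[x] + bl[y] + ifelse(same, 0, 1)
  }
  for (x in letters[1:4]) for (y in letters[1:4]) {
    if (x != y) d4[x, y] <- path(x, y)
  }
  tree <- nj_tree(d4)
  got <- as.matrix(ape::cophenetic.phylo(tree))[letters[1:4], letters[1:4]]
  expect_equal(got, d4, tolerance = 1e-12)
  expect_true(ape::is.monophyletic(ape::unroot(tree), c("a", "b")))

  # 5-taxon additive matrix from a random tree with known lengths
  ref <- ape::read.tree(text = "((a:1.5,b:2.5):0.8,(c:1.2,(d:2.0,e:0.7):0.9):0.4);")
  d5 <- as.matrix(ape::cophenetic.phylo(ref))
  tree5 <- nj_tree(d5)
  expect_equal(as.matrix(ape::cophenetic.phylo(tree5))[rownames(d5), colnames(d5)],
               d5, tolerance = 1e-12)
  expect_identical(ape::dist.topo(ape::unroot(tree5), ape::unroot(ref))[1], 0)
})

test_that("NJ on additive data equals minimum evolution by enumeration", {
  ref <- ape::read.tree(text = "((a:1.1,b:0.6):0.5,(c:2.2,(d:0.9,e:1.4):0.6):0.3);")
  d5 <- as.matrix(ape::cophenetic.phylo(ref))
  njt <- ape::unroot(nj_tree(d5))
  topos <- phangorn::allTrees(5, tip.label = rownames(d5))
  lens <- vapply(topos, function(tp) {
    fit <- phangorn::nnls.tree(d5, tp, method = "unrooted")
    sum(pmax(fit$edge.length, 0))
  }, 0)
  best <- topos[[which.min(lens)]]
  expect_identical(ape::dist.topo(njt, ape::unroot(best))[1], 0)
})

test_that("asymmetric matrices are rejected, negatives clamped", {
  d <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "symmetric")
  # a matrix driving an NJ edge negative
  dneg <- matrix(c(0, 1, 6, 6,
                   1, 0, 6, 6,
                   6, 6, 0, 1,
                   6, 6, 1, 0) * 1.0, 4, 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  dneg["a", "b"] <- dneg["b", "a"] <- 5.9
  tree <- nj_tree(dneg)
  expect_true(all(tree$edge.length >= 0))
})

test_that("bootstrap supports are deterministic and saturate on clean splits", {
  # two clean 3-leaf clades, zero within-clade divergence
  left <- strrep("AC", 30)
  right <- strrep("KW", 30)
  msa <- multiple_alignment(c(l1 = left, l2 = left, l3 = left,
                              r1 = right, r2 = right, r3 = right))
  t1 <- bootstrap_nj(msa, n_reps = 30, seed = 5)
  t2 <- bootstrap_nj(msa, n_reps = 30, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  # the central bipartition {l1,l2,l3} | {r1,r2,r3} has support 1
  part <- ape::prop.part(t1)
  labs <- attr(part, "labels")
  central <- which(vapply(part, function(p) {
    setequal(labs[p], c("l1", "l2", "l3")) ||
      setequal(labs[p], c("r1", "r2", "r3"))
  }, TRUE))
  sup <- t1$node.label[central]
  expect_true(any(sup == 1))
  expect_error(bootstrap_nj(multiple_alignment(c(a = "A", b = "C", c = "A")),
                            n_reps = 5, seed = 1), "single-column")
})

test_that("queries join their subfamily clade with 100% accuracy", {
  sim <- simulate_reference_panel(subfamilies = c("TPS-a", "TPS-b", "TPS-g"),
                                  n_per = 4, length = 60,
                                  within_divergence = 0.1, seed = 9)
  correct <- 0; total <- 0
  for (s in names(sim$consensus)) {
    for (q in 1:3) {
      # query at within-subfamily divergence from its consensus: the
      # between/within ratio is >= 2 by construction
      qseq <- with_seed(100 * q + match(s, names(sim$consensus)), {
        chars <- strsplit(sim$consensus[[s]], "")[[1]]
        hit <- runif(60) < 0.1
        chars[hit] <- vapply(chars[hit], function(a)
          sample(setdiff(tpsurvey:::AA_ALPHABET20, a), 1), "")
        paste(chars, collapse = "")
      })
      got <- classify_query(setNames(qseq, "query"), sim$panel)$subfamily
      total <- total + 1
      if (identical(got, s)) correct <- correct + 1
    }
  }
  expect_identical(correct, total)
})

test_that("a query identical to a reference gets that reference's label", {
  sim <- simulate_reference_panel(seed = 21)
  ref <- sim$panel[5, ]   # a TPS-b reference
  got <- classify_query(setNames(ref$seq, "query"), sim$panel)
  expect_identical(got$subfamily, ref$subfamily)
})

test_that("equidistant queries are unassigned (tie contract)", {
  # two 2-reference clades; query built as a 50/50 chimera of the two
  # consensus sequences is equidistant by construction
  sim <- simulate_reference_panel(subfamilies = c("TPS-a", "TPS-b"),
                                  n_per = 2, length = 60,
                                  within_divergence = 0.02, seed = 33)
  a <- strsplit(sim$consensus[["TPS-a"]], "")[[1]]
  b <- strsplit(sim$consensus[["TPS-b"]], "")[[1]]
  chim <- paste(ifelse(seq_len(60) %% 2 == 0, a, b), collapse = "")
  got <- classify_query(setNames(chim, "query"), sim$panel)$subfamily
  expect_identical(got, "unassigned")
})

test_that("domain disagreement keeps the NTD call and flags conflict", {
  sim_n <- simulate_reference_panel(subfamilies = c("TPS-a", "TPS-g"),
                                    n_per = 3, length = 50, seed = 41)
  sim_c <- simulate_reference_panel(subfamilies = c("TPS-a", "TPS-g"),
                                    n_per = 3, length = 50, seed = 42)
  # NTD sequence near the TPS-a consensus, CTD sequence near TPS-g
  res <- assign_subfamily("gene1",
                          ntd_seq = sim_n$consensus[["TPS-a"]],
                          ctd_seq = sim_c$consensus[["TPS-g"]],
                          ntd_panel = sim_n$panel, ctd_panel = sim_c$panel)
  expect_identical(res$subfamily, "TPS-a")
  expect_identical(res$domain_used, "NTD")
  expect_true(res$conflict)
  # single-domain gene: classified on the domain it has
  res2 <- assign_subfamily("gene2", ctd_seq = sim_c$consensus[["TPS-g"]],
                           ctd_panel = sim_c$panel)
  expect_identical(res2$subfamily, "TPS-g")
  expect_identical(res2$domain_used, "CTD")
  expect_false(res2$conflict)
})

test_that("assignment is invariant to panel order and reference duplication", {
  sim <- simulate_reference_panel(seed = 55)
  q <- setNames(sim$consensus[["TPS-a"]], "query")
  base <- classify_query(q, sim$panel)$subfamily
  shuffled <- sim$panel[rev(seq_len(nrow(sim$panel))), ]
  expect_identical(classify_query(q, shuffled)$subfamily, base)
  dup <- sim$panel[c(seq_len(nrow(sim$panel)), 1), ]
  dup$id[nrow(dup)] <- "dup_ref"
  expect_identical(classify_query(q, dup)$subfamily, base)
})
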