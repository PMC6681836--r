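# ---------------------------------------------------------------------------
# Domain-wise phylogenies and subfamily assignment. Trees are built by
# neighbor joining on JTT maximum-likelihood distances with bootstrap
# support; queries are assigned to the subfamily (TPS-a..h) of the smallest
# enclosing monophyletic reference group, with the N-terminal-domain tree
# taking precedence when the two domains disagree.
# ---------------------------------------------------------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining ([ape::nj()]); negative branch lengths are
#' clamped to zero and flagged via the `clamped` attribute.
#'
#' @param d symmetric distance matrix (>= 3 taxa, zero diagonal).
#' @return an [ape::phylo] tree with attribute `clamped` (number of edges
#'   clamped to zero).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("need >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  tree <- ape::nj(as.dist(d))
  clamped <- sum(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Bootstrap support for an alignment's NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the JTT-distance
#' NJ tree per replicate, and reports for each internal edge of the
#' original tree the fraction of replicates containing the same
#' bipartition.
#'
#' @param msa a [multiple_alignment].
#' @param n_reps bootstrap replicates (>= 1; the survey convention is
#'   1000).
#' @param seed RNG seed (same seed, same supports).
#' @param max_dist saturation cap for the JTT distances.
#' @return the original NJ tree with `node.label` set to support fractions
#'   (in `[0, 1]`) for internal nodes.
#' @export
bootstrap_nj <- function(msa, n_reps = 100, seed = 1, max_dist = 10) {
  if (msa$n_columns < 2) stop("single-column alignment cannot be resampled")
  if (n_reps < 1) stop("n_reps must be >= 1")
  rows <- do.call(rbind, strsplit(msa$rows, ""))
  rownames(rows) <- names(msa$rows)
  tree <- nj_tree(jtt_distance_matrix(msa, max_dist = max_dist))
  reps <- with_seed(seed, {
    lapply(seq_len(n_reps), function(r) {
      cols <- sample.int(ncol(rows), replace = TRUE)
      m <- multiple_alignment(apply(rows[, cols, drop = FALSE], 1,
                                    paste, collapse = ""))
      nj_tree(jtt_distance_matrix(m, max_dist = max_dist))
    })
  })
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  tree$node.label <- counts / n_reps
  tree
}

#' Reference panel for subfamily classification
#'
#' Panels pair aligned (or alignable) reference domain sequences with their
#' known subfamily. The packaged embodiment of the classification system is
#' a FASTA whose headers carry `subfamily=<label>`; synthetic panels are
#' produced by [simulate_reference_panel()].
#'
#' @param seqs named character vector of reference domain sequences.
#' @param subfamily character vector of subfamily labels (same length).
#' @return a `reference_panel` data.frame with columns `id`, `seq`,
#'   `subfamily`.
#' @export
reference_panel <- function(seqs, subfamily) {
  stopifnot(length(seqs) == length(subfamily), !is.null(names(seqs)))
  if (any(table(subfamily) < 1)) stop("every subfamily needs >= 1 reference")
  data.frame(id = names(seqs), seq = as.character(seqs),
             subfamily = subfamily, stringsAsFactors = FALSE)
}

#' Read a reference panel from FASTA
#'
#' Headers must carry a `subfamily=<label>` tag in the description.
#'
#' @param path FASTA file.
#' @return a [reference_panel()].
#' @export
read_reference_panel <- function(path) {
  seqs <- read_fasta(path)
  desc <- attr(seqs, "description")
  if (!all(grepl("subfamily=", desc))) {
    stop("every panel header needs a subfamily=<label> tag")
  }
  sub <- sub("^.*subfamily=([^ ]+).*$", "\\1", desc)
  reference_panel(setNames(as.character(unclass(seqs)), names(seqs)), sub)
}

#' Simulate a labeled reference panel
#'
#' A random family ancestor is mutated at `between_divergence` per site to
#' give each subfamily its consensus; members then diverge from their
#' consensus at `within_divergence`. With the defaults the
#' between/within divergence ratio is well above 2 while distances stay
#' far from saturation (fully unrelated consensuses would saturate the
#' JTT distances and randomize the tree).
#'
#' @param subfamilies labels (e.g. `c("TPS-a", "TPS-b", "TPS-g")`).
#' @param n_per number of references per subfamily.
#' @param length domain length.
#' @param within_divergence per-site divergence within a subfamily.
#' @param between_divergence per-site divergence of each subfamily
#'   consensus from the family ancestor.
#' @param seed RNG seed.
#' @return list with `panel` (a [reference_panel()]) and `consensus`
#'   (named vector of subfamily consensus sequences).
#' @export
simulate_reference_panel <- function(subfamilies = c("TPS-a", "TPS-b", "TPS-g"),
                                     n_per = 4, length = 60,
                                     within_divergence = 0.1,
                                     between_divergence = 0.35, seed = 1) {
  with_seed(seed, {
    ancestor <- random_protein(length)
    mutate0 <- function(s, rate) {
      chars <- strsplit(s, "")[[1]]
      hit <- runif(base::length(chars)) < rate
      chars[hit] <- vapply(chars[hit], function(a) {
        sample(setdiff(AA_ALPHABET20, a), 1)
      }, "")
      paste(chars, collapse = "")
    }
    consensus <- setNames(vapply(subfamilies, function(s) {
      mutate0(ancestor, between_divergence)
    }, ""), subfamilies)
    mutate <- function(s, rate) {
      chars <- strsplit(s, "")[[1]]
      hit <- runif(base::length(chars)) < rate
      chars[hit] <- vapply(chars[hit], function(a) {
        sample(setdiff(AA_ALPHABET20, a), 1)
      }, "")
      paste(chars, collapse = "")
    }
    seqs <- character(0); labels <- character(0)
    for (s in subfamilies) for (i in seq_len(n_per)) {
      id <- sprintf("%s_ref%02d", gsub("[^A-Za-z]", "", s), i)
      seqs[id] <- mutate(consensus[[s]], within_divergence)
      labels <- c(labels, s)
    }
    list(panel = reference_panel(seqs, labels), consensus = consensus)
  })
}

#' Assign a query domain sequence to a subfamily
#'
#' The query is aligned jointly with the panel ([progressive_msa()]) and a
#' JTT-distance NJ tree is built. Every edge of the unrooted tree splits the
#' leaves in two; the side holding the query is an enclosing group. The
#' query inherits the shared label of the smallest enclosing group that
#' contains at least one reference; a smallest group with mixed labels, or
#' equally small groups with different labels, give `unassigned`.
#'
#' @param query named character vector of length 1 (the query domain
#'   sequence).
#' @param panel a [reference_panel()].
#' @return list with `subfamily` (label or `"unassigned"`) and `tree`.
#' @export
classify_query <- function(query, panel) {
  if (nrow(panel) == 0) stop("empty reference panel")
  qid <- names(query)
  if (is.null(qid)) stop("query must be named")
  seqs <- c(setNames(panel$seq, panel$id), query)
  msa <- progressive_msa(seqs)
  tree <- nj_tree(jtt_distance_matrix(msa))
  labels <- setNames(panel$subfamily, panel$id)
  all_tips <- tree$tip.label
  n_tip <- length(all_tips)
  # tip sets below every edge (child side), in ape's stored orientation
  desc <- vector("list", max(tree$edge))
  for (t in seq_len(n_tip)) desc[[t]] <- all_tips[t]
  for (e in ape::postorder(tree)) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    if (is.null(desc[[parent]])) desc[[parent]] <- character(0)
    desc[[parent]] <- c(desc[[parent]], desc[[child]])
  }
  best_refs <- Inf; best_labels <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    side <- desc[[tree$edge[e, 2]]]
    group <- if (qid %in% side) side else setdiff(all_tips, side)
    refs <- setdiff(group, qid)
    if (length(refs) == 0) next
    if (length(refs) < best_refs) {
      best_refs <- length(refs)
      best_labels <- unique(labels[refs])
    } else if (length(refs) == best_refs) {
      best_labels <- unique(c(best_labels, labels[refs]))
    }
  }
  if (is.infinite(best_refs)) {
    # star-like tree: every edge groups the query with all references
    best_labels <- unique(labels)
  }
  sub <- if (length(best_labels) == 1) best_labels else "unassigned"
  list(subfamily = unname(sub), tree = tree)
}

#' Subfamily assignment with N-terminal-domain precedence
#'
#' Classifies the query independently on the NTD and CTD panels; when the
#' two domains disagree, the NTD call stands and the conflict is flagged.
#' A query lacking one domain is classified on the other alone.
#'
#' @param gene_id gene identifier carried into the result.
#' @param ntd_seq,ctd_seq domain sequences (either may be `NA`).
#' @param ntd_panel,ctd_panel [reference_panel()]s per domain.
#' @return a `subfamily_assignment`: data.frame row with `gene_id`,
#'   `subfamily`, `domain_used`, `conflict`, `ntd_call`, `ctd_call`.
#' @export
assign_subfamily <- function(gene_id, ntd_seq = NA, ctd_seq = NA,
                             ntd_panel = NULL, ctd_panel = NULL) {
  ntd_call <- if (!is.na(ntd_seq) && !is.null(ntd_panel)) {
    classify_query(setNames(ntd_seq, gene_id), ntd_panel)$subfamily
  } else NA_character_
  ctd_call <- if (!is.na(ctd_seq) && !is.null(ctd_panel)) {
    classify_query(setNames(ctd_seq, gene_id), ctd_panel)$subfamily
  } else NA_character_
  if (is.na(ntd_call) && is.na(ctd_call)) {
    stop("no domain sequence/panel available for ", gene_id)
  }
  conflict <- !is.na(ntd_call) && !is.na(ctd_call) && ntd_call != ctd_call
  subfamily <- if (!is.na(ntd_call)) ntd_call else ctd_call
  domain_used <- if (!is.na(ntd_call)) "NTD" else "CTD"
  data.frame(gene_id = gene_id, subfamily = subfamily,
             domain_used = domain_used, conflict = conflict,
             ntd_call = ntd_call, ctd_call = ctd_call,
             stringsAsFactors = FALSE)
}
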