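# ---------------------------------------------------------------------------
# Expansion-mechanism classification: the three-rule tandem classifier, the
# collinear anchor chaining that defines segmental duplication blocks
# (>= 5 anchor pairs), and mobile-element overlap within 50 kb flanks.
# ---------------------------------------------------------------------------

#' Genome-size dependent tandem proximity window
#'
#' 100 kb for assemblies under 200 Mb, 350 kb otherwise.
#'
#' @param genome_size assembly size in bp (> 0).
#' @return window in bp (100000 or 350000).
#' @export
tandem_window <- function(genome_size) {
  stopifnot(genome_size > 0)
  ifelse(genome_size < 200e6, 100000, 350000)
}

#' Three-rule tandem duplication call
#'
#' A child gene is a tandem duplicate of its putative parent when (1) at
#' least 30% of the child's residues align to the parent (local alignment at
#' E <= 0.01), (2) the aligned region shows at least 70% identity, and (3)
#' the genes are proximal: no more than 10 gene ranks apart (`|rank_a -
#' rank_b| <= 10`) and within the genome-size window
#' ([tandem_window()], measured midpoint to midpoint). Genes on different
#' chromosomes fail proximity (verdict `FALSE`), not an error.
#'
#' @param child_id,parent_id gene ids present in `annotation`.
#' @param alignment a [local_align()] result with the *child* as query, or
#'   `NULL` to compute it from `proteins`.
#' @param annotation a [genome_annotation].
#' @param proteins a [tps_seqs] (needed when `alignment` is `NULL`).
#' @param e_cutoff alignment significance gate (default 0.01); a
#'   non-significant alignment zeroes the coverage/identity evidence.
#' @param min_coverage,min_identity,max_rank_distance rule thresholds.
#' @return a `tandem_call`: list with `child`, `parent`, `identity`,
#'   `coverage`, `rank_distance`, `bp_distance`, `window`, `rule_flags`
#'   (named logical: coverage, identity, proximity) and `verdict`
#'   (= AND of the flags).
#' @export
call_tandem <- function(child_id, parent_id, alignment = NULL,
                        annotation, proteins = NULL, e_cutoff = 0.01,
                        min_coverage = 0.30, min_identity = 0.70,
                        max_rank_distance = 10) {
  g <- annotation$genes
  child <- g[g$gene_id == child_id, ]
  parent <- g[g$gene_id == parent_id, ]
  if (nrow(child) != 1 || nrow(parent) != 1) {
    stop("child or parent not found in annotation")
  }
  if (is.null(alignment)) {
    if (is.null(proteins)) stop("need either an alignment or proteins")
    alignment <- local_align(proteins[[child_id]], proteins[[parent_id]],
                             query_id = child_id, subject_id = parent_id)
  }
  significant <- !is.null(alignment$evalue) && !is.na(alignment$evalue) &&
    alignment$evalue <= e_cutoff
  identity <- if (significant) alignment$identity else 0
  coverage <- if (significant) alignment$query_coverage else 0
  window <- tandem_window(annotation$genome_size)
  same_chrom <- child$chrom == parent$chrom
  rank_distance <- if (same_chrom) abs(child$rank - parent$rank) else NA_integer_
  mid <- function(x) (x$start + x$end) / 2
  bp_distance <- if (same_chrom) abs(mid(child) - mid(parent)) else NA_real_
  rule_flags <- c(
    coverage = coverage >= min_coverage,
    identity = identity >= min_identity,
    proximity = isTRUE(same_chrom && rank_distance <= max_rank_distance &&
                         bp_distance <= window))
  structure(list(child = child_id, parent = parent_id,
                 identity = identity, coverage = coverage,
                 rank_distance = rank_distance, bp_distance = bp_distance,
                 window = window, rule_flags = rule_flags,
                 verdict = all(rule_flags)),
            class = "tandem_call")
}

#' @export
print.tandem_call <- function(x, ...) {
  cat(sprintf(paste0("tandem_call %s -> %s: %s (identity %.2f, coverage ",
                     "%.2f, ranks %s, %s bp)\n"),
              x$child, x$parent, if (x$verdict) "TANDEM" else "not tandem",
              x$identity, x$coverage,
              ifelse(is.na(x$rank_distance), "NA", x$rank_distance),
              ifelse(is.na(x$bp_distance), "NA",
                     format(x$bp_distance, big.mark = ","))))
  invisible(x)
}

#' Call tandem duplication for all family gene pairs on a chromosome
#'
#' Convenience wrapper: evaluates [call_tandem()] for every ordered pair of
#' family genes that share a chromosome and returns the calls as a table.
#'
#' @param family_ids gene ids of the family under study.
#' @param annotation a [genome_annotation].
#' @param proteins a [tps_seqs].
#' @param ... passed to [call_tandem()].
#' @return data.frame with one row per evaluated pair.
#' @export
tandem_scan <- function(family_ids, annotation, proteins, ...) {
  g <- annotation$genes
  g <- g[g$gene_id %in% family_ids, ]
  rows <- list()
  for (chrom in unique(g$chrom)) {
    ids <- g$gene_id[g$chrom == chrom]
    if (length(ids) < 2) next
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i == j) next
      cl <- call_tandem(ids[j], ids[i], annotation = annotation,
                        proteins = proteins, ...)
      rows[[length(rows) + 1]] <- data.frame(
        child = cl$child, parent = cl$parent, identity = cl$identity,
        coverage = cl$coverage, rank_distance = cl$rank_distance,
        bp_distance = cl$bp_distance, verdict = cl$verdict,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(child = character(), parent = character(),
               identity = numeric(), coverage = numeric(),
               rank_distance = integer(), bp_distance = numeric(),
               verdict = logical())
  rownames(out) <- NULL
  out
}

#' Chain collinear anchor pairs into synteny blocks
#'
#' DAGchainer-style sparse dynamic programming over anchor pairs: anchors
#' are chained when both coordinates increase (or, for the antiparallel
#' orientation, one increases while the other decreases), with a linear gap
#' penalty in both coordinate gaps. Maximum-score chains are reported
#' greedily (best chain, remove its anchors, repeat); chains with fewer than
#' `min_pairs` anchors are discarded.
#'
#' @param anchors data.frame with columns `geneA`, `geneB`, `posA`, `posB`
#'   (gene rank or bp positions on the two chromosomes), deduplicated.
#' @param max_gap maximum allowed gap between chained anchors, in the units
#'   of `posA`/`posB` (default 10, suited to gene-rank coordinates).
#' @param min_pairs minimum anchors per reported block (default 5).
#' @param anchor_score score per chained anchor.
#' @param gap_penalty linear penalty per unit gap.
#' @return list of `synteny_block`s: each a list with `anchor_pairs`
#'   (data.frame), `chain_score` and `orientation` (`"parallel"` or
#'   `"antiparallel"`).
#' @export
chain_anchors <- function(anchors, max_gap = 10, min_pairs = 5,
                          anchor_score = 1, gap_penalty = 0.05) {
  blocks <- list()
  if (NROW(anchors) == 0) return(blocks)
  remaining <- anchors
  repeat {
    best <- NULL
    for (orientation in c("parallel", "antiparallel")) {
      ch <- best_chain(remaining, orientation, max_gap, anchor_score,
                       gap_penalty)
      if (!is.null(ch) && (is.null(best) || ch$score > best$score)) best <- ch
    }
    if (is.null(best) || length(best$idx) < min_pairs) break
    blocks[[length(blocks) + 1]] <- structure(
      list(anchor_pairs = remaining[best$idx, c("geneA", "geneB"),
                                    drop = FALSE],
           chain_score = best$score, orientation = best$orientation),
      class = "synteny_block")
    remaining <- remaining[-best$idx, , drop = FALSE]
    if (nrow(remaining) < min_pairs) break
  }
  blocks
}

# O(n^2) chain DP; orientation "antiparallel" flips posB.
best_chain <- function(anchors, orientation, max_gap, anchor_score,
                       gap_penalty) {
  n <- nrow(anchors)
  if (n == 0) return(NULL)
  a <- anchors$posA
  b <- if (orientation == "parallel") anchors$posB else -anchors$posB
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  score <- rep(anchor_score, n)
  prev <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      da <- a[i] - a[j]; db <- b[i] - b[j]
      if (da <= 0 || db <= 0 || da > max_gap || db > max_gap) next
      cand <- score[j] + anchor_score - gap_penalty * (da + db - 2)
      if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
    }
  }
  end <- which.max(score)
  idx <- integer(0)
  i <- end
  while (!is.na(i)) { idx <- c(i, idx); i <- prev[i] }
  list(idx = ord[idx], score = score[end], orientation = orientation)
}

#' @export
print.synteny_block <- function(x, ...) {
  cat("synteny_block: ", nrow(x$anchor_pairs), " anchor pairs (",
      x$orientation, "), score ", round(x$chain_score, 2), "\n", sep = "")
  invisible(x)
}

#' Mobile-element overlap with a gene and its 50 kb flanks
#'
#' Relations: `contained` when the gene interval lies inside the element;
#' `partial` when the intervals overlap without containment; `flank_only`
#' when the element intersects the +/- `window` flank but not the gene;
#' `none` otherwise. Only elements on the gene's chromosome are considered.
#'
#' @param gene_id a gene in `annotation`.
#' @param annotation a [genome_annotation].
#' @param elements data.frame (`chrom`, `start`, `end`, `feature_type`),
#'   1-based inclusive.
#' @param window flank size in bp (default 50000).
#' @return an `element_overlap`: list with `gene_id`, `relation` (the
#'   closest relation in the order contained > partial > flank_only >
#'   none), and `evidence` (per-element relations).
#' @export
flank_overlap <- function(gene_id, annotation, elements, window = 50000) {
  g <- annotation$genes
  gene <- g[g$gene_id == gene_id, ]
  if (nrow(gene) != 1) stop("gene not found: ", gene_id)
  el <- elements[elements$chrom == gene$chrom, , drop = FALSE]
  relation_of <- function(es, ee) {
    if (gene$start >= es && gene$end <= ee) return("contained")
    if (es <= gene$end && ee >= gene$start) return("partial")
    if (es <= gene$end + window && ee >= gene$start - window) {
      return("flank_only")
    }
    "none"
  }
  rel <- if (nrow(el)) mapply(relation_of, el$start, el$end) else character(0)
  order_levels <- c("contained", "partial", "flank_only", "none")
  best <- if (length(rel)) order_levels[min(match(rel, order_levels))] else "none"
  structure(list(gene_id = gene_id, relation = best,
                 evidence = if (nrow(el)) cbind(el, relation = rel) else el,
                 window = window),
            class = "element_overlap")
}

#' @export
print.element_overlap <- function(x, ...) {
  cat("element_overlap ", x$gene_id, ": ", x$relation, "\n", sep = "")
  invisible(x)
}
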