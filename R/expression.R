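# ---------------------------------------------------------------------------
# Expression profiling: FPKM, log2 transformation with zero masking,
# tissue-preferred calling (>= 2x against every other tissue plus a t-test),
# and duplicate-pair expression divergence.
# ---------------------------------------------------------------------------

#' FPKM from raw counts
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * total[s])`.
#'
#' @param counts gene x sample matrix of raw counts.
#' @param gene_lengths named transcript lengths in bp (> 0), covering all
#'   rows of `counts`.
#' @param totals per-sample mapped-fragment totals (> 0); defaults to the
#'   per-sample count sums.
#' @return FPKM matrix with the dimnames of `counts`.
#' @export
fpkm <- function(counts, gene_lengths, totals = colSums(counts)) {
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0)) {
    stop("every gene needs a positive length")
  }
  if (any(totals <= 0)) stop("zero per-sample total")
  counts * 1e9 / outer(as.numeric(gene_lengths), as.numeric(totals))
}

#' log2 transform with zero masking
#'
#' Zeros mean "no expression": they are masked (NA in the returned matrix,
#' TRUE in the `mask` attribute) rather than transformed, and downstream
#' fold computations treat them as silent.
#'
#' @param x non-negative matrix (FPKM or normalized values).
#' @return log2 matrix with NA at masked cells and a logical `mask`
#'   attribute.
#' @export
log2_matrix <- function(x) {
  if (any(x < 0)) stop("negative expression values")
  mask <- x == 0
  out <- suppressWarnings(log2(x))
  out[mask] <- NA
  attr(out, "mask") <- mask
  out
}

# per-tissue value matrix (linear scale) for one gene: list of replicate
# vectors keyed by tissue
tissue_values <- function(table, gene) {
  vals <- expression_values(table)[gene, ]
  split(unname(vals), table$design$tissue)[unique(table$design$tissue)]
}

# linear-scale expression used by the calling rules: FPKM in counts mode,
# the stored values in normalized mode
expression_values <- function(table) {
  if (!is.null(attr(table, "linear_cache"))) return(attr(table, "linear_cache"))
  if (table$mode == "counts") {
    if (is.null(table$gene_lengths)) {
      stop("counts mode needs gene_lengths for FPKM")
    }
    fpkm(table$values, table$gene_lengths)
  } else {
    table$values
  }
}

#' Tissue-preferred expression calls
#'
#' A gene is preferred in its top tissue when its mean linear expression is
#' at least `fold` times the mean of *every* other tissue and a two-sample
#' Student's t-test (pooled variance by default; set `var_equal = FALSE`
#' for Welch) against every other tissue gives `p < alpha`. Genes silent
#' everywhere are excluded; comparisons against tissues with fewer than 2
#' replicates are skipped with a warning (fold-only evidence).
#'
#' @param table an [expression_table].
#' @param alpha significance level (default 0.05).
#' @param fold linear fold-change gate (default 2).
#' @param var_equal `TRUE` (default) for the classic pooled-variance
#'   Student's t-test; `FALSE` for Welch. At triplicate depth the pooled
#'   test keeps its degrees of freedom and with it the power the calling
#'   rule needs.
#' @return data.frame with one row per gene: `gene_id`, `tissue` (candidate
#'   top tissue), `min_fold_margin` (fold vs the best other tissue),
#'   `max_p` (largest t-test p across comparisons), `verdict`.
#' @export
call_tissue_preferred <- function(table, alpha = 0.05, fold = 2,
                                  var_equal = TRUE) {
  vals <- expression_values(table)
  tissues <- unique(table$design$tissue)
  if (length(tissues) < 2) stop("need >= 2 tissues")
  rows <- lapply(rownames(vals), function(g) {
    by_tissue <- split(vals[g, ], table$design$tissue)[tissues]
    means <- vapply(by_tissue, mean, 0)
    if (all(means == 0)) {
      return(data.frame(gene_id = g, tissue = NA_character_,
                        min_fold_margin = NA_real_, max_p = NA_real_,
                        verdict = FALSE, stringsAsFactors = FALSE))
    }
    top <- names(means)[which.max(means)]
    others <- setdiff(tissues, top)
    margins <- means[top] / means[others]
    ps <- vapply(others, function(o) {
      if (length(by_tissue[[top]]) < 2 || length(by_tissue[[o]]) < 2) {
        warning("tissue with < 2 replicates: comparison ", top, " vs ", o,
                " skipped")
        return(NA_real_)
      }
      if (sd(by_tissue[[top]]) == 0 && sd(by_tissue[[o]]) == 0) {
        # degenerate t-test: identical constants are not different,
        # distinct constants are
        return(if (mean(by_tissue[[top]]) == mean(by_tissue[[o]])) 1 else 0)
      }
      t.test(by_tissue[[top]], by_tissue[[o]], var.equal = var_equal)$p.value
    }, 0)
    min_fold <- min(margins)
    max_p <- if (all(is.na(ps))) NA_real_ else max(ps, na.rm = TRUE)
    verdict <- is.finite(min_fold) && min_fold >= fold &&
      !is.na(max_p) && max_p < alpha
    data.frame(gene_id = g, tissue = top, min_fold_margin = min_fold,
               max_p = max_p, verdict = verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression divergence of a duplicate gene pair
#'
#' The pair is diverged when some tissue shows at least `fold` difference
#' between the two genes with a t-test `p < alpha`, or when one gene is
#' expressed in a tissue where the other is silent (mean zero).
#'
#' @param gene_a,gene_b genes present in `table`.
#' @param table an [expression_table].
#' @param alpha significance level.
#' @param fold linear fold gate (default 2).
#' @param var_equal `TRUE` (default) for pooled-variance Student's t-test,
#'   `FALSE` for Welch (see [call_tissue_preferred()]).
#' @return a `divergence_call`: list with `pair`, `diverged`, and
#'   `evidence` (per-tissue means, fold, p, specificity change).
#' @export
pair_divergence <- function(gene_a, gene_b, table, alpha = 0.05, fold = 2,
                            var_equal = TRUE) {
  va <- tissue_values(table, gene_a)
  vb <- tissue_values(table, gene_b)
  tissues <- names(va)
  ev <- lapply(tissues, function(t) {
    ma <- mean(va[[t]]); mb <- mean(vb[[t]])
    spec_change <- xor(ma == 0, mb == 0)
    fold_t <- if (min(ma, mb) == 0) Inf else max(ma, mb) / min(ma, mb)
    p <- if (length(va[[t]]) < 2 || length(vb[[t]]) < 2) NA_real_
         else if (sd(va[[t]]) == 0 && sd(vb[[t]]) == 0) {
           if (ma == mb) 1 else 0
         } else t.test(va[[t]], vb[[t]], var.equal = var_equal)$p.value
    sig <- spec_change || (is.finite(fold_t) && fold_t >= fold &&
                             !is.na(p) && p < alpha)
    data.frame(tissue = t, mean_a = ma, mean_b = mb, fold = fold_t,
               p = p, specificity_change = spec_change, diverged_here = sig,
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  structure(list(pair = c(gene_a, gene_b), diverged = any(ev$diverged_here),
                 evidence = ev),
            class = "divergence_call")
}

#' @export
print.divergence_call <- function(x, ...) {
  cat("divergence_call ", x$pair[1], " / ", x$pair[2], ": ",
      if (x$diverged) "DIVERGED" else "not diverged", "\n", sep = "")
  invisible(x)
}
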