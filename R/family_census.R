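# ---------------------------------------------------------------------------
# Merge domain-hit evidence into per-gene architectures and produce the
# full-length / N-only / C-only census with its domain-loss arithmetic.
# ---------------------------------------------------------------------------

#' Supplemental homology search for family members missed by the HMM scan
#'
#' Representative confirmed family members are aligned locally against the
#' proteome; proteins hit at `E <= e_cutoff` that are not already in the HMM
#' hit set become candidates. Candidates are only admitted after
#' re-verification by a domain scan (`verify_profiles` at
#' `verify_e_cutoff`); the rest are reported as unverified artifacts.
#'
#' @param representatives a [tps_seqs] of HMM-confirmed family members
#'   (non-empty).
#' @param proteome a [tps_seqs] to search.
#' @param known_ids gene ids already found by the HMM scan (excluded from
#'   the candidate set).
#' @param e_cutoff homology E-value threshold (default 0.01).
#' @param verify_profiles list of calibrated profiles used to re-verify
#'   candidates (typically the NTD and CTD profiles); `NULL` skips
#'   verification.
#' @param verify_e_cutoff E-value threshold for the verification scan.
#' @return list with `admitted` (gene ids confirmed by re-verification),
#'   `unverified` (homology-only ids, reported but not counted), and
#'   `hit_table` (per candidate best identity/coverage/E).
#' @export
supplemental_homology_search <- function(representatives, proteome, known_ids,
                                         e_cutoff = 0.01,
                                         verify_profiles = NULL,
                                         verify_e_cutoff = 1.0) {
  if (length(representatives) == 0) stop("empty representative set")
  cand <- setdiff(names(proteome), known_ids)
  rows <- list()
  for (id in cand) {
    best <- NULL
    for (r in seq_along(representatives)) {
      al <- local_align(representatives[[r]], proteome[[id]],
                        query_id = names(representatives)[r], subject_id = id,
                        search_space = nchar(representatives[[r]]) *
                          sum(nchar(proteome)))
      if (is.null(best) || al$evalue < best$evalue) best <- al
    }
    if (!is.infinite(best$evalue) && best$evalue <= e_cutoff) {
      rows[[id]] <- data.frame(gene_id = id, identity = best$identity,
                               coverage = best$query_coverage,
                               evalue = best$evalue, stringsAsFactors = FALSE)
    }
  }
  hit_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), identity = numeric(),
               coverage = numeric(), evalue = numeric())
  rownames(hit_table) <- NULL
  if (is.null(verify_profiles) || nrow(hit_table) == 0) {
    return(list(admitted = hit_table$gene_id, unverified = character(0),
                hit_table = hit_table))
  }
  verified <- character(0)
  for (id in hit_table$gene_id) {
    ok <- any(vapply(verify_profiles, function(p) {
      nrow(scan_proteome(p, proteome[id], e_cutoff = verify_e_cutoff)) > 0
    }, TRUE))
    if (ok) verified <- c(verified, id)
  }
  list(admitted = verified,
       unverified = setdiff(hit_table$gene_id, verified),
       hit_table = hit_table)
}

#' Classify per-gene domain architecture
#'
#' Reduces a domain-hit table to one architecture per gene: the category is
#' the deterministic function of the two booleans (has NTD / has CTD hit);
#' duplicate hits of the same domain on one gene do not change the category.
#'
#' @param hits a [scan_proteome()]-style data.frame (`seq_id`, `domain`)
#'   pooled over the NTD and CTD scans.
#' @param gene_ids all gene ids under consideration (genes without hits get
#'   category `"none"`).
#' @param ntd_label,ctd_label domain labels counted as N- and C-terminal.
#' @return data.frame with `gene_id`, `has_ntd`, `has_ctd`, `category`
#'   (`full_length`, `ntd_only`, `ctd_only`, `none`).
#' @export
classify_architecture <- function(hits, gene_ids,
                                  ntd_label = "NTD", ctd_label = "CTD") {
  if (nrow(hits) > 0 && !all(hits$seq_id %in% gene_ids)) {
    stop("hit table references unknown gene id(s): ",
         paste(setdiff(unique(hits$seq_id), gene_ids), collapse = ", "))
  }
  has_ntd <- gene_ids %in% hits$seq_id[hits$domain == ntd_label]
  has_ctd <- gene_ids %in% hits$seq_id[hits$domain == ctd_label]
  category <- ifelse(has_ntd & has_ctd, "full_length",
              ifelse(has_ntd, "ntd_only",
              ifelse(has_ctd, "ctd_only", "none")))
  data.frame(gene_id = gene_ids, has_ntd = has_ntd, has_ctd = has_ctd,
             category = category, stringsAsFactors = FALSE)
}

#' Family census and domain-loss counts
#'
#' Either summarizes an architecture table or, given the domain totals and
#' the full-length count, applies the subtraction identities directly:
#' `n_ntd_only = n_ntd_total - n_full` (genes that lost the C-terminal
#' domain) and `n_ctd_only = n_ctd_total - n_full` (genes that lost the
#' N-terminal domain).
#'
#' @param architectures a [classify_architecture()] result, or `NULL` when
#'   the three totals are given directly.
#' @param n_ntd_total,n_ctd_total,n_full direct counts (used when
#'   `architectures` is `NULL`).
#' @param species species label.
#' @return a `census_summary`: list with `species`, `n_ntd_total`,
#'   `n_ctd_total`, `n_full`, `n_ntd_only`, `n_ctd_only`, `n_tps`.
#' @export
census <- function(architectures = NULL, n_ntd_total = NULL,
                   n_ctd_total = NULL, n_full = NULL, species = "synthetic") {
  if (!is.null(architectures)) {
    n_ntd_total <- sum(architectures$has_ntd)
    n_ctd_total <- sum(architectures$has_ctd)
    n_full <- sum(architectures$category == "full_length")
  }
  n_ntd_only <- n_ntd_total - n_full
  n_ctd_only <- n_ctd_total - n_full
  if (n_ntd_only < 0 || n_ctd_only < 0) {
    stop("inconsistent totals: full-length count exceeds a domain total")
  }
  structure(list(species = species,
                 n_ntd_total = n_ntd_total, n_ctd_total = n_ctd_total,
                 n_full = n_full, n_ntd_only = n_ntd_only,
                 n_ctd_only = n_ctd_only,
                 n_tps = n_full + n_ntd_only + n_ctd_only),
            class = "census_summary")
}

#' @export
print.census_summary <- function(x, ...) {
  cat(sprintf(paste0("census_summary [%s]: %d TPS genes; %d full-length, ",
                     "%d N-terminal only (lost CTD), %d C-terminal only ",
                     "(lost NTD)\n"),
              x$species, x$n_tps, x$n_full, x$n_ntd_only, x$n_ctd_only))
  invisible(x)
}

#' Flag sequences with premature stop codons
#'
#' Proteins containing an internal `*` are putative pseudogenes: they stay
#' in the census but are excluded from phylogenetic analysis. A single
#' trailing `*` (a translated terminal stop) is not flagged.
#'
#' @param seqs a [tps_seqs].
#' @return logical vector named by gene id.
#' @export
has_premature_stop <- function(seqs) {
  vapply(seq_along(seqs), function(i) {
    s <- sub("\\*$", "", seqs[[i]])
    grepl("*", s, fixed = TRUE)
  }, TRUE) |> setNames(names(seqs))
}

#' Write census tables to TSV
#'
#' @param summary a `census_summary`.
#' @param architectures the per-gene architecture table.
#' @param census_path,architecture_path output files.
#' @return invisibly, the paths.
#' @export
write_census <- function(summary, architectures, census_path,
                         architecture_path) {
  df <- data.frame(species = summary$species,
                   n_ntd_total = summary$n_ntd_total,
                   n_ctd_total = summary$n_ctd_total,
                   n_full = summary$n_full,
                   n_ntd_only = summary$n_ntd_only,
                   n_ctd_only = summary$n_ctd_only)
  write.table(df, census_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(architectures, architecture_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(census_path, architecture_path))
}
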