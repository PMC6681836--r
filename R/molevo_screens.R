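# ---------------------------------------------------------------------------
# Molecular-evolution screens: pairwise Nei-Gojobori (1986) Ka/Ks with
# Jukes-Cantor correction, the partial-C-terminal-domain (PPD) motif
# pipeline linking TPSs to isoprenyl diphosphate synthases, conserved-column
# analysis, and the horizontal-gene-transfer rule engine.
# ---------------------------------------------------------------------------

CODON_BASES <- c("T", "C", "A", "G")

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Replaces each aligned residue by its source codon (gaps become `---`),
#' giving the codon-aware nucleotide alignment used for Ka/Ks.
#'
#' @param aligned_protein gapped protein string.
#' @param cds ungapped coding sequence for the same protein (length 3x the
#'   ungapped protein length; a trailing stop codon is tolerated and
#'   dropped).
#' @return gapped CDS string.
#' @export
back_translate <- function(aligned_protein, cds) {
  cds <- toupper(gsub("U", "T", cds))
  chars <- strsplit(toupper(aligned_protein), "")[[1]]
  n_res <- sum(!chars %in% GAP_CHARS)
  if (nchar(cds) == 3 * (n_res + 1)) cds <- substr(cds, 1, 3 * n_res)
  if (nchar(cds) != 3 * n_res) {
    stop("cds length does not match the ungapped protein (", nchar(cds),
         " vs ", 3 * n_res, " nt)")
  }
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  out <- character(length(chars))
  k <- 0
  for (i in seq_along(chars)) {
    if (chars[i] %in% GAP_CHARS) {
      out[i] <- "---"
    } else {
      k <- k + 1
      out[i] <- codons[k]
    }
  }
  paste(out, collapse = "")
}

# NG86 synonymous site count of one codon: at each position the three
# alternative nucleotides are examined; changes to stop codons are excluded
# and the fractions renormalized, so every codon contributes exactly 3
# sites (S + N = 3).
ng86_codon_sites <- function(codon, code = genetic_code()) {
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    alt <- setdiff(CODON_BASES, substr(codon, pos, pos))
    syn <- 0; valid <- 0
    for (b in alt) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == "*") next
      valid <- valid + 1
      if (code[[mut]] == aa) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal substitution pathways; pathways through stop codons are excluded
# unless every pathway hits a stop, in which case all pathways count and
# steps involving a stop are nonsynonymous.
ng86_codon_diffs <- function(codon_a, codon_b, code = genetic_code()) {
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  d <- length(diff_pos)
  if (d == 0) return(c(sd = 0, nd = 0))
  paths <- perms(diff_pos)
  tally <- function(order, allow_stop) {
    cur <- codon_a
    sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (!allow_stop && (code[[cur]] == "*" || code[[nxt]] == "*")) {
        return(NULL)
      }
      if (code[[cur]] == code[[nxt]] && code[[cur]] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- lapply(paths, tally, allow_stop = FALSE)
  res <- res[!vapply(res, is.null, TRUE)]
  if (length(res) == 0) res <- lapply(paths, tally, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1]] <- c(x[i], rest)
  }
  out
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Site counts are fractional per codon (renormalized after excluding
#' mutations to stop codons) and averaged over the two sequences;
#' differences average the synonymous/nonsynonymous step counts over all
#' minimal substitution pathways between differing codons (stop-crossing
#' pathways excluded); the proportions are Jukes-Cantor corrected. Codons
#' with a gap in either sequence are dropped pairwise.
#'
#' @param cds_a,cds_b aligned coding sequences (equal length, divisible by
#'   3, gaps allowed, no internal stop codons).
#' @param max_dist cap applied to a saturated corrected distance.
#' @return a `kaks_result`: list with `ka`, `ks`, `ratio`,
#'   `ratio_defined`, site counts `n`, `s`, difference counts `nd`, `sd`,
#'   proportions `pn`, `ps`, `n_codons`, and `saturated` flags.
#' @export
ng86_kaks <- function(cds_a, cds_b, max_dist = 10) {
  cds_a <- toupper(gsub("U", "T", cds_a))
  cds_b <- toupper(gsub("U", "T", cds_b))
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned CDS differ in length")
  if (nchar(cds_a) %% 3 != 0) stop("alignment length not divisible by 3")
  code <- genetic_code()
  starts <- seq(1, nchar(cds_a), 3)
  ca <- substring(cds_a, starts, starts + 2)
  cb <- substring(cds_b, starts, starts + 2)
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) stop("no ungapped codon pairs")
  if (any(code[ca] == "*") || any(code[cb] == "*")) {
    stop("internal stop codon in coding sequence")
  }
  s_sites <- (vapply(ca, ng86_codon_sites, 0, code = code) +
              vapply(cb, ng86_codon_sites, 0, code = code)) / 2
  S <- sum(s_sites)
  N <- 3 * length(ca) - S
  diffs <- mapply(function(a, b) ng86_codon_diffs(a, b, code), ca, cb)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(structure(max_dist, saturated = TRUE))
    structure(-3 / 4 * log(1 - 4 * p / 3), saturated = FALSE)
  }
  ks <- jc(ps); ka <- jc(pn)
  ratio_defined <- as.numeric(ks) > 0
  structure(list(ka = as.numeric(ka), ks = as.numeric(ks),
                 ratio = if (ratio_defined) as.numeric(ka) / as.numeric(ks)
                         else NA_real_,
                 ratio_defined = ratio_defined,
                 n = N, s = S, nd = Nd, sd = Sd, pn = pn, ps = ps,
                 n_codons = length(ca),
                 saturated = c(ka = attr(ka, "saturated"),
                               ks = attr(ks, "saturated"))),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("kaks_result: Ka %.4f, Ks %.4f, Ka/Ks %s (%d codons)\n",
              x$ka, x$ks,
              if (x$ratio_defined) sprintf("%.3f", x$ratio) else "undefined",
              x$n_codons))
  invisible(x)
}

# ---------------------------------------------------------------------------
# PPD motif pipeline
# ---------------------------------------------------------------------------

#' Discover partial C-terminal-domain (PPD) seeds in IDS proteins
#'
#' Scans an IDS protein set with the C-terminal-domain profile at a relaxed
#' E-value cutoff (the standard cutoff misses these degenerate envelopes),
#' extracts the envelope subsequences and deduplicates them by exact string
#' equality.
#'
#' @param ids_seqs a [tps_seqs] of IDS proteins.
#' @param ctd_profile calibrated C-terminal-domain profile.
#' @param relaxed_e relaxed E-value cutoff (default 100).
#' @return list with `seeds` (unique envelope strings), `n_raw`,
#'   `n_unique`, and the underlying `hits` table.
#' @export
discover_ppd <- function(ids_seqs, ctd_profile, relaxed_e = 100) {
  hits <- scan_proteome(ctd_profile, ids_seqs, e_cutoff = relaxed_e)
  segs <- character(0)
  if (nrow(hits) > 0) {
    segs <- vapply(seq_len(nrow(hits)), function(i) {
      substr(ids_seqs[[hits$seq_id[i]]], hits$env_start[i], hits$env_end[i])
    }, "")
  }
  seeds <- unique(segs)
  list(seeds = seeds, n_raw = length(segs), n_unique = length(seeds),
       hits = hits)
}

#' Build a PPD profile from discovered seeds
#'
#' Aligns the unique seeds ([progressive_msa()]) and builds a profile
#' calibrated against the lengths of the sets it will scan.
#'
#' @param seeds unique seed strings (>= 2).
#' @param null_lengths lengths used for E-value calibration.
#' @param seed RNG seed for calibration.
#' @return a calibrated `profile_hmm` labeled `"PPD"`.
#' @export
build_ppd_profile <- function(seeds, null_lengths, seed = 1) {
  if (length(seeds) < 2) stop("need >= 2 unique seeds to build a profile")
  msa <- progressive_msa(setNames(seeds, sprintf("ppd%03d", seq_along(seeds))))
  prof <- build_profile(msa, label = "PPD")
  calibrate_profile(prof, null_lengths, seed = seed)
}

#' Per-set PPD hit report
#'
#' Scans each named protein set with the PPD profile and reports hit counts
#' and percentages (exact ratio, half-up rounding to one decimal).
#'
#' @param ppd_profile calibrated PPD profile.
#' @param target_sets named list of [tps_seqs] sets.
#' @param e_cutoff E-value cutoff for a hit.
#' @return data.frame with `set`, `n_hits`, `set_size`, `percentage`.
#' @export
ppd_scan_report <- function(ppd_profile, target_sets, e_cutoff = 1.0) {
  if (any(lengths(target_sets) == 0)) stop("empty target set")
  rows <- lapply(names(target_sets), function(nm) {
    seqs <- target_sets[[nm]]
    hits <- scan_proteome(ppd_profile, seqs, e_cutoff = e_cutoff)
    n <- length(unique(hits$seq_id))
    data.frame(set = nm, n_hits = n, set_size = length(seqs),
               percentage = percent_of(n, length(seqs)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Conserved columns of a multiple alignment
#'
#' Returns the column indices whose non-gap residues reach the identity
#' threshold (fraction of residues equal to the modal residue; the default
#' 1.0 demands complete identity). With `subset`, conservation is assessed
#' over those rows only — the route used to find sites conserved in IDSs
#' but variable in TPSs.
#'
#' @param msa a [multiple_alignment].
#' @param identity_threshold in `(0, 1]`.
#' @param subset optional character vector of row ids.
#' @return integer vector of 1-based column indices.
#' @export
conserved_columns <- function(msa, identity_threshold = 1.0, subset = NULL) {
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  rows <- msa$rows
  if (!is.null(subset)) {
    missing <- setdiff(subset, names(rows))
    if (length(missing)) stop("subset rows not in alignment: ",
                              paste(missing, collapse = ", "))
    rows <- rows[subset]
  }
  m <- do.call(rbind, strsplit(rows, ""))
  which(vapply(seq_len(ncol(m)), function(j) {
    res <- m[, j]
    res <- res[!res %in% GAP_CHARS]
    if (length(res) == 0) return(FALSE)
    max(table(res)) / length(res) >= identity_threshold
  }, TRUE))
}

# ---------------------------------------------------------------------------
# Horizontal gene transfer screening
# ---------------------------------------------------------------------------

#' HGT rule engine on precomputed hit summaries
#'
#' Pure rule evaluation, exposed separately so the verdict logic can be
#' exercised on arbitrary evidence tables. A bacterial protein is an HGT
#' candidate iff its best plant hit has query coverage > `min_coverage` and
#' identity > `min_identity`, at least `min_plant_species` plant species
#' show such high-similarity hits, and no other bacterium has a homolog
#' above `bacterial_identity`.
#'
#' @param best_identity,best_coverage best plant hit metrics for the query.
#' @param n_plant_species_high number of plant species with
#'   coverage > `min_coverage` and identity > `min_identity` hits.
#' @param n_other_bacteria_with_homolog number of other bacteria with a
#'   homolog above `bacterial_identity`.
#' @param min_coverage,min_identity,min_plant_species,bacterial_identity
#'   rule thresholds (defaults 0.70, 0.80, 2, 0.50).
#' @return list with `verdict` (`"HGT_candidate"` or `"rejected"`) and
#'   `failed_rules` (character vector).
#' @export
hgt_rules <- function(best_identity, best_coverage, n_plant_species_high,
                      n_other_bacteria_with_homolog, min_coverage = 0.70,
                      min_identity = 0.80, min_plant_species = 2,
                      bacterial_identity = 0.50) {
  failed <- character(0)
  if (!(best_coverage > min_coverage)) failed <- c(failed, "coverage")
  if (!(best_identity > min_identity)) failed <- c(failed, "identity")
  if (!(n_plant_species_high >= min_plant_species)) {
    failed <- c(failed, "multiple_plant_species")
  }
  if (!(n_other_bacteria_with_homolog == 0)) {
    failed <- c(failed, "bacterial_homolog")
  }
  list(verdict = if (length(failed) == 0) "HGT_candidate" else "rejected",
       failed_rules = failed)
}

#' Screen bacterial proteins for plant-to-bacterium HGT
#'
#' Two stages. Candidate stage: a bacterial protein enters when its best
#' plant hit aligns at least `candidate_coverage` of the query at
#' `E <= e_cutoff`. Verdict stage: [hgt_rules()] on the best plant hit, the
#' number of plant species with high-similarity hits, and homologs in other
#' bacteria (a homolog is "significant" above 50% identity).
#'
#' @param bacterial_seqs a [tps_seqs] of query proteins.
#' @param plant_panels named list (by species) of [tps_seqs] TPS panels.
#' @param other_bacteria named list (by genome) of [tps_seqs] panels.
#' @param e_cutoff candidate-stage E-value threshold (default 0.01).
#' @param candidate_coverage candidate-stage coverage (default 0.70).
#' @param ... thresholds passed to [hgt_rules()].
#' @return data.frame with per-query evidence and verdicts.
#' @export
screen_hgt <- function(bacterial_seqs, plant_panels, other_bacteria,
                       e_cutoff = 0.01, candidate_coverage = 0.70, ...) {
  if (length(plant_panels) == 0) stop("empty plant panel list")
  rows <- lapply(seq_along(bacterial_seqs), function(qi) {
    q <- bacterial_seqs[[qi]]
    qid <- names(bacterial_seqs)[qi]
    best <- list(identity = 0, coverage = 0, evalue = Inf, subject = NA)
    n_species_high <- 0
    for (sp in names(plant_panels)) {
      sp_best <- NULL
      for (t in seq_along(plant_panels[[sp]])) {
        al <- local_align(q, plant_panels[[sp]][[t]], query_id = qid,
                          subject_id = names(plant_panels[[sp]])[t])
        if (is.null(sp_best) || al$score > sp_best$score) sp_best <- al
      }
      if (sp_best$identity > best$identity ||
          (sp_best$identity == best$identity &&
           sp_best$query_coverage > best$coverage)) {
        best <- list(identity = sp_best$identity,
                     coverage = sp_best$query_coverage,
                     evalue = sp_best$evalue, subject = sp_best$subject_id)
      }
      if (sp_best$query_coverage > candidate_coverage &&
          sp_best$identity > 0.80) {
        n_species_high <- n_species_high + 1
      }
    }
    n_bact <- 0
    for (bg in names(other_bacteria)) {
      ids <- vapply(seq_along(other_bacteria[[bg]]), function(t) {
        local_align(q, other_bacteria[[bg]][[t]])$identity
      }, 0)
      if (length(ids) && max(ids) > 0.50) n_bact <- n_bact + 1
    }
    is_candidate <- best$coverage >= candidate_coverage &&
      best$evalue <= e_cutoff
    rule <- hgt_rules(best$identity, best$coverage, n_species_high, n_bact,
                      ...)
    data.frame(query = qid, best_plant_hit = best$subject,
               best_identity = best$identity, best_coverage = best$coverage,
               best_evalue = best$evalue,
               n_plant_species_high = n_species_high,
               n_other_bacteria_with_homolog = n_bact,
               candidate = is_candidate,
               verdict = if (!is_candidate) "rejected" else rule$verdict,
               failed_rules = paste(
                 if (!is_candidate) union("candidate_stage", rule$failed_rules)
                 else rule$failed_rules, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
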