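# ---------------------------------------------------------------------------
# Profile hidden Markov models: construction from seed alignments, Viterbi /
# forward scoring against a background null, empirical E-value calibration,
# and proteome scanning. This is the identification engine of the survey:
# one profile per domain (NTD = PF01397-like, CTD = PF03936-like, IDS =
# PF00348-like, PPD = the 33-aa partial C-terminal motif).
# ---------------------------------------------------------------------------

GAP_CHARS <- c("-", ".")

#' Build a profile HMM from a seed alignment
#'
#' Columns whose non-gap fraction is at least `match_fraction` become match
#' states; other columns are assigned to insert states. Emission and
#' transition counts receive a Laplace pseudocount and are normalized; the
#' background distribution is the pseudocounted residue frequency of the
#' whole seed alignment.
#'
#' @param msa a [multiple_alignment] with >= 2 rows.
#' @param label domain name carried on hits (e.g. `"NTD"`, `"CTD"`).
#' @param pseudocount Laplace pseudocount added to every count cell.
#' @param match_fraction minimum non-gap fraction for a match column.
#' @return a `profile_hmm`: list with `label`, `L`, `match_emissions`
#'   (L x 20), `insert_emissions` ((L+1) x 20, row k+1 = insert state after
#'   match column k), `transitions` ((L+1) x 7 columns MM MI MD IM II DM DD),
#'   `background`, `consensus`, and `calibration` (`NULL` until
#'   [calibrate_profile()] is run).
#' @export
build_profile <- function(msa, label = "domain", pseudocount = 1,
                          match_fraction = 0.5) {
  rows <- do.call(rbind, strsplit(toupper(msa$rows), ""))
  if (nrow(rows) < 2) stop("need at least 2 alignment rows")
  is_gap <- matrix(rows %in% GAP_CHARS, nrow(rows))
  is_res <- matrix(rows %in% AA_ALPHABET20, nrow(rows))
  match_cols <- which(colMeans(!is_gap) >= match_fraction)
  L <- length(match_cols)
  if (L == 0) stop("no alignment column qualifies as a match state")
  col_state <- integer(ncol(rows))           # match index, 0 for insert cols
  col_state[match_cols] <- seq_len(L)

  me <- matrix(pseudocount, L, 20, dimnames = list(NULL, AA_ALPHABET20))
  ie <- matrix(pseudocount, L + 1, 20, dimnames = list(NULL, AA_ALPHABET20))
  tr_names <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  tc <- matrix(pseudocount, L + 1, 7, dimnames = list(NULL, tr_names))

  for (r in seq_len(nrow(rows))) {
    # state sequence for this row: (type, k) with type M/D at match columns,
    # I at insert columns carrying the current match index
    k <- 0L
    prev <- c("M", 0L)                       # begin state acts as M_0
    for (j in seq_len(ncol(rows))) {
      if (col_state[j] > 0) {
        k <- col_state[j]
        if (is_res[r, j]) {
          me[k, rows[r, j]] <- me[k, rows[r, j]] + 1
          cur <- c("M", k)
        } else {
          cur <- c("D", k)
        }
        tname <- paste0(prev[1], cur[1])
        # I->D and D->I have no core transition; they are dropped and the
        # pseudocounts keep every row normalizable
        if (tname %in% tr_names) {
          tc[as.integer(prev[2]) + 1L, tname] <- tc[as.integer(prev[2]) + 1L, tname] + 1
        }
        prev <- cur
      } else if (is_res[r, j]) {
        ie[k + 1L, rows[r, j]] <- ie[k + 1L, rows[r, j]] + 1
        tname <- paste0(prev[1], "I")
        if (tname %in% tr_names) {
          tc[as.integer(prev[2]) + 1L, tname] <- tc[as.integer(prev[2]) + 1L, tname] + 1
        }
        prev <- c("I", k)
      }
    }
    # closing transition into the (virtual) end state, counted as *M
    tname <- paste0(prev[1], "M")
    tc[as.integer(prev[2]) + 1L, tname] <- tc[as.integer(prev[2]) + 1L, tname] + 1
  }

  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  tr <- tc
  tr[, c("MM", "MI", "MD")] <- tc[, c("MM", "MI", "MD")] /
    rowSums(tc[, c("MM", "MI", "MD"), drop = FALSE])
  tr[, c("IM", "II")] <- tc[, c("IM", "II")] /
    rowSums(tc[, c("IM", "II"), drop = FALSE])
  tr[, c("DM", "DD")] <- tc[, c("DM", "DD")] /
    rowSums(tc[, c("DM", "DD"), drop = FALSE])

  res_counts <- table(factor(rows[is_res], levels = AA_ALPHABET20))
  background <- (as.numeric(res_counts) + pseudocount) /
    (sum(res_counts) + 20 * pseudocount)
  names(background) <- AA_ALPHABET20

  consensus <- paste(AA_ALPHABET20[apply(me, 1, which.max)], collapse = "")
  structure(list(label = label, L = L, match_emissions = me,
                 insert_emissions = ie, transitions = tr,
                 background = background, consensus = consensus,
                 calibration = NULL),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile_hmm '", x$label, "': L = ", x$L,
      if (is.null(x$calibration)) ", uncalibrated" else ", calibrated",
      "\n", sep = "")
  invisible(x)
}

# assemble the natural-log parameter set consumed by the C++ kernel
profile_log_params <- function(profile) {
  key <- paste0("logpar_", profile$label, "_", profile$L,
                "_", signif(sum(profile$match_emissions), 12))
  bg <- profile$background
  match_lodds <- log(sweep(profile$match_emissions, 2, bg, "/"))
  L <- profile$L
  ins_lodds <- matrix(0, L, 20)
  if (L > 1) {
    core <- profile$insert_emissions[2:L, , drop = FALSE]
    ins_lodds[seq_len(L - 1), ] <- log(sweep(core, 2, bg, "/"))
  }
  list(match_lodds = match_lodds, ins_lodds = ins_lodds,
       lt = log(profile$transitions))
}

#' Score a protein with a profile HMM
#'
#' `hmm_viterbi` returns the best-path log-odds bit score together with the
#' envelope (sequence coordinates emitted by the profile core on the best
#' path) and the span of match columns used; `hmm_forward` returns the
#' all-paths (forward) bit score, which is the score calibrated into
#' E-values. Masked positions cannot be emitted by the core, which is how
#' secondary domains are searched after a first envelope is found.
#'
#' @param profile a [build_profile()] result.
#' @param seq protein sequence (string).
#' @param mask optional logical vector (length `nchar(seq)`).
#' @return `hmm_viterbi`: list with `bits`, `env_start`, `env_end`,
#'   `first_col`, `last_col`; `hmm_forward`: bit score (numeric).
#' @export
hmm_viterbi <- function(profile, seq, mask = NULL) {
  idx <- aa_to_index(check_protein(seq))
  idx[is.na(idx)] <- 0L
  mask <- mask %||% rep(FALSE, length(idx))
  p <- profile_log_params(profile)
  hmm_engine(idx, p$match_lodds, p$ins_lodds, p$lt, mask, TRUE)
}

#' @rdname hmm_viterbi
#' @export
hmm_forward <- function(profile, seq, mask = NULL) {
  idx <- aa_to_index(check_protein(seq))
  idx[is.na(idx)] <- 0L
  mask <- mask %||% rep(FALSE, length(idx))
  p <- profile_log_params(profile)
  hmm_engine(idx, p$match_lodds, p$ins_lodds, p$lt, mask, FALSE)$bits
}

#' Calibrate a profile's E-values against a null score distribution
#'
#' Samples `n_samples` background sequences whose lengths are resampled from
#' `null_lengths` (typically the lengths of the database to be scanned),
#' scores them with the forward algorithm, and fits a Gumbel distribution by
#' maximum likelihood. E-values are then
#' `database_size * P(S >= s | Gumbel)`.
#'
#' @param profile a `profile_hmm`.
#' @param null_lengths integer vector of lengths to resample.
#' @param n_samples number of null sequences (>= 100; default 1000).
#' @param seed RNG seed (calibration is deterministic given the seed).
#' @param null_freqs residue composition of the null sequences. The default
#'   (uniform) matches an uninformative null; pass the scanned database's
#'   composition when it is strongly biased, since E-values are only honest
#'   when the null matches what is scanned.
#' @return the profile with its `calibration` field set.
#' @export
calibrate_profile <- function(profile, null_lengths, n_samples = 1000,
                              seed = 1, null_freqs = rep(1 / 20, 20)) {
  if (n_samples < 100) stop("n_samples too small for a stable Gumbel fit")
  null_lengths <- null_lengths[null_lengths >= 5]
  if (length(null_lengths) == 0) stop("no usable null lengths")
  scores <- with_seed(seed, {
    lens <- sample(null_lengths, n_samples, replace = TRUE)
    vapply(lens, function(l) {
      hmm_forward(profile, random_protein(l, freqs = null_freqs))
    }, 0)
  })
  fit <- fit_gumbel(scores)
  profile$calibration <- list(mu = fit$mu, beta = fit$beta,
                              n_samples = n_samples, seed = seed)
  profile
}

#' E-value of a bit score under a calibrated profile
#'
#' @param profile calibrated `profile_hmm`.
#' @param bits forward bit score(s).
#' @param database_size number of sequences in the scanned database.
#' @return E-value(s), monotone decreasing in `bits`.
#' @export
profile_evalue <- function(profile, bits, database_size) {
  cal <- profile$calibration
  if (is.null(cal)) stop("profile is not calibrated; run calibrate_profile()")
  z <- (bits - cal$mu) / cal$beta
  database_size * -expm1(-exp(-z))
}

#' Scan a proteome for domain hits
#'
#' Every sequence is scored with the forward algorithm; sequences whose
#' E-value passes `e_cutoff` contribute a hit with the Viterbi envelope.
#' The envelope is then masked and the sequence re-scanned, so several
#' non-overlapping envelopes per sequence can be reported (up to
#' `max_hits_per_seq`). A hit is flagged `partial` when its span of match
#' columns covers less than `partial_fraction` of the profile length.
#'
#' @param profile calibrated `profile_hmm`.
#' @param seqs a [tps_seqs] proteome (or named character vector).
#' @param e_cutoff per-sequence E-value threshold (1.0 for the standard
#'   search, 0.01 for the homology supplement, 100 for the relaxed PPD
#'   discovery mode).
#' @param max_hits_per_seq cap on envelopes per sequence.
#' @param partial_fraction match-column span fraction below which a hit is
#'   flagged partial (default 0.6).
#' @return data.frame with columns `seq_id`, `domain`, `env_start`,
#'   `env_end`, `bit_score`, `evalue`, `partial`, `first_col`, `last_col`.
#' @export
scan_proteome <- function(profile, seqs, e_cutoff = 1.0,
                          max_hits_per_seq = 4, partial_fraction = 0.6) {
  if (is.null(profile$calibration)) {
    stop("profile is not calibrated; run calibrate_profile()")
  }
  db_size <- length(seqs)
  hits <- vector("list", db_size)
  for (s in seq_along(seqs)) {
    seq <- as.character(seqs[[s]])
    id <- names(seqs)[s]
    mask <- rep(FALSE, nchar(seq))
    found <- list()
    for (h in seq_len(max_hits_per_seq)) {
      bits <- hmm_forward(profile, seq, mask)
      ev <- profile_evalue(profile, bits, db_size)
      if (ev > e_cutoff) break
      vit <- hmm_viterbi(profile, seq, mask)
      if (is.na(vit$env_start)) break
      span <- vit$last_col - vit$first_col + 1
      found[[h]] <- data.frame(
        seq_id = id, domain = profile$label,
        env_start = vit$env_start, env_end = vit$env_end,
        bit_score = bits, evalue = ev,
        partial = span < partial_fraction * profile$L,
        first_col = vit$first_col, last_col = vit$last_col,
        stringsAsFactors = FALSE)
      mask[vit$env_start:vit$env_end] <- TRUE
    }
    if (length(found)) hits[[s]] <- do.call(rbind, found)
  }
  out <- do.call(rbind, hits[!vapply(hits, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), domain = character(),
                      env_start = integer(), env_end = integer(),
                      bit_score = numeric(), evalue = numeric(),
                      partial = logical(), first_col = integer(),
                      last_col = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Plain-text profile serialization
# ---------------------------------------------------------------------------

#' Write / read a profile HMM as plain text
#'
#' Format: a header (`tpsurvey-profile 1`), `label`, `L`, the background
#' vector, then the match-emission, insert-emission and transition tables
#' one row per line, and the calibration (or `calibration none`).
#'
#' @param profile a `profile_hmm`.
#' @param path output file.
#' @return `write_profile`: `path` invisibly; `read_profile`: the profile.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(sprintf("%.10g", x), collapse = " ")
  writeLines(c("tpsurvey-profile 1",
               paste("label", profile$label),
               paste("L", profile$L),
               paste("background", num(profile$background))), con)
  writeLines("match_emissions", con)
  writeLines(apply(profile$match_emissions, 1, num), con)
  writeLines("insert_emissions", con)
  writeLines(apply(profile$insert_emissions, 1, num), con)
  writeLines("transitions", con)
  writeLines(apply(profile$transitions, 1, num), con)
  cal <- profile$calibration
  if (is.null(cal)) {
    writeLines("calibration none", con)
  } else {
    writeLines(paste("calibration", num(c(cal$mu, cal$beta, cal$n_samples,
                                          cal$seed))), con)
  }
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "tpsurvey-profile 1") stop("not a tpsurvey profile file")
  label <- sub("^label ", "", lines[2])
  L <- as.integer(sub("^L ", "", lines[3]))
  nums <- function(s) as.numeric(strsplit(s, " +")[[1]])
  background <- nums(sub("^background ", "", lines[4]))
  names(background) <- AA_ALPHABET20
  stopifnot(lines[5] == "match_emissions")
  me <- do.call(rbind, lapply(lines[5 + seq_len(L)], nums))
  o <- 5 + L
  stopifnot(lines[o + 1] == "insert_emissions")
  ie <- do.call(rbind, lapply(lines[o + 1 + seq_len(L + 1)], nums))
  o <- o + 2 + L
  stopifnot(lines[o + 1] == "transitions")
  tr <- do.call(rbind, lapply(lines[o + 1 + seq_len(L + 1)], nums))
  o <- o + 2 + L
  colnames(me) <- colnames(ie) <- AA_ALPHABET20
  colnames(tr) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  cal_line <- lines[o + 1]
  calibration <- if (identical(cal_line, "calibration none")) NULL else {
    v <- nums(sub("^calibration ", "", cal_line))
    list(mu = v[1], beta = v[2], n_samples = v[3], seed = v[4])
  }
  consensus <- paste(AA_ALPHABET20[apply(me, 1, which.max)], collapse = "")
  structure(list(label = label, L = L, match_emissions = me,
                 insert_emissions = ie, transitions = tr,
                 background = background, consensus = consensus,
                 calibration = calibration),
            class = "profile_hmm")
}

#' Write a hit table as TSV
#'
#' @param hits a [scan_proteome()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
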