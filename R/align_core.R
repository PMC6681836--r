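# ---------------------------------------------------------------------------
# Homology engine: pairwise protein alignment with calibrated E-values,
# progressive multiple alignment, and JTT maximum-likelihood distances.
# Pairwise optimal alignment is delegated to Biostrings::pairwiseAlignment;
# identity/coverage semantics, E-value calibration, the progressive MSA and
# the JTT distance estimator are defined here.
# ---------------------------------------------------------------------------

.tps_cache <- new.env(parent = emptyenv())

get_submatrix <- function(name = "BLOSUM62") {
  key <- paste0("submat_", name)
  if (is.null(.tps_cache[[key]])) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    .tps_cache[[key]] <- e[[name]]
  }
  .tps_cache[[key]]
}

check_protein <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  if (!grepl("^[ARNDCQEGHILKMFPSTWYVXBZJUO*]+$", toupper(seq))) {
    stop("sequence contains residues outside the accepted protein alphabet")
  }
  toupper(seq)
}

#' Optimal pairwise protein alignment
#'
#' Affine-gap Smith-Waterman (`local_align`) or Needleman-Wunsch
#' (`global_align`) via [Biostrings::pairwiseAlignment()], with BLASTP-style
#' reporting: identity is the fraction of alignment columns (gap-gap columns
#' cannot occur pairwise) whose residues are identical; coverage is the
#' fraction of *query* residues inside the aligned region; the E-value uses
#' Karlin-Altschul statistics with parameters fitted once per scoring scheme
#' by a Gumbel fit to null alignment scores (see [alignment_calibration()]).
#'
#' @param query,subject protein sequences (plain strings).
#' @param query_id,subject_id ids carried into the result.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend affine gap penalties (BLASTP defaults 11/1; a
#'   gap of length k costs `gap_open + k * gap_extend`).
#' @param search_space optional `m * n` product for the E-value; defaults to
#'   `nchar(query) * nchar(subject)`.
#' @param calibration optional calibration from [alignment_calibration()];
#'   when `NULL` the E-value is computed lazily from a cached calibration.
#' @return a `pairwise_alignment`: list with `query_id`, `subject_id`,
#'   `aligned_query`, `aligned_subject`, `score`, `identity`,
#'   `query_coverage`, `evalue` and `n_columns`. A local alignment with
#'   score <= 0 is reported as a no-hit (`identity = coverage = 0`,
#'   `evalue = Inf`).
#' @export
local_align <- function(query, subject, query_id = "query", subject_id = "subject",
                        matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                        search_space = NULL, calibration = NULL) {
  pairwise_align_impl(query, subject, query_id, subject_id, "local",
                      matrix, gap_open, gap_extend, search_space, calibration)
}

#' @rdname local_align
#' @export
global_align <- function(query, subject, query_id = "query", subject_id = "subject",
                         matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  pairwise_align_impl(query, subject, query_id, subject_id, "global",
                      matrix, gap_open, gap_extend, NULL, NA)
}

pairwise_align_impl <- function(query, subject, query_id, subject_id, type,
                                matrix, gap_open, gap_extend, search_space,
                                calibration) {
  query <- check_protein(query)
  subject <- check_protein(subject)
  submat <- get_submatrix(matrix)
  al <- Biostrings::pairwiseAlignment(
    pattern = query, subject = subject, type = type,
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  score <- Biostrings::score(al)
  aq <- as.character(Biostrings::alignedPattern(al))
  as_ <- as.character(Biostrings::alignedSubject(al))
  ncol_al <- nchar(aq)
  if (type == "local" && score <= 0) {
    return(structure(list(query_id = query_id, subject_id = subject_id,
                          aligned_query = "", aligned_subject = "",
                          score = 0, identity = 0, query_coverage = 0,
                          evalue = Inf, n_columns = 0L),
                     class = "pairwise_alignment"))
  }
  qa <- strsplit(aq, "")[[1]]
  sa <- strsplit(as_, "")[[1]]
  both <- qa != "-" & sa != "-"
  identity <- sum(qa == sa & both) / ncol_al
  q_res_aligned <- sum(qa != "-")
  coverage <- if (type == "global") 1 else q_res_aligned / nchar(query)
  evalue <- NA_real_
  if (type == "local") {
    if (is.null(calibration)) {
      calibration <- alignment_calibration(matrix, gap_open, gap_extend)
    }
    if (!identical(calibration, NA)) {
      mn <- search_space %||% (nchar(query) * nchar(subject))
      evalue <- karlin_altschul_evalue(score, mn, calibration)
    }
  }
  structure(list(query_id = query_id, subject_id = subject_id,
                 aligned_query = aq, aligned_subject = as_,
                 score = score, identity = identity,
                 query_coverage = coverage, evalue = evalue,
                 n_columns = ncol_al),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment %s vs %s: score %.1f, identity %.3f, coverage %.3f, E %.3g\n",
              x$query_id, x$subject_id, x$score, x$identity,
              x$query_coverage, x$evalue))
  invisible(x)
}

#' Karlin-Altschul calibration for local alignment E-values
#'
#' Fits the null distribution of optimal local alignment scores for one
#' scoring scheme. Random background sequences of length `len` are aligned
#' pairwise; the scores are fitted with a Gumbel distribution by maximum
#' likelihood, giving `lambda = 1/beta` and `K = exp(lambda * mu) / (len^2)`,
#' so that `E = K * m * n * exp(-lambda * S)`. Results are cached per scheme
#' for the session.
#'
#' @param matrix substitution matrix name.
#' @param gap_open,gap_extend gap penalties.
#' @param n_pairs number of null pairs (default 10000).
#' @param len null sequence length.
#' @param seed RNG seed for the null sample (fixed so calibration is
#'   deterministic).
#' @return list with `K`, `lambda`, `mu`, `beta`, `len`.
#' @export
alignment_calibration <- function(matrix = "BLOSUM62", gap_open = 11,
                                  gap_extend = 1, n_pairs = 10000, len = 120,
                                  seed = 20160613) {
  key <- paste("ka", matrix, gap_open, gap_extend, n_pairs, len, seed, sep = "_")
  if (!is.null(.tps_cache[[key]])) return(.tps_cache[[key]])
  submat <- get_submatrix(matrix)
  scores <- with_seed(seed, {
    n_batches <- 20
    per_batch <- ceiling(n_pairs / n_batches)
    unlist(lapply(seq_len(n_batches), function(b) {
      subject <- random_protein(len)
      patterns <- Biostrings::AAStringSet(
        vapply(seq_len(per_batch), function(i) random_protein(len), ""))
      Biostrings::pairwiseAlignment(
        pattern = patterns, subject = subject, type = "local",
        substitutionMatrix = submat, gapOpening = gap_open,
        gapExtension = gap_extend, scoreOnly = TRUE)
    }))
  })
  fit <- fit_gumbel(scores)
  cal <- list(K = exp(fit$mu / fit$beta) / (len * len),
              lambda = 1 / fit$beta, mu = fit$mu, beta = fit$beta, len = len)
  .tps_cache[[key]] <- cal
  cal
}

karlin_altschul_evalue <- function(score, search_space, calibration) {
  calibration$K * search_space * exp(-calibration$lambda * score)
}

#' Maximum-likelihood Gumbel fit
#'
#' @param x numeric sample.
#' @return list with location `mu` and scale `beta`.
#' @export
fit_gumbel <- function(x) {
  if (sd(x) < 1e-9) stop("degenerate sample: zero variance")
  # moment start values, then ML via closed-form profile for mu given beta
  beta0 <- sd(x) * sqrt(6) / pi
  nll <- function(beta) {
    if (beta <= 0) return(Inf)
    z <- exp(-x / beta)
    mu <- -beta * log(mean(z))
    sum((x - mu) / beta + exp(-(x - mu) / beta)) + length(x) * log(beta)
  }
  opt <- optimize(nll, interval = c(beta0 / 10, beta0 * 10))
  beta <- opt$minimum
  mu <- -beta * log(mean(exp(-x / beta)))
  list(mu = mu, beta = beta)
}

random_protein <- function(len, freqs = rep(1 / 20, 20)) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE, prob = freqs),
        collapse = "")
}

# ---------------------------------------------------------------------------
# Progressive multiple alignment
# ---------------------------------------------------------------------------

#' Multiple alignment container
#'
#' @param rows named character vector of equal-length gapped strings.
#' @return a `multiple_alignment`: list with `rows` and `n_columns`.
#' @export
multiple_alignment <- function(rows) {
  if (length(unique(nchar(rows))) != 1) stop("rows must have equal length")
  if (is.null(names(rows)) || anyDuplicated(names(rows))) {
    stop("rows must have unique names")
  }
  structure(list(rows = rows, n_columns = nchar(rows[[1]])),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("multiple_alignment: ", length(x$rows), " rows x ", x$n_columns,
      " columns\n", sep = "")
  invisible(x)
}

#' Read/write aligned FASTA
#' @param path aligned FASTA file.
#' @return a [multiple_alignment].
#' @export
read_alignment <- function(path) {
  seqs <- read_fasta(path, alphabet = "protein")
  multiple_alignment(setNames(as.character(unclass(seqs)), names(seqs)))
}

#' @rdname read_alignment
#' @param msa a [multiple_alignment].
#' @export
write_alignment <- function(msa, path) {
  write_fasta(tps_seqs(msa$rows), path)
}

#' Progressive multiple sequence alignment
#'
#' Classic progressive scheme: all-pairs global alignments give an identity
#' matrix; a UPGMA guide tree on `1 - identity` orders profile-profile
#' merges; profiles are aligned by dynamic programming with sum-of-pairs
#' column scores and a linear gap penalty.
#'
#' @param seqs named character vector (or [tps_seqs]) of >= 2 protein
#'   sequences.
#' @param matrix substitution matrix name.
#' @param gap_cost linear per-symbol gap penalty used in the profile DP.
#' @return a [multiple_alignment].
#' @export
progressive_msa <- function(seqs, matrix = "BLOSUM62", gap_cost = 8) {
  seqs <- setNames(toupper(as.character(seqs)), names(seqs))
  n <- length(seqs)
  if (n < 2) stop("progressive_msa needs at least 2 sequences")
  submat <- get_submatrix(matrix)
  ids <- names(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- global_align(seqs[[i]], seqs[[j]], matrix = matrix)
    d[i, j] <- d[j, i] <- 1 - al$identity
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  # profiles: list of gapped row character matrices (rows = sequences)
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(seqs[[i]], "")[[1]], nrow = 1)
    rownames(m) <- ids[i]
    m
  })
  merged <- vector("list", nrow(hc$merge))
  getp <- function(k) if (k < 0) profiles[[-k]] else merged[[k]]
  for (s in seq_len(nrow(hc$merge))) {
    merged[[s]] <- align_profiles(getp(hc$merge[s, 1]), getp(hc$merge[s, 2]),
                                  submat, gap_cost)
  }
  final <- merged[[nrow(hc$merge)]]
  final <- final[ids, , drop = FALSE]
  multiple_alignment(apply(final, 1, paste, collapse = ""))
}

# Profile-profile DP with sum-of-pairs column scores and linear gaps.
align_profiles <- function(a, b, submat, gap_cost) {
  la <- ncol(a); lb <- ncol(b)
  # per-column residue count matrices over the 20-letter alphabet
  cnt <- function(p) {
    apply(p, 2, function(col) {
      col <- col[col != "-"]
      tabulate(match(col, AA_ALPHABET20), 20)
    })
  }
  ca <- cnt(a); cb <- cnt(b)  # 20 x L matrices
  na <- nrow(a); nb <- nrow(b)
  sm <- submat[AA_ALPHABET20, AA_ALPHABET20]
  # expected substitution score between columns i of a and j of b
  colscore <- t(ca) %*% sm %*% cb / (na * nb)
  gap_a <- gap_cost * colSums(ca) / na  # cost of gapping column of a vs b rows
  gap_b <- gap_cost * colSums(cb) / nb
  S <- matrix(-Inf, la + 1, lb + 1)
  P <- matrix(0L, la + 1, lb + 1)  # 1 diag, 2 up (gap in b), 3 left (gap in a)
  S[1, 1] <- 0
  for (i in seq_len(la)) { S[i + 1, 1] <- S[i, 1] - gap_a[i]; P[i + 1, 1] <- 2L }
  for (j in seq_len(lb)) { S[1, j + 1] <- S[1, j] - gap_b[j]; P[1, j + 1] <- 3L }
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      cand <- c(S[i, j] + colscore[i, j], S[i, j + 1] - gap_a[i],
                S[i + 1, j] - gap_b[j])
      k <- which.max(cand)
      S[i + 1, j + 1] <- cand[k]
      P[i + 1, j + 1] <- k
    }
  }
  # traceback
  i <- la; j <- lb
  cols_a <- integer(0); cols_b <- integer(0)  # 0 = gap column
  while (i > 0 || j > 0) {
    k <- P[i + 1, j + 1]
    if (k == 1L) { cols_a <- c(i, cols_a); cols_b <- c(j, cols_b); i <- i - 1; j <- j - 1 }
    else if (k == 2L) { cols_a <- c(i, cols_a); cols_b <- c(0L, cols_b); i <- i - 1 }
    else { cols_a <- c(0L, cols_a); cols_b <- c(j, cols_b); j <- j - 1 }
  }
  take <- function(p, cols) {
    out <- matrix("-", nrow(p), length(cols))
    nz <- cols != 0
    out[, nz] <- p[, cols[nz], drop = FALSE]
    rownames(out) <- rownames(p)
    out
  }
  rbind(take(a, cols_a), take(b, cols_b))
}

#' Sum-of-pairs score of a multiple alignment
#'
#' Scoring convention of [progressive_msa()]: substitution-matrix score for
#' residue pairs, `-gap_cost` for residue-gap pairs, 0 for gap-gap pairs.
#' Used by tests as the objective for the exhaustive small-case oracle.
#'
#' @param msa a [multiple_alignment].
#' @param matrix substitution matrix name.
#' @param gap_cost linear gap penalty.
#' @return numeric score.
#' @export
sum_of_pairs_score <- function(msa, matrix = "BLOSUM62", gap_cost = 8) {
  submat <- get_submatrix(matrix)
  rows <- do.call(rbind, strsplit(msa$rows, ""))
  total <- 0
  for (i in seq_len(nrow(rows) - 1)) for (j in (i + 1):nrow(rows)) {
    a <- rows[i, ]; b <- rows[j, ]
    both <- a != "-" & b != "-"
    one <- xor(a != "-", b != "-")
    if (any(both)) total <- total + sum(submat[cbind(a[both], b[both])])
    total <- total - gap_cost * sum(one)
  }
  total
}

# ---------------------------------------------------------------------------
# JTT maximum-likelihood distances
# ---------------------------------------------------------------------------

# JTT rate matrix and equilibrium frequencies, taken from the model tables
# packaged with phangorn and normalized to one expected substitution per
# unit time. Cached with its eigendecomposition.
jtt_model <- function() {
  if (!is.null(.tps_cache$jtt)) return(.tps_cache$jtt)
  tmp <- get(".JTT", envir = asNamespace("phangorn"))
  ex <- tmp$Q   # exchangeabilities, lower triangle, length 190
  bf <- tmp$bf  # equilibrium frequencies
  if (is.null(ex) || is.null(bf)) stop("could not load the JTT model tables")
  R <- matrix(0, 20, 20)
  R[lower.tri(R)] <- ex
  R <- R + t(R)
  Q <- R * rep(bf, each = 20)       # Q[a, b] = s_ab * pi_b
  diag(Q) <- -rowSums(Q)
  rate <- -sum(bf * diag(Q))
  Q <- Q / rate                      # 1 expected substitution / unit time
  eig <- eigen(Q)
  model <- list(Q = Q, bf = bf, V = eig$vectors, Vi = solve(eig$vectors),
                lambda = eig$values)
  dimnames(model$Q) <- list(AA_ALPHABET20, AA_ALPHABET20)
  .tps_cache$jtt <- model
  model
}

# P(t) = V exp(lambda t) V^-1 (real part; Q is similar to a symmetric matrix)
jtt_prob <- function(t, model = jtt_model()) {
  P <- Re(model$V %*% (exp(model$lambda * t) * model$Vi))
  P[P < 1e-12] <- 1e-12
  P
}

# 20x20 table of aligned residue pairs over shared non-gap columns
pair_count_table <- function(a_chars, b_chars) {
  keep <- a_chars %in% AA_ALPHABET20 & b_chars %in% AA_ALPHABET20
  if (!any(keep)) stop("no shared non-gap columns")
  ia <- match(a_chars[keep], AA_ALPHABET20)
  ib <- match(b_chars[keep], AA_ALPHABET20)
  tab <- matrix(0, 20, 20)
  for (k in seq_along(ia)) tab[ia[k], ib[k]] <- tab[ia[k], ib[k]] + 1
  tab
}

#' JTT log-likelihood of an aligned pair at divergence time t
#'
#' `sum over shared columns of log(pi_a * P_JTT(a -> b | t))`. Exposed so the
#' estimate of [jtt_distance()] can be checked against a grid search.
#'
#' @param a_aligned,b_aligned equal-length gapped strings.
#' @param t divergence time (expected substitutions per site).
#' @return log-likelihood.
#' @export
jtt_loglik <- function(a_aligned, b_aligned, t) {
  tab <- pair_count_table(strsplit(toupper(a_aligned), "")[[1]],
                          strsplit(toupper(b_aligned), "")[[1]])
  model <- jtt_model()
  P <- jtt_prob(t, model)
  sum(tab * log(model$bf * P))
}

#' Maximum-likelihood JTT distance between two aligned sequences
#'
#' Maximizes the JTT likelihood over shared non-gap columns by bounded
#' scalar optimization. Distances hitting the cap are flagged saturated.
#'
#' @param a_aligned,b_aligned equal-length gapped protein strings with at
#'   least one shared non-gap column.
#' @param max_dist cap on the estimate (substitutions/site).
#' @return numeric distance with attribute `saturated` (logical).
#' @export
jtt_distance <- function(a_aligned, b_aligned, max_dist = 10) {
  if (nchar(a_aligned) != nchar(b_aligned)) stop("aligned rows differ in length")
  tab <- pair_count_table(strsplit(toupper(a_aligned), "")[[1]],
                          strsplit(toupper(b_aligned), "")[[1]])
  model <- jtt_model()
  if (sum(tab) == sum(diag(tab))) {
    return(structure(0, saturated = FALSE))
  }
  nll <- function(t) -sum(tab * log(model$bf * jtt_prob(t, model)))
  opt <- optimize(nll, interval = c(1e-8, max_dist))
  d <- opt$minimum
  saturated <- d > max_dist * 0.99
  structure(if (saturated) max_dist else d, saturated = saturated)
}

#' JTT distance matrix for a multiple alignment
#'
#' @param msa a [multiple_alignment].
#' @param max_dist saturation cap per pair.
#' @return symmetric matrix of substitutions/site with zero diagonal.
#' @export
jtt_distance_matrix <- function(msa, max_dist = 10) {
  ids <- names(msa$rows)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- as.numeric(
      jtt_distance(msa$rows[[i]], msa$rows[[j]], max_dist = max_dist))
  }
  d
}
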