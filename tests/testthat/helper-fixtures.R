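# Shared fixtures, built once per test run and memoized. Everything is
# generated in code under fixed seeds; no data files are read.

.fix <- new.env()

memo <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

# small, quick profiles (toy scale for unit tests)
fix_small_profiles <- function() {
  memo("small_profiles", function() {
    ntd <- build_profile(simulate_seed_msa("NTD", length = 40, n_seqs = 10,
                                           divergence = 0.1, seed = 101),
                         label = "NTD")
    ctd <- build_profile(simulate_seed_msa("CTD", length = 50, n_seqs = 10,
                                           divergence = 0.1, seed = 102),
                         label = "CTD")
    list(ntd = ntd, ctd = ctd)
  })
}

# realistic-length profiles (domain scale, used by recovery tests)
fix_domain_profiles <- function() {
  memo("domain_profiles", function() {
    ntd <- build_profile(simulate_seed_msa("NTD", length = 150, n_seqs = 12,
                                           divergence = 0.15, seed = 201),
                         label = "NTD")
    ctd <- build_profile(simulate_seed_msa("CTD", length = 180, n_seqs = 12,
                                           divergence = 0.15, seed = 202),
                         label = "CTD")
    list(ntd = ntd, ctd = ctd)
  })
}

# a calibrated small NTD profile for threshold tests
fix_calibrated_small <- function() {
  memo("calibrated_small", function() {
    p <- fix_small_profiles()$ntd
    calibrate_profile(p, null_lengths = rep(c(80, 150, 300), 10),
                      n_samples = 600, seed = 7)
  })
}

# random protein helper with a local seed
rand_prot <- function(len, seed) {
  with_seed(seed, tpsurvey:::random_protein(len))
}

# brute-force optimal local alignment score by recursive enumeration
# (affine gaps, gap of length k costs open + k * extend), for tiny inputs
brute_local_score <- function(a, b, submat, open = 11, extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- 0
  # enumerate all substring pairs and all gapped alignments between them
  align_all <- function(sa, sb) {
    # returns best global alignment score of char vectors sa, sb under
    # affine gaps, by exhaustive recursion over edit scripts
    rec <- function(i, j, state) {
      # state: 0 none/last match, 1 in gap-a, 2 in gap-b
      if (i > length(sa) && j > length(sb)) return(0)
      sc <- -Inf
      if (i <= length(sa) && j <= length(sb)) {
        sc <- max(sc, submat[sa[i], sb[j]] + rec(i + 1, j + 1, 0))
      }
      if (j <= length(sb)) {
        pen <- if (state == 1) extend else open + extend
        sc <- max(sc, -pen + rec(i, j + 1, 1))
      }
      if (i <= length(sa)) {
        pen <- if (state == 2) extend else open + extend
        sc <- max(sc, -pen + rec(i + 1, j, 2))
      }
      sc
    }
    rec(1, 1, 0)
  }
  for (i1 in seq_along(a)) for (i2 in i1:length(a)) {
    for (j1 in seq_along(b)) for (j2 in j1:length(b)) {
      best <- max(best, align_all(a[i1:i2], b[j1:j2]))
    }
  }
  best
}

# Independent oracle for the forward score: enumerate every state path of
# the local model and sum the path odds. Model semantics mirrored: N/C
# flanks emit background (odds 1 per residue) with loop probability
# n/(n+2) and leave probability 2/(n+2); entry N->M_k uniform 1/L; exit
# M_k->C uniform 1/L from any match column; core transitions from the
# profile tables (insert states exist after columns 1..L-1); delete states
# emit nothing. Exponential in n and L: use on toy profiles only.
enumerate_forward_bits <- function(profile, seq) {
  idx <- tpsurvey:::aa_to_index(seq)
  n <- length(idx)
  L <- profile$L
  bg <- profile$background
  me <- profile$match_emissions
  ie <- profile$insert_emissions
  tr <- profile$transitions
  eta <- n / (n + 2)
  leave <- 2 / (n + 2)
  total <- 0
  emit_m <- function(k, i) me[k, idx[i]] / bg[idx[i]]
  emit_i <- function(k, i) ie[k + 1, idx[i]] / bg[idx[i]]
  # i = the residue consumed by an emitting state when entered; for D, the
  # next residue still to be consumed
  recurse <- function(state, k, i, prob) {
    if (state == "M") {
      p <- prob * emit_m(k, i)
      # exit to C after this match; C emits residues i+1..n
      total <<- total + p * (1 / L) * eta^(n - i) * leave
      if (i < n && k < L) {
        recurse("M", k + 1, i + 1, p * tr[k + 1, "MM"])
        recurse("I", k, i + 1, p * tr[k + 1, "MI"])
        recurse("D", k + 1, i + 1, p * tr[k + 1, "MD"])
      }
    } else if (state == "I") {
      p <- prob * emit_i(k, i)
      if (i < n && k < L) {
        recurse("M", k + 1, i + 1, p * tr[k + 1, "IM"])
        recurse("I", k, i + 1, p * tr[k + 1, "II"])
      }
    } else {  # D: consumes nothing; transitions exist while k < L
      if (k < L) {
        if (i <= n) recurse("M", k + 1, i, prob * tr[k + 1, "DM"])
        recurse("D", k + 1, i, prob * tr[k + 1, "DD"])
      }
    }
  }
  for (j0 in 0:(n - 1)) {
    p0 <- eta^j0 * leave
    for (k in seq_len(L)) recurse("M", k, j0 + 1, p0 / L)
  }
  as.numeric(log2(total))
}

# exhaustive three-sequence alignment: full 3D dynamic program over all
# 7 gap patterns, maximizing the sum-of-pairs score used by
# sum_of_pairs_score() (substitution matrix + linear gap cost, gap-gap 0)
brute_sp_optimum <- function(seqs, matrix = "BLOSUM62", gap_cost = 8) {
  stopifnot(length(seqs) == 3)
  sm <- tpsurvey:::get_submatrix(matrix)
  s <- lapply(seqs, function(x) strsplit(x, "")[[1]])
  n <- vapply(s, length, 0L)
  pair <- function(x, y) {
    if (is.na(x) && is.na(y)) 0
    else if (is.na(x) || is.na(y)) -gap_cost
    else sm[x, y]
  }
  col_score <- function(a, b, c) pair(a, b) + pair(a, c) + pair(b, c)
  D <- array(-Inf, dim = n + 1)
  D[1, 1, 1] <- 0
  for (i in 0:n[1]) for (j in 0:n[2]) for (k in 0:n[3]) {
    if (i == 0 && j == 0 && k == 0) next
    best <- -Inf
    for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
      if (di + dj + dk == 0) next
      if (i - di < 0 || j - dj < 0 || k - dk < 0) next
      prev <- D[i - di + 1, j - dj + 1, k - dk + 1]
      if (prev == -Inf) next
      a <- if (di) s[[1]][i] else NA
      b <- if (dj) s[[2]][j] else NA
      c <- if (dk) s[[3]][k] else NA
      best <- max(best, prev + col_score(a, b, c))
    }
    D[i + 1, j + 1, k + 1] <- best
  }
  D[n[1] + 1, n[2] + 1, n[3] + 1]
}
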