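#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed survey fractions (for
#' example "89.9%") use conventional half-up rounding, so reporting functions
#' go through this helper instead.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(0.25, 1)  # 0.3, where round(0.25, 1) gives 0.2
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Report a count as a percentage
#'
#' Exact rational arithmetic (`100 * k / n`) followed by half-up rounding to
#' one decimal place, the convention used for every fraction this package
#' prints (e.g. 948/1054 -> 89.9).
#'
#' @param k numerator count.
#' @param n denominator count; must be positive.
#' @param digits decimal places (default 1).
#' @return numeric percentage in `[0, 100]`.
#' @export
percent_of <- function(k, n, digits = 1) {
  stopifnot(n > 0, k >= 0, k <= n)
  round_half_up(100 * k / n, digits)
}

# 20 standard amino acids, fixed order used by all emission tables.
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

# Residues tolerated on input but not modeled: ambiguity/unknown codes are
# remapped to "X" and scored as background.
AA_AMBIGUITY <- c("X", "B", "Z", "J", "U", "O", "*")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Map residue characters to 1..20 indices; ambiguity codes -> NA (scored as
# background by the DP kernels). Errors on characters outside both sets.
aa_to_index <- function(residues) {
  chars <- strsplit(toupper(residues), "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET20)
  bad <- is.na(idx) & !(chars %in% AA_AMBIGUITY)
  if (any(bad)) {
    stop("residue(s) outside the protein alphabet: ",
         paste(unique(chars[bad]), collapse = ", "))
  }
  idx
}

log2_safe <- function(p) ifelse(p > 0, log2(p), -Inf)

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's RNG
#' state afterwards, so every generator in this package is a pure function of
#' `(config, seed)` without side effects on the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
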