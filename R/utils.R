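# Shared constants and small internal helpers.

#' Standard amino-acid alphabet used throughout the package
#'
#' The 20 canonical residues in alphabetical one-letter order. All emission
#' vectors/matrices in [build_hmm()] and friends are indexed in this order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residue -> 1..20 code, anything else (X, *, gaps) -> 0
aa_code <- function(chars) {
  idx <- match(chars, AA_ALPHABET)
  idx[is.na(idx)] <- 0L
  idx
}

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded package internals never perturb user-level
#' random streams.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# deterministic child seeds derived from a master seed (kept < 2^31)
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
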