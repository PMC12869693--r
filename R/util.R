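# Internal helpers shared across modules.

err_format    <- function(msg) stop(errorCondition(msg, class = c("pantag_format_error", "pantag_error")))
err_domain    <- function(msg) stop(errorCondition(msg, class = c("pantag_domain_error", "pantag_error")))
err_conflict  <- function(msg) stop(errorCondition(msg, class = c("pantag_conflict_error", "pantag_error")))
err_integrity <- function(msg) stop(errorCondition(msg, class = c("pantag_integrity_error", "pantag_error")))
err_usage     <- function(msg) stop(errorCondition(msg, class = c("pantag_usage_error", "pantag_error")))

# Alphabet order is fixed: '$' below all bases, then A < C < G < N < T.
DNA_BASES <- c("A", "C", "G", "N", "T")
ALPHABET  <- c("$", DNA_BASES)

# complement by alphabet code (1-based into ALPHABET): $->$, A<->T, C<->G, N->N
COMP_CODE <- c(1L, 6L, 4L, 3L, 5L, 2L)
COMP_CHAR <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

rc_string <- function(s) {
  vapply(s, function(x) {
    if (nchar(x) == 0L) return(x)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

base_codes <- function(s) {
  cc <- match(chars_of(s), ALPHABET)
  if (anyNA(cc)) err_domain(sprintf("non-ACGTN character in '%s'", s))
  cc
}
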