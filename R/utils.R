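DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of character DNA strings
#'
#' Vectorised over `x`; operates on plain character vectors (A/C/G/T only).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp_chr <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' @keywords internal
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

stop2 <- function(...) stop(..., call. = FALSE)

assert_dna <- function(seq, what = "sequence") {
  bad <- regexpr("[^ACGT]", seq)
  if (bad > 0L) {
    stop2(sprintf("%s contains a non-ACGT base ('%s') at position %d",
                  what, substr(seq, bad, bad), bad))
  }
  invisible(TRUE)
}

#' Generate n random fixed-length strings over an alphabet
#'
#' Builds one long string per chunk and slices it, which is far faster than
#' n individual paste() calls for large n.
#' @keywords internal
random_strings <- function(n, len, alphabet = DNA_BASES, prob = NULL,
                           chunk = 2e6L) {
  if (n == 0L) return(character(0))
  out <- character(n)
  done <- 0L
  while (done < n) {
    k <- min(chunk, n - done)
    chars <- sample(alphabet, k * len, replace = TRUE, prob = prob)
    big <- paste(chars, collapse = "")
    starts <- seq.int(1L, by = len, length.out = k)
    out[(done + 1L):(done + k)] <- substring(big, starts, starts + len - 1L)
    done <- done + k
  }
  out
}

# rejection marker: NA flagged with a machine-readable reason
rejection <- function(reason) structure(NA, reason = reason)

#' Is a result a rejection, and why?
#' @param x a result from [merge_pairs()] or [demultiplex_and_trim()].
#' @return `TRUE` if `x` is a rejection; `rejection_reason()` gives its
#'   reason string (or `NA`).
#' @export
is_rejection <- function(x) !is.list(x) && length(x) == 1L && is.na(x) &&
  !is.null(attr(x, "reason"))

#' @rdname is_rejection
#' @export
rejection_reason <- function(x) {
  r <- attr(x, "reason")
  if (is.null(r)) NA_character_ else r
}

#' Standard error of the mean
#' @keywords internal
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1L) return(0)
  stats::sd(x) / sqrt(length(x))
}
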