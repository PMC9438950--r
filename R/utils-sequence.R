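# Low-level nucleotide string helpers shared by the readers, writers and the
# edit operations. All coordinates handled here are 0-based half-open.

IUPAC_CHARS <- "ACGTURYSWKMBDHVN"
COMPLEMENT_FROM <- paste0(IUPAC_CHARS, tolower(IUPAC_CHARS))
COMPLEMENT_TO <- {
  to <- "TGCAAYRSWMKVHDBN"
  paste0(to, tolower(to))
}

#' Reverse-complement nucleotide sequences
#'
#' Complements IUPAC nucleotide codes (case preserved, `N` maps to `N`) and
#' reverses the string. Vectorised over `x`.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of reverse-complemented sequences.
#' @export
#' @examples
#' revcomp("AACG")
revcomp <- function(x) {
  stringi::stri_reverse(chartr(COMPLEMENT_FROM, COMPLEMENT_TO, x))
}

# regex matching any character outside the accepted nucleotide alphabet
invalid_nt_regex <- function() {
  sprintf("[^%s%s]", IUPAC_CHARS, tolower(IUPAC_CHARS))
}

# maximal runs of N/n in a sequence; returns tibble(start, end) 0-based half-open
n_runs <- function(seq) {
  m <- gregexpr("[Nn]+", seq, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  tibble::tibble(start = start, end = start + attr(m, "match.length"))
}

# wrap a single sequence at `width` characters; UNLIMITED (NULL/Inf/0) = one line
wrap_sequence <- function(seq, width = 60L) {
  n <- nchar(seq)
  if (is.null(width) || !is.finite(width) || width <= 0L || n <= width) {
    return(seq)
  }
  starts <- seq.int(1L, n, by = width)
  substring(seq, starts, pmin(starts + width - 1L, n))
}

# natural ("version-style") ordering: numeric substrings compare numerically,
# so chr1 < chr2 < chr10. Returns an ordering permutation; stable.
natural_order <- function(x) {
  pieces <- stringr::str_extract_all(x, "[0-9]+|[^0-9]+")
  max_len <- max(lengths(pieces), 1L)
  keys <- lapply(seq_len(max_len), function(i) {
    piece <- vapply(pieces, function(p) if (i <= length(p)) p[[i]] else "", "")
    num <- suppressWarnings(as.numeric(piece))
    # numeric pieces sort before non-numeric ones of the same rank
    list(is_text = !is.na(piece) & is.na(num) & piece != "",
         num = ifelse(is.na(num), -Inf, num),
         txt = piece)
  })
  args <- unlist(lapply(keys, function(k) list(k$is_text, k$num, k$txt)),
                 recursive = FALSE)
  do.call(order, args)
}

# effective (rendered) gap length: NA distance means unknown -> placeholder Ns
gap_effective_length <- function(distance, unknown_gap_size = 100L) {
  ifelse(is.na(distance), as.integer(unknown_gap_size), as.integer(distance))
}
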