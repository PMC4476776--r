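# String similarity primitives for register linkage.

#' Normalise an identifier for comparison
#'
#' Upper-cases and strips whitespace and punctuation, the usual hygiene
#' before comparing vessel names or callsigns across registries.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_id <- function(x) {
  x <- toupper(as.character(x))
  gsub("[^A-Z0-9]", "", x)
}

#' Normalised Levenshtein similarity
#'
#' `1 - d / max(nchar)`, where `d` is the plain Levenshtein edit distance.
#' Two empty strings have similarity 0 (they carry no evidence).
#'
#' @param a,b character vectors (recycled to common length).
#' @return numeric vector in `[0, 1]`.
#' @export
levenshtein_sim <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- vapply(seq_len(n), function(i) utils::adist(a[i], b[i])[1L, 1L],
              numeric(1))
  m <- pmax(nchar(a), nchar(b))
  out <- ifelse(m == 0, 0, 1 - d / m)
  as.numeric(out)
}

#' Jaro similarity
#'
#' The classical Jaro string similarity: characters match if equal and no
#' further apart than half the longer string (minus one); the score combines
#' the match fractions with the transposition count. Robust to the adjacent
#' swaps typical of hand-keyed identifiers.
#'
#' @param a,b character vectors (recycled to common length).
#' @return numeric vector in `[0, 1]`.
#' @export
jaro_sim <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) .jaro1(a[i], b[i]), numeric(1))
}

.jaro1 <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  l1 <- length(c1); l2 <- length(c2)
  if (l1 == 0L || l2 == 0L) return(0)
  if (s1 == s2) return(1)
  win <- max(0L, floor(max(l1, l2) / 2) - 1L)
  m1 <- logical(l1); m2 <- logical(l2)
  for (i in seq_len(l1)) {
    lo <- max(1L, i - win); hi <- min(l2, i + win)
    if (lo > hi) next
    for (j in lo:hi) {
      if (!m2[j] && c1[i] == c2[j]) {
        m1[i] <- TRUE; m2[j] <- TRUE
        break
      }
    }
  }
  m <- sum(m1)
  if (m == 0L) return(0)
  t <- sum(c1[m1] != c2[m2]) / 2
  (m / l1 + m / l2 + (m - t) / m) / 3
}
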