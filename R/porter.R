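# Classic Porter (1980) suffix-stripping stemmer, implemented directly from
# the algorithm definition (no stemming package exists in the dependency
# stack). Operates on single lowercase ASCII words.

.p_is_cons <- function(w, i) {
  ch <- substr(w, i, i)
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") return(i == 1L || !.p_is_cons(w, i - 1L))
  TRUE
}

# measure m of [C](VC)^m[V]
.p_measure <- function(w) {
  n <- nchar(w)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) .p_is_cons(w, i), logical(1))
  # collapse runs
  runs <- rle(types)$values
  m <- 0L
  i <- 1L
  if (length(runs) > 0L && runs[1L]) i <- 2L   # skip leading consonant run
  while (i + 1L <= length(runs)) {             # V followed by C
    if (!runs[i] && runs[i + 1L]) m <- m + 1L
    i <- i + 1L
  }
  m
}

.p_has_vowel <- function(w) {
  n <- nchar(w)
  n > 0L && any(!vapply(seq_len(n), function(i) .p_is_cons(w, i), logical(1)))
}

.p_double_cons <- function(w) {
  n <- nchar(w)
  n >= 2L && substr(w, n, n) == substr(w, n - 1L, n - 1L) && .p_is_cons(w, n)
}

# *o: stem ends cvc where the final c is not w, x or y
.p_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  if (!.p_is_cons(w, n) || .p_is_cons(w, n - 1L) || !.p_is_cons(w, n - 2L))
    return(FALSE)
  !substr(w, n, n) %in% c("w", "x", "y")
}

.p_ends <- function(w, suf) {
  n <- nchar(w); k <- nchar(suf)
  n > k && substr(w, n - k + 1L, n) == suf
}

.p_chop <- function(w, k) substr(w, 1L, nchar(w) - k)

# apply the first matching rule from a list(suffix = replacement) given a
# measure condition on the stem
.p_rule_set <- function(w, rules, cond) {
  for (suf in names(rules)) {
    if (.p_ends(w, suf)) {
      stem <- .p_chop(w, nchar(suf))
      if (cond(stem)) return(paste0(stem, rules[[suf]]))
      return(w)
    }
  }
  w
}

#' Porter-stem a single word
#'
#' @param word lowercase word.
#' @return the Porter stem (e.g. `"diabetic"` -> `"diabet"`,
#'   `"retinopathy"` -> `"retinopathi"`).
#' @export
porter_stem <- function(word) {
  w <- tolower(word)
  if (nchar(w) <= 2L) return(w)
  # step 1a
  if (.p_ends(w, "sses")) w <- .p_chop(w, 2L)
  else if (.p_ends(w, "ies")) w <- .p_chop(w, 2L)
  else if (!.p_ends(w, "ss") && .p_ends(w, "s")) w <- .p_chop(w, 1L)
  # step 1b
  if (.p_ends(w, "eed")) {
    if (.p_measure(.p_chop(w, 3L)) > 0L) w <- .p_chop(w, 1L)
  } else {
    flag <- FALSE
    if (.p_ends(w, "ed") && .p_has_vowel(.p_chop(w, 2L))) {
      w <- .p_chop(w, 2L); flag <- TRUE
    } else if (.p_ends(w, "ing") && .p_has_vowel(.p_chop(w, 3L))) {
      w <- .p_chop(w, 3L); flag <- TRUE
    }
    if (flag) {
      if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.p_double_cons(w) &&
                 !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
        w <- .p_chop(w, 1L)
      } else if (.p_measure(w) == 1L && .p_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }
  # step 1c
  if (.p_ends(w, "y") && .p_has_vowel(.p_chop(w, 1L)))
    w <- paste0(.p_chop(w, 1L), "i")
  # step 2
  w <- .p_rule_set(w, list(
    ational = "ate", tional = "tion", enci = "ence", anci = "ance",
    izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
    ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
    alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
    aliti = "al", iviti = "ive", biliti = "ble"),
    function(stem) .p_measure(stem) > 0L)
  # step 3
  w <- .p_rule_set(w, list(
    icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
    ful = "", ness = ""),
    function(stem) .p_measure(stem) > 0L)
  # step 4
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  # longest match first
  step4 <- step4[order(-nchar(step4))]
  for (suf in step4) {
    if (.p_ends(w, suf)) {
      stem <- .p_chop(w, nchar(suf))
      ok <- .p_measure(stem) > 1L
      if (suf == "ion")
        ok <- ok && substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t")
      if (ok) w <- stem
      break
    }
  }
  # step 5a
  if (.p_ends(w, "e")) {
    stem <- .p_chop(w, 1L)
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_cvc(stem))) w <- stem
  }
  # step 5b
  if (.p_measure(w) > 1L && .p_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l")
    w <- .p_chop(w, 1L)
  w
}
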