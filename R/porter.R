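# Classic Porter (1980) affix-removal stemmer.
#
# Implemented from the original algorithm definition (steps 1a-5b, the
# measure m, and the *v*, *d, *o conditions), not the later "Porter2"
# revision: no "logi"/"bli" rules, step 2 uses "abli" -> "able".

VOWELS <- c("a", "e", "i", "o", "u")

# consonant/vowel profile of a word; y is a consonant only at position 1 or
# after a vowel ("toy" -> y consonant, "syzygy" -> interior y vowels)
.porter_cons <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% VOWELS) {
      cons[i] <- FALSE
    } else if (ch == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# m of [C](VC)^m[V]: number of vowel-run -> consonant-run transitions
.porter_m <- function(word) {
  if (!nzchar(word)) return(0L)
  cons <- .porter_cons(strsplit(word, "", fixed = TRUE)[[1]])
  runs <- rle(cons)$values
  sum(runs[-1] & !runs[-length(runs)]) + 0L
}

.porter_has_vowel <- function(word) {
  if (!nzchar(word)) return(FALSE)
  any(!.porter_cons(strsplit(word, "", fixed = TRUE)[[1]]))
}

# *d: ends with a double consonant
.porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  if (chars[n] != chars[n - 1L]) return(FALSE)
  .porter_cons(chars)[n]
}

# *o: ends cvc where the final consonant is not w, x or y
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  cons <- .porter_cons(chars)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(chars[n] %in% c("w", "x", "y"))
}

.ends <- function(word, suffix) {
  ns <- nchar(suffix)
  nchar(word) >= ns && substring(word, nchar(word) - ns + 1L) == suffix
}

.chop <- function(word, n) substring(word, 1L, nchar(word) - n)

# longest matching suffix from a named map (names = suffixes); once the
# longest match is found the condition is tested and no shorter suffix is
# tried, per the original longest-match rule
.replace_longest <- function(word, map, min_m) {
  sufs <- names(map)[order(-nchar(names(map)))]
  for (s in sufs) {
    if (.ends(word, s)) {
      stem <- .chop(word, nchar(s))
      if (.porter_m(stem) > min_m) {
        return(paste0(stem, map[[s]]))
      }
      return(word)
    }
  }
  word
}

.STEP2 <- c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble"
)

.STEP3 <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
  ful = "", ness = ""
)

.STEP4 <- c(
  "al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
  "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize"
)

.porter_one <- function(word) {
  if (nchar(word) <= 2L) return(word)

  # step 1a: plurals
  if (.ends(word, "sses")) {
    word <- .chop(word, 2L)
  } else if (.ends(word, "ies")) {
    word <- .chop(word, 2L)
  } else if (!.ends(word, "ss") && .ends(word, "s")) {
    word <- .chop(word, 1L)
  }

  # step 1b: -eed / -ed / -ing
  stripped <- FALSE
  if (.ends(word, "eed")) {
    if (.porter_m(.chop(word, 3L)) > 0L) word <- .chop(word, 1L)
  } else if (.ends(word, "ed") && .porter_has_vowel(.chop(word, 2L))) {
    word <- .chop(word, 2L)
    stripped <- TRUE
  } else if (.ends(word, "ing") && .porter_has_vowel(.chop(word, 3L))) {
    word <- .chop(word, 3L)
    stripped <- TRUE
  }
  if (stripped) {
    if (.ends(word, "at") || .ends(word, "bl") || .ends(word, "iz")) {
      word <- paste0(word, "e")
    } else if (.porter_double_cons(word) &&
               !(.ends(word, "l") || .ends(word, "s") || .ends(word, "z"))) {
      word <- .chop(word, 1L)
    } else if (.porter_m(word) == 1L && .porter_cvc(word)) {
      word <- paste0(word, "e")
    }
  }

  # step 1c: y -> i when the stem has a vowel
  if (.ends(word, "y") && .porter_has_vowel(.chop(word, 1L))) {
    word <- paste0(.chop(word, 1L), "i")
  }

  word <- .replace_longest(word, .STEP2, min_m = 0L)
  word <- .replace_longest(word, .STEP3, min_m = 0L)

  # step 4: strip residual suffixes when m > 1; -ion needs stem ending s/t
  sufs4 <- .STEP4[order(-nchar(.STEP4))]
  for (s in sufs4) {
    if (.ends(word, s)) {
      stem <- .chop(word, nchar(s))
      ok <- .porter_m(stem) > 1L
      if (ok && s == "ion") ok <- .ends(stem, "s") || .ends(stem, "t")
      if (ok) word <- stem
      break
    }
  }

  # step 5a: drop a final e
  if (.ends(word, "e")) {
    stem <- .chop(word, 1L)
    m <- .porter_m(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) word <- stem
  }

  # step 5b: -ll -> -l when m > 1
  if (.porter_m(word) > 1L && .porter_double_cons(word) && .ends(word, "l")) {
    word <- .chop(word, 1L)
  }

  word
}

#' Porter stem of a word
#'
#' Applies the classic Porter (1980) suffix-stripping algorithm. The input is
#' expected to be a lowercase word token; words of one or two characters are
#' returned unchanged, as in the reference algorithm.
#'
#' @param token character vector of lowercase word tokens.
#' @return character vector of stems, same length as `token`.
#' @examples
#' porter_stem(c("caresses", "relational", "sky"))
#' @export
porter_stem <- function(token) {
  stopifnot(is.character(token))
  vapply(token, .porter_one, character(1), USE.NAMES = FALSE)
}
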