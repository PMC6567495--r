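#' Porter stemming
#'
#' The original Porter (1980) suffix-stripping algorithm, steps 1a
#' through 5b, for lowercase alphabetic tokens. Reduces inflected
#' forms to a common stem (talks, talking, talked all become "talk") to
#' shrink the vocabulary before topic modelling. Words of one or two
#' letters are returned unchanged.
#'
#' @param words Character vector of tokens.
#' @return Character vector of stems, same length.
#' @export
#' @examples
#' porter_stem(c("talks", "talking", "talked"))   # all "talk"
#' porter_stem(c("implementation", "priorities")) # "implement" "prioriti"
porter_stem <- function(words) {
  vapply(tolower(as.character(words)), porter_stem_word, "",
         USE.NAMES = FALSE)
}

# consonant mask: a letter is a consonant unless it is a,e,i,o,u or a
# "y" preceded by a consonant
porter_cons_mask <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    cons[i] <- if (chars[i] %in% c("a", "e", "i", "o", "u")) {
      FALSE
    } else if (chars[i] == "y") {
      if (i == 1L) TRUE else !cons[i - 1L]
    } else TRUE
  }
  cons
}

# measure m: number of vowel-to-consonant transitions in [C](VC)^m[V]
porter_m <- function(stem) {
  if (!nzchar(stem)) return(0L)
  r <- rle(porter_cons_mask(strsplit(stem, "")[[1L]]))
  sum(!r$values[-length(r$values)] & r$values[-1L])
}

porter_has_vowel <- function(stem) {
  nzchar(stem) && any(!porter_cons_mask(strsplit(stem, "")[[1L]]))
}

porter_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  ch <- strsplit(w, "")[[1L]]
  ch[n] == ch[n - 1L] && porter_cons_mask(ch)[n]
}

# *o: stem ends consonant-vowel-consonant and the final consonant is
# not w, x or y
porter_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  ch <- strsplit(w, "")[[1L]]
  cons <- porter_cons_mask(ch)
  cons[n] && !cons[n - 1L] && cons[n - 2L] && !(ch[n] %in% c("w", "x", "y"))
}

porter_ends <- function(w, s) {
  nchar(w) > nchar(s) &&
    substring(w, nchar(w) - nchar(s) + 1L) == s
}

porter_chop <- function(w, s) substring(w, 1L, nchar(w) - nchar(s))

# apply the longest matching rule of a step-2/3/4 table; once a suffix
# matches, the step ends whether or not the m-condition lets it fire
porter_rule_step <- function(w, rules, cond) {
  ord <- order(-nchar(names(rules)))
  for (s in names(rules)[ord]) {
    if (porter_ends(w, s)) {
      stem <- porter_chop(w, s)
      if (cond(stem, s)) w <- paste0(stem, rules[[s]])
      return(w)
    }
  }
  w
}

porter_step2_rules <- c(
  ational = "ate", tional = "tion", enci = "ence", anci = "ance",
  izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
  ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
  alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
  aliti = "al", iviti = "ive", biliti = "ble")

porter_step3_rules <- c(
  icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
  ful = "", ness = "")

porter_step4_rules <- c(
  ement = "", ance = "", ence = "", able = "", ible = "", ment = "",
  ant = "", ent = "", ion = "", ism = "", ate = "", iti = "", ous = "",
  ive = "", ize = "", al = "", er = "", ic = "", ou = "")

porter_stem_word <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # step 1a: plurals
  if (porter_ends(w, "sses")) {
    w <- paste0(porter_chop(w, "sses"), "ss")
  } else if (porter_ends(w, "ies")) {
    w <- paste0(porter_chop(w, "ies"), "i")
  } else if (!porter_ends(w, "ss") && porter_ends(w, "s")) {
    w <- porter_chop(w, "s")
  }

  # step 1b: -eed, -ed, -ing
  if (porter_ends(w, "eed")) {
    if (porter_m(porter_chop(w, "eed")) > 0L) w <- porter_chop(w, "d")
  } else {
    stripped <- FALSE
    if (porter_ends(w, "ed") && porter_has_vowel(porter_chop(w, "ed"))) {
      w <- porter_chop(w, "ed"); stripped <- TRUE
    } else if (porter_ends(w, "ing") &&
               porter_has_vowel(porter_chop(w, "ing"))) {
      w <- porter_chop(w, "ing"); stripped <- TRUE
    }
    if (stripped) {
      if (porter_ends(w, "at") || porter_ends(w, "bl") ||
          porter_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (porter_double_cons(w) &&
                 !substring(w, nchar(w)) %in% c("l", "s", "z")) {
        w <- substring(w, 1L, nchar(w) - 1L)
      } else if (porter_m(w) == 1L && porter_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c: terminal y -> i when the stem holds a vowel
  if (porter_ends(w, "y") && porter_has_vowel(porter_chop(w, "y"))) {
    w <- paste0(porter_chop(w, "y"), "i")
  }

  # steps 2 and 3: double suffixes, m(stem) > 0
  w <- porter_rule_step(w, porter_step2_rules,
                        function(stem, s) porter_m(stem) > 0L)
  w <- porter_rule_step(w, porter_step3_rules,
                        function(stem, s) porter_m(stem) > 0L)

  # step 4: residual suffixes, m(stem) > 1; -ion needs stem ending s/t
  w <- porter_rule_step(w, porter_step4_rules, function(stem, s) {
    ok <- porter_m(stem) > 1L
    if (s == "ion") {
      ok <- ok && nzchar(stem) &&
        substring(stem, nchar(stem)) %in% c("s", "t")
    }
    ok
  })

  # step 5a: terminal e
  if (porter_ends(w, "e")) {
    stem <- porter_chop(w, "e")
    m <- porter_m(stem)
    if (m > 1L || (m == 1L && !porter_cvc(stem))) w <- stem
  }
  # step 5b: -ll -> -l when m > 1
  if (porter_m(w) > 1L && porter_double_cons(w) &&
      substring(w, nchar(w)) == "l") {
    w <- substring(w, 1L, nchar(w) - 1L)
  }
  w
}
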