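#' Similarity configuration
#'
#' Thresholds and Winkler parameters used throughout duplicate detection and
#' bibliographic-index matching.
#'
#' @param title_match_threshold Minimum Jaro-Winkler similarity between
#'   normalized titles for two records to be considered the same publication
#'   during deduplication. Default 0.85, chosen to tolerate the title
#'   perturbations portals introduce (special-character variants, trailing
#'   truncation) while keeping distinct articles apart.
#' @param pubmed_best_match_threshold Hard minimum similarity for accepting the
#'   best candidate returned by a bibliographic index when looking a record up
#'   by title. Default 0.9: index lookups fan out over synonym-expanded terms
#'   and return many near-miss candidates, so the bar is stricter than for
#'   within-store dedup.
#' @param winkler_prefix_scale Winkler prefix bonus scale `p` in `[0, 0.25]`;
#'   default 0.1.
#' @param max_prefix_length Cap `l_max` on the common-prefix length used by the
#'   Winkler bonus; default 4.
#' @return A `similarity_config` list.
#' @export
similarity_config <- function(title_match_threshold = 0.85,
                              pubmed_best_match_threshold = 0.9,
                              winkler_prefix_scale = 0.1,
                              max_prefix_length = 4L) {
  stopifnot(title_match_threshold >= 0, title_match_threshold <= 1,
            pubmed_best_match_threshold >= 0, pubmed_best_match_threshold <= 1,
            winkler_prefix_scale >= 0, winkler_prefix_scale <= 0.25,
            max_prefix_length >= 0)
  structure(list(title_match_threshold = title_match_threshold,
                 pubmed_best_match_threshold = pubmed_best_match_threshold,
                 winkler_prefix_scale = winkler_prefix_scale,
                 max_prefix_length = as.integer(max_prefix_length)),
            class = "similarity_config")
}

#' Normalize an article title for comparison
#'
#' Portals deliver the same title with different casing, accented versus plain
#' characters, and irregular whitespace. Normalization case-folds, applies
#' Unicode compatibility decomposition and strips combining marks (so
#' `"café"` and `"cafe"` coincide), collapses whitespace runs to single spaces
#' and trims the ends. Idempotent.
#'
#' @param title Character scalar (or vector; applied elementwise).
#' @return Normalized character of the same length.
#' @examples
#' normalize_title("Dendritic  Café")  # "dendritic cafe"
#' @export
normalize_title <- function(title) {
  if (length(title) == 0L) return(character())
  x <- enc2utf8(as.character(title))
  x[is.na(x)] <- ""
  y <- fold_diacritics(x)
  # combining marks already present in decomposed input
  y <- gsub("\\p{M}", "", y, perl = TRUE)
  y <- tolower(y)
  y <- gsub("[[:space:]]+", " ", y)
  trimws(y)
}

# Folds precomposed accented Latin letters to their base letter: equivalent to
# compatibility decomposition followed by removal of combining marks, for the
# Latin-1 supplement plus the Latin Extended-A letters common in titles and
# author names. R core exposes no Unicode normalization primitive, hence the
# explicit table.
fold_diacritics <- function(x) {
  from <- c("\u00e0","\u00e1","\u00e2","\u00e3","\u00e4","\u00e5","\u00e7",
            "\u00e8","\u00e9","\u00ea","\u00eb","\u00ec","\u00ed","\u00ee",
            "\u00ef","\u00f1","\u00f2","\u00f3","\u00f4","\u00f5","\u00f6",
            "\u00f9","\u00fa","\u00fb","\u00fc","\u00fd","\u00ff",
            "\u00c0","\u00c1","\u00c2","\u00c3","\u00c4","\u00c5","\u00c7",
            "\u00c8","\u00c9","\u00ca","\u00cb","\u00cc","\u00cd","\u00ce",
            "\u00cf","\u00d1","\u00d2","\u00d3","\u00d4","\u00d5","\u00d6",
            "\u00d9","\u00da","\u00db","\u00dc","\u00dd",
            "\u0101","\u0113","\u012b","\u014d","\u016b","\u0107","\u010d",
            "\u0161","\u017e","\u0142","\u0153","\u00e6")
  to   <- c("a","a","a","a","a","a","c",
            "e","e","e","e","i","i","i",
            "i","n","o","o","o","o","o",
            "u","u","u","u","y","y",
            "A","A","A","A","A","A","C",
            "E","E","E","E","I","I","I",
            "I","N","O","O","O","O","O",
            "U","U","U","U","Y",
            "a","e","i","o","u","c","c",
            "s","z","l","oe","ae")
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    idx <- match(ch, from)
    hit <- !is.na(idx)
    if (any(hit)) ch[hit] <- to[idx[hit]]
    paste0(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Jaro similarity between two strings
#'
#' Characters of `s1` and `s2` match when equal and within a sliding window of
#' `floor(max(|s1|, |s2|) / 2) - 1` positions. With `m` matches and `t`
#' transpositions (half the number of matched characters appearing out of
#' order), the similarity is `0` if `m = 0` and otherwise
#' `(m/|s1| + m/|s2| + (m - t)/m) / 3`.
#'
#' Symmetric; equals 1 exactly for equal strings; 0 when one string is empty
#' and the other is not.
#'
#' @param s1,s2 Character scalars (compared codepoint-wise, case-sensitively;
#'   normalize first if case must not matter).
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaro("MARTHA", "MARHTA")   # 0.9444...
#' jaro("DIXON", "DICKSONX")  # 0.7666...
#' @export
jaro <- function(s1, s2) {
  if (identical(s1, s2)) return(if (is.na(s1)) NA_real_ else 1)
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  la <- length(a); lb <- length(b)
  if (la == 0L || lb == 0L) return(0)
  window <- max(la, lb) %/% 2L - 1L
  if (window < 0L) window <- 0L
  b_taken <- logical(lb)
  a_to_b <- integer(la)  # 0 = unmatched; else index into b
  for (i in seq_len(la)) {
    lo <- max(1L, i - window); hi <- min(lb, i + window)
    if (lo > hi) next
    cand <- which(!b_taken[lo:hi] & b[lo:hi] == a[i])
    if (length(cand)) {
      j <- lo + cand[1L] - 1L
      b_taken[j] <- TRUE
      a_to_b[i] <- j
    }
  }
  matched <- a_to_b[a_to_b > 0L]
  m <- length(matched)
  if (m == 0L) return(0)
  # matched characters of s1 in s1-order vs matched characters of s2 in s2-order
  t <- sum(b[matched] != b[sort(matched)]) / 2
  (m / la + m / lb + (m - t) / m) / 3
}

#' Jaro-Winkler similarity
#'
#' Boosts the [jaro()] similarity in proportion to the length `l` of the common
#' prefix (capped at `max_prefix_length`):
#' `sim = jaro + l * p * (1 - jaro)` with prefix scale `p`. Never below the
#' plain Jaro value, and equal to it when the strings share no prefix.
#'
#' @inheritParams jaro
#' @param cfg A [similarity_config()]; supplies `p` and the prefix cap.
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaro_winkler("MARTHA", "MARHTA")  # 0.9611...
#' @export
jaro_winkler <- function(s1, s2, cfg = similarity_config()) {
  j <- jaro(s1, s2)
  if (is.na(j)) return(NA_real_)
  l <- common_prefix_length(s1, s2, cfg$max_prefix_length)
  j + l * cfg$winkler_prefix_scale * (1 - j)
}

common_prefix_length <- function(s1, s2, cap) {
  a <- strsplit(s1, "", fixed = TRUE)[[1]]
  b <- strsplit(s2, "", fixed = TRUE)[[1]]
  n <- min(length(a), length(b), cap)
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq)) neq[1L] - 1L else n
}

#' Jaro-Winkler similarity of two titles after normalization
#'
#' Convenience composition of [normalize_title()] and [jaro_winkler()]; this is
#' the quantity thresholded during deduplication.
#'
#' @inheritParams jaro_winkler
#' @export
title_similarity <- function(s1, s2, cfg = similarity_config()) {
  jaro_winkler(normalize_title(s1), normalize_title(s2), cfg)
}
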