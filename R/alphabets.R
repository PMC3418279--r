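#' Degenerate motif alphabets
#'
#' Two fixed alphabets are used throughout. The 11-letter alphabet covers
#' 8-mer motifs with full two-fold degeneracy: the concrete bases A, C, G, T
#' plus the wobbles r = A|G, y = C|T, s = C|G, w = A|T, m = A|C, k = G|T and
#' the four-fold wildcard n = A|C|G|T. The 5-letter alphabet (A, C, G, T, n)
#' covers 12-mer motifs with wildcard-only degeneracy. Letters are assigned
#' the digits 0, 1, 2, ... in the order given above, which defines the
#' positional-notation integer code of a word (base 11 for 8-mers, base 5 for
#' 12-mers). Three-fold wobbles (b, d, h, v) are deliberately not
#' representable.
#'
#' Motif strings are written with uppercase concrete bases and lowercase
#' wobbles (e.g. `"rGTCAAmn"`); parsers accept either case and canonicalize.
#'
#' @return A `motif_alphabet` object: a list with `name`, `letters` (in digit
#'   order), `match` (named list, letter to concrete bases), and `comp`
#'   (named character vector, letter-wise complement).
#' @examples
#' a <- alphabet11()
#' a$letters
#' a$match[["r"]]
#' @export
alphabet11 <- function() .alpha11

#' @rdname alphabet11
#' @export
alphabet5 <- function() .alpha5

.make_alphabet <- function(name, letters, match, comp) {
    stopifnot(identical(names(match), letters), identical(names(comp), letters))
    structure(list(name = name, letters = letters, match = match, comp = comp),
              class = "motif_alphabet")
}

.alpha11 <- .make_alphabet(
    "alpha11",
    c("A", "C", "G", "T", "r", "y", "s", "w", "m", "k", "n"),
    list(A = "A", C = "C", G = "G", T = "T",
         r = c("A", "G"), y = c("C", "T"), s = c("C", "G"), w = c("A", "T"),
         m = c("A", "C"), k = c("G", "T"),
         n = c("A", "C", "G", "T")),
    c(A = "T", C = "G", G = "C", T = "A",
      r = "y", y = "r", s = "s", w = "w", m = "k", k = "m", n = "n"))

.alpha5 <- .make_alphabet(
    "alpha5",
    c("A", "C", "G", "T", "n"),
    list(A = "A", C = "C", G = "G", T = "T", n = c("A", "C", "G", "T")),
    c(A = "T", C = "G", G = "C", T = "A", n = "n"))

#' @export
print.motif_alphabet <- function(x, ...) {
    cat("<motif_alphabet ", x$name, ">: ", paste(x$letters, collapse = " "),
        "\n", sep = "")
    invisible(x)
}

#' Size of the search space
#'
#' Number of distinct degenerate words of length `L` over an alphabet:
#' `|alphabet|^L`. For the canonical configurations this is 11^8 =
#' 214,358,881 (8-mers) and 5^12 = 244,140,625 (12-mers).
#'
#' @param alphabet a [motif_alphabet][alphabet11].
#' @param L word length.
#' @return A numeric scalar.
#' @export
n_oligos <- function(alphabet, L) {
    stopifnot(inherits(alphabet, "motif_alphabet"), L >= 1)
    length(alphabet$letters)^as.numeric(L)
}

# 0-based concrete base indices (A,C,G,T -> 0..3) of each letter's match set,
# in digit order; the layout handed to the C++ indexer.
.letter_match_idx <- function(alphabet) {
    lapply(alphabet$match, function(b) match(b, c("A", "C", "G", "T")) - 1L)
}

# digit-level complement permutation (0-based digits)
.comp_digits <- function(alphabet) {
    match(unname(alphabet$comp[alphabet$letters]), alphabet$letters) - 1L
}
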