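#' Canonicalize and validate degenerate words
#'
#' Accepts words in any letter case and returns the canonical dialect:
#' uppercase concrete bases, lowercase wobbles (`"rGTCAAmn"`). Letters
#' outside the alphabet raise an error naming the first offending position.
#'
#' @param word character vector of words.
#' @param alphabet a [motif_alphabet][alphabet11].
#' @param L required word length, or `NULL` to accept any (equal) length.
#' @return The canonicalized character vector.
#' @export
as_oligo <- function(word, alphabet = alphabet11(), L = NULL) {
    stopifnot(is.character(word), inherits(alphabet, "motif_alphabet"))
    word <- chartr("acgtRYSWMKN", "ACGTryswmkn", word)
    len <- unique(nchar(word))
    if (length(len) != 1)
        stop("all words must have the same length")
    if (!is.null(L) && len != L)
        stop("word length ", len, " does not match required length ", L)
    mat <- .word_matrix(word, len)
    bad <- !(mat %in% alphabet$letters)
    if (any(bad)) {
        hit <- which(matrix(bad, nrow = length(word)), arr.ind = TRUE)[1, ]
        stop("invalid letter '", mat[hit[1], hit[2]], "' at position ",
             hit[2], " of word '", word[hit[1]], "'")
    }
    word
}

# words -> n x L character matrix
.word_matrix <- function(word, L = nchar(word[1])) {
    matrix(unlist(strsplit(word, "", fixed = TRUE), use.names = FALSE),
           nrow = length(word), ncol = L, byrow = TRUE)
}

#' Positional-notation integer code of a degenerate word
#'
#' Words are mapped bijectively onto `[0, |alphabet|^L)` by reading their
#' letters as digits (A,C,G,T,r,y,s,w,m,k,n = 0..10 for the 11-letter
#' alphabet; A,C,G,T,n = 0..4 for the 5-letter one), leftmost letter most
#' significant: base-11 positional notation for 8-mers, base-5 for 12-mers.
#'
#' @param word character vector of degenerate words (any case).
#' @param alphabet a [motif_alphabet][alphabet11].
#' @return `encode_oligo`: numeric vector of integer codes.
#' @examples
#' encode_oligo("AAAAAAAA")            # 0
#' encode_oligo("nnnnnnnn")            # 11^8 - 1
#' decode_oligo(19487171)              # "CAAAAAAA"
#' @export
encode_oligo <- function(word, alphabet = alphabet11()) {
    word <- as_oligo(word, alphabet)
    L <- nchar(word[1])
    A <- length(alphabet$letters)
    dig <- match(.word_matrix(word, L), alphabet$letters) - 1
    dim(dig) <- c(length(word), L)
    drop(dig %*% A^((L - 1):0))
}

#' @param code numeric vector of codes in `[0, |alphabet|^L)`.
#' @param L word length.
#' @return `decode_oligo`: character vector of canonical words.
#' @rdname encode_oligo
#' @export
decode_oligo <- function(code, alphabet = alphabet11(), L = 8L) {
    stopifnot(is.numeric(code), inherits(alphabet, "motif_alphabet"))
    A <- length(alphabet$letters)
    if (any(code < 0 | code >= A^L | code != floor(code)))
        stop("code out of range [0, ", A, "^", L, ")")
    cols <- vector("list", L)
    x <- code
    for (i in L:1) {
        cols[[i]] <- alphabet$letters[x %% A + 1]
        x <- x %/% A
    }
    do.call(paste0, cols)
}

#' All degenerate forms of a concrete word
#'
#' Every word over the degenerate alphabet whose match set contains the given
#' concrete word. Under the 11-letter alphabet each position independently
#' takes the base itself, one of the three two-fold wobbles containing it, or
#' n, giving 5^L forms; under the 5-letter alphabet each position takes the
#' base or n, giving 2^L. The concrete word itself is a member of its own
#' expansion set.
#'
#' @param word a single concrete word over A, C, G, T (no N).
#' @inheritParams encode_oligo
#' @return Character vector of degenerate words.
#' @export
degenerate_expansions <- function(word, alphabet = alphabet11()) {
    stopifnot(length(word) == 1)
    word <- as_oligo(word, alphabet)
    chars <- strsplit(word, "", fixed = TRUE)[[1]]
    if (!all(chars %in% c("A", "C", "G", "T")))
        stop("word must be concrete (A/C/G/T only): ", word)
    opts <- lapply(chars, function(b)
        alphabet$letters[vapply(alphabet$match, function(m) b %in% m, logical(1))])
    do.call(paste0, rev(expand.grid(rev(opts), stringsAsFactors = FALSE,
                                    KEEP.OUT.ATTRS = FALSE)))
}

#' Match a degenerate word against concrete windows
#'
#' True iff, at every position, the window base belongs to the oligo letter's
#' match set. An `N` in the window matches nothing (degeneracy is a query-side
#' wildcard, not sequence uncertainty).
#'
#' @param oligo a single degenerate word.
#' @param window character vector of concrete windows of the same length.
#' @inheritParams encode_oligo
#' @return Logical vector, one element per window.
#' @export
oligo_matches <- function(oligo, window, alphabet = alphabet11()) {
    oligo <- as_oligo(oligo, alphabet)
    stopifnot(length(oligo) == 1)
    L <- nchar(oligo)
    if (any(nchar(window) != L))
        stop("window length must equal oligo length ", L)
    wm <- .word_matrix(toupper(window), L)
    om <- strsplit(oligo, "", fixed = TRUE)[[1]]
    ok <- rep(TRUE, length(window))
    for (i in seq_len(L))
        ok <- ok & wm[, i] %in% alphabet$match[[om[i]]]
    ok
}

#' Reverse complement on the degenerate alphabet
#'
#' Letter-wise complement (A-T, C-G, r-y, m-k; s, w, n self-complementary)
#' followed by reversal. An involution, and dual to matching:
#' `oligo_matches(rc_oligo(o), rc(window)) == oligo_matches(o, window)`.
#'
#' @param word character vector of degenerate words.
#' @inheritParams encode_oligo
#' @return Character vector of reverse-complemented words.
#' @examples
#' rc_oligo("rGTCAAmn")  # "nkTTGACy"
#' @export
rc_oligo <- function(word, alphabet = alphabet11()) {
    word <- as_oligo(word, alphabet)
    L <- nchar(word[1])
    mat <- .word_matrix(word, L)
    comp <- alphabet$comp[mat]
    dim(comp) <- dim(mat)
    do.call(paste0, lapply(L:1, function(i) comp[, i]))
}

# reverse complement directly on integer codes (vectorized)
rc_code <- function(code, alphabet = alphabet11(), L = 8L) {
    A <- length(alphabet$letters)
    comp <- .comp_digits(alphabet)
    rc <- numeric(length(code))
    x <- code
    for (i in seq_len(L)) {
        rc <- rc * A + comp[x %% A + 1]
        x <- x %/% A
    }
    rc
}
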