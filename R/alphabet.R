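#' @useDynLib rabrep, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# The 20 canonical amino acids, in the row/column order used by every
# probability table in the package.  'X' (unknown residue) is tolerated in
# sequences and always emits the background distribution.
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Amino-acid background frequency tables
#'
#' Returns a named 20-entry probability vector over the canonical amino
#' acids. `"uniform"` assigns 0.05 to every residue and is the package
#' default; `"robinson"` gives the Robinson-Robinson average composition of
#' proteins, renormalised to sum to one.
#'
#' @param type `"uniform"` or `"robinson"`.
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' aa_background("uniform")[["A"]]
aa_background <- function(type = c("uniform", "robinson")) {
  type <- match.arg(type)
  if (type == "uniform") {
    q <- rep(0.05, 20L)
  } else {
    q <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
           Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
           L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
           S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
    q <- q[AA_ALPHABET]
    q <- q / sum(q)
  }
  names(q) <- AA_ALPHABET
  q
}

# residues (character scalar) -> integer codes 0..19, 20 for 'X'
encode_residues <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET)
  idx[is.na(idx) & chars == "X"] <- 21L
  if (anyNA(idx)) {
    bad <- sort(unique(chars[is.na(idx)]))
    stop("invalid residue characters: ", paste(bad, collapse = ", "))
  }
  as.integer(idx - 1L)
}

decode_residues <- function(codes) {
  paste(c(AA_ALPHABET, "X")[codes + 1L], collapse = "")
}

check_residues <- function(residues, allow_gap = FALSE, what = "sequence") {
  allowed <- c(AA_ALPHABET, "X")
  if (allow_gap) allowed <- c(allowed, "-")
  chars <- unique(strsplit(paste(residues, collapse = ""), "", fixed = TRUE)[[1]])
  bad <- setdiff(chars, allowed)
  if (length(bad) > 0) {
    stop(what, " contains invalid characters: ", paste(sort(bad), collapse = ", "))
  }
  invisible(TRUE)
}

# BLOSUM62 over AA_ALPHABET order (row/col 21 = 'X', scored -1 against
# everything); standard table used by the affine-gap local aligner.
blosum62_matrix <- function() {
  v <- c(
     4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,
    -1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,
    -2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3,
    -2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3,
     0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,
    -1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2,
    -1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2,
     0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,
    -2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3,
    -1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,
    -1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,
    -1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2,
    -1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,
    -2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,
    -1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,
     1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2,
     0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,
    -3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,
    -2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,
     0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4)
  m <- matrix(v, nrow = 20, byrow = TRUE,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  full <- matrix(-1, 21, 21,
                 dimnames = list(c(AA_ALPHABET, "X"), c(AA_ALPHABET, "X")))
  full[1:20, 1:20] <- m
  full
}
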