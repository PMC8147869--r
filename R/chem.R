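# Structure handling: canonical no-stereo aromatic SMILES, hashed circular
# (Morgan/ECFP-like) fingerprints, Tanimoto similarity. Parsing and bit
# generation are delegated to RDKit through inst/python/chemtools.py; the
# similarity arithmetic and all containers live here.

#' Canonicalize SMILES strings
#'
#' Converts SMILES to a canonical aromatic form with all stereochemistry
#' descriptors removed, so that stereoisomers map to the same string and the
#' representation matches the "NostereoAromaticSMILES" dataset column.
#' Idempotent: canonicalizing a canonical string returns it unchanged.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, same length as the input.
#' @examples
#' \dontrun{
#' canonicalize_smiles(c("C1=CC=CC=C1", "c1ccccc1"))  # identical outputs
#' }
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  res <- chemtools("canon", list(smiles = as.list(unname(smiles))))
  out <- vapply(res$canonical, function(x) if (is.null(x)) NA_character_ else x,
                character(1))
  if (anyNA(out)) {
    bad <- smiles[is.na(out)]
    stop("unparsable SMILES: ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  names(out) <- names(smiles)
  out
}

new_fingerprint <- function(bits, n_bits, radius) {
  structure(list(bits = as.integer(bits), n_bits = as.integer(n_bits),
                 radius = as.integer(radius)),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint: %d/%d bits set, radius %d>\n",
              length(x$bits), x$n_bits, x$radius))
  invisible(x)
}

#' Hashed circular fingerprints
#'
#' Computes binary Morgan fingerprints (radius 2, 2048 bits by default, no
#' occurrence counts) for a vector of SMILES. The fingerprint depends only on
#' the canonical structure, so different spellings of one molecule agree.
#'
#' @param smiles Character vector of SMILES (optionally named by compound id).
#' @param radius Neighborhood radius of the circular algorithm.
#' @param n_bits Length of the hashed bit vector (a power of two).
#' @return A named list of `fingerprint` objects, each holding the sorted
#'   0-based indices of the set bits.
#' @export
fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  stopifnot(is.character(smiles), radius >= 1, n_bits >= 2,
            bitwAnd(as.integer(n_bits), as.integer(n_bits) - 1L) == 0L)
  if (length(smiles) == 0) return(structure(list(), names = character(0)))
  res <- chemtools("fp", list(smiles = as.list(unname(smiles)),
                              radius = radius, n_bits = n_bits))
  fps <- lapply(seq_along(res$bits), function(i) {
    b <- res$bits[[i]]
    if (is.null(b)) stop("unparsable SMILES: ", smiles[i], call. = FALSE)
    new_fingerprint(unlist(b, use.names = FALSE), n_bits, radius)
  })
  names(fps) <- if (!is.null(names(smiles))) names(smiles) else smiles
  fps
}

#' Tanimoto similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the set bits; the standard 2D
#' chemical similarity coefficient. Symmetric, in `[0, 1]`, and 1 for
#' identical bit sets.
#'
#' @param a,b `fingerprint` objects of equal length.
#' @return Numeric similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$n_bits != b$n_bits) {
    stop("fingerprint length mismatch: ", a$n_bits, " vs ", b$n_bits,
         call. = FALSE)
  }
  n_union <- length(union(a$bits, b$bits))
  if (n_union == 0) {
    stop("both fingerprints are empty; Tanimoto undefined", call. = FALSE)
  }
  length(intersect(a$bits, b$bits)) / n_union
}

#' Pairwise Tanimoto similarity matrix
#'
#' Dense all-against-all Tanimoto similarities computed by bit-matrix
#' algebra; used by nearest-neighbor set reduction where every group pair is
#' needed anyway.
#'
#' @param fps Named list of `fingerprint` objects (equal `n_bits`).
#' @return Numeric matrix with unit diagonal, dimnames from `names(fps)`.
#' @export
tanimoto_matrix <- function(fps) {
  stopifnot(length(fps) >= 1)
  n_bits <- unique(vapply(fps, `[[`, integer(1), "n_bits"))
  if (length(n_bits) != 1) stop("fingerprint length mismatch", call. = FALSE)
  m <- matrix(0L, nrow = length(fps), ncol = n_bits)
  for (i in seq_along(fps)) m[i, fps[[i]]$bits + 1L] <- 1L
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  un <- outer(sizes, sizes, `+`) - inter
  sim <- ifelse(un > 0, inter / un, 0)
  dimnames(sim) <- list(names(fps), names(fps))
  sim
}
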