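# Dataset curation: molecular fingerprints + Tanimoto similarity for the
# compounds, TM-score for the proteins, and selection of the held-out
# test pair as the entry least similar to the rest of the set.

#' Hashed linear-path fingerprint
#'
#' Enumerates all simple paths of 1-7 atoms over the bond graph, writes
#' each as a canonical element string (the lexicographically smaller of
#' the path and its reverse), and hashes the distinct strings into a
#' fixed-length bit string. Deterministic and independent of atom
#' numbering.
#'
#' @param ligand an `mc_ligand` with bonds perceived.
#' @param nbits fingerprint length (default 2048).
#' @param max_len maximum path length in atoms (default 7).
#' @return a `fingerprint`: list with `bits` (sorted set-bit indices,
#'   1-based) and `nbits`.
#' @export
fingerprint <- function(ligand, nbits = 2048L, max_len = 7L) {
  atoms <- ligand$atoms
  n <- nrow(atoms)
  el <- atoms$element
  nbrs <- .neighbor_list(n, ligand$bonds)
  paths <- new.env(hash = TRUE, parent = emptyenv())
  walk <- function(path) {
    s <- paste(el[path], collapse = "-")
    r <- paste(rev(el[path]), collapse = "-")
    key <- if (s <= r) s else r
    assign(key, TRUE, envir = paths)
    if (length(path) < max_len) {
      for (nx in nbrs[[path[length(path)]]]) {
        if (!(nx %in% path)) walk(c(path, nx))
      }
    }
  }
  for (s in seq_len(n)) walk(s)
  keys <- ls(paths)
  bits <- sort(unique(vapply(keys, .string_hash, 0L, nbits = nbits)))
  structure(list(bits = bits, nbits = as.integer(nbits)), class = "fingerprint")
}

# Deterministic polynomial string hash folded to 1..nbits.
.string_hash <- function(s, nbits) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 1048573
  as.integer(h %% nbits) + 1L
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d/%d bits set\n", length(x$bits), x$nbits))
  invisible(x)
}

#' Tanimoto similarity between two fingerprints
#'
#' |A intersect B| / (|A| + |B| - |A intersect B|) over set bits. Two
#' empty fingerprints compare as 0 (with a warning).
#'
#' @param a,b `fingerprint` objects of equal length.
#' @return scalar in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (a$nbits != b$nbits) stop("fingerprint length mismatch")
  na <- length(a$bits); nb <- length(b$bits)
  if (na == 0 && nb == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  inter <- length(intersect(a$bits, b$bits))
  inter / (na + nb - inter)
}

# ---------------------------------------------------------------------------
# TM-score

#' TM-score between two protein structures
#'
#' score = (1/L) sum_i 1/(1 + (d_i/d0)^2) with the length-dependent scale
#' d0 = 1.24 (L - 15)^(1/3) - 1.8 (floored at 0.5 Angstrom), L the number
#' of residues of the reference (second) structure, and d_i the distances
#' of matched residues after an iteratively refined Kabsch superposition
#' that maximizes the score. Correspondence comes from an explicit
#' mapping, from identical lengths (identity mapping), or from a global
#' sequence alignment of the supplied one-letter sequences (BLOSUM62,
#' affine gaps, via Biostrings).
#'
#' @param coords_a,coords_b representative-atom coordinate matrices (one
#'   row per residue, e.g. C-alpha).
#' @param correspondence optional 2-column integer matrix mapping rows of
#'   `coords_a` to rows of `coords_b`.
#' @param seq_a,seq_b optional one-letter amino-acid sequences used to
#'   align when the correspondence is not given.
#' @return a `tm_score_result`: `score`, `L` (aligned length), `d0`,
#'   `distances` (per matched residue, after the final superposition).
#' @export
tm_score <- function(coords_a, coords_b, correspondence = NULL,
                     seq_a = NULL, seq_b = NULL) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (is.null(correspondence)) {
    if (!is.null(seq_a) && !is.null(seq_b)) {
      correspondence <- .align_sequences(seq_a, seq_b)
    } else if (nrow(coords_a) == nrow(coords_b)) {
      correspondence <- cbind(seq_len(nrow(coords_a)), seq_len(nrow(coords_b)))
    } else {
      stop("no correspondence: supply a mapping or sequences to align")
    }
  }
  L <- nrow(correspondence)
  if (L < 20) stop(sprintf("only %d matched residues (need >= 20)", L))
  L_ref <- nrow(coords_b)
  d0 <- max(0.5, 1.24 * (L_ref - 15)^(1 / 3) - 1.8)
  A <- coords_a[correspondence[, 1], , drop = FALSE]
  B <- coords_b[correspondence[, 2], , drop = FALSE]
  score_of <- function(fitA) {
    d <- sqrt(rowSums((fitA - B)^2))
    list(score = sum(1 / (1 + (d / d0)^2)) / L_ref, d = d)
  }
  subset <- seq_len(L)
  best <- list(score = -Inf, d = NULL)
  for (it in 1:30) {
    k <- kabsch(A[subset, , drop = FALSE], B[subset, , drop = FALSE])
    sc <- score_of(k$transform(A))
    if (sc$score > best$score) best <- sc
    cut <- max(d0, 1.5)
    new_subset <- which(sc$d < cut)
    if (length(new_subset) < 4) new_subset <- order(sc$d)[1:min(L, 4)]
    if (identical(new_subset, subset)) break
    subset <- new_subset
  }
  structure(list(score = best$score, L = L, d0 = d0, distances = best$d),
            class = "tm_score_result")
}

#' @export
print.tm_score_result <- function(x, ...) {
  cat(sprintf("<tm_score> %.4f (L = %d, d0 = %.3f A)\n", x$score, x$L, x$d0))
  invisible(x)
}

# Global alignment of one-letter sequences -> residue correspondence.
.align_sequences <- function(seq_a, seq_b) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("sequence-based correspondence needs the Biostrings package")
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ia <- 0L; ib <- 0L
  map <- matrix(integer(0), ncol = 2)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (ps[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && ps[k] != "-") map <- rbind(map, c(ia, ib))
  }
  map
}

#' Select the held-out test pair
#'
#' Given the pairwise Tanimoto matrix of the compounds and the pairwise
#' TM-score matrix of the proteins, returns the entry whose mean
#' off-diagonal similarity, averaged over the two matrices, is smallest -
#' the complex that in total differs the most from the rest of the set.
#' Ties take the lowest index / first name.
#'
#' @param tanimoto_matrix,tm_matrix square numeric matrices over the same
#'   index set (matching dimnames when named).
#' @return the selected id (name when available, otherwise index).
#' @export
select_test_pair <- function(tanimoto_matrix, tm_matrix) {
  A <- as.matrix(tanimoto_matrix); B <- as.matrix(tm_matrix)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 entries")
  if (!all(dim(A) == dim(B))) stop("matrix dimensions differ")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B))) {
    B <- B[rownames(A), rownames(A)]
  }
  off_mean <- function(M, i) mean(M[i, -i])
  combined <- vapply(seq_len(n), function(i) {
    (off_mean(A, i) + off_mean(B, i)) / 2
  }, 0)
  i <- which.min(combined)  # which.min takes the first (lowest) on ties
  if (!is.null(rownames(A))) rownames(A)[i] else i
}
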