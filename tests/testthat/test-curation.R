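fp_of <- function(bits, nbits = 16) {
  structure(list(bits = as.integer(sort(bits)), nbits = as.integer(nbits)),
            class = "fingerprint")
}

test_that("Tanimoto similarity follows the intersection-over-union identity", {
  expect_equal(tanimoto(fp_of(c(1, 2, 3)), fp_of(c(1, 2, 3))), 1)
  expect_equal(tanimoto(fp_of(c(1, 2)), fp_of(c(3, 4))), 0)
  # |A| = 4, |B| = 6, |A int B| = 2 -> 2 / 8
  expect_equal(tanimoto(fp_of(1:4), fp_of(c(3, 4, 7, 8, 9, 10))), 0.25)
  expect_error(tanimoto(fp_of(1, nbits = 16), fp_of(1, nbits = 32)), "mismatch")
  expect_warning(v <- tanimoto(fp_of(integer(0)), fp_of(integer(0))), "empty")
  expect_equal(v, 0)
})

test_that("Tanimoto is symmetric and bounded on random fingerprints", {
  set.seed(41)
  for (k in 1:20) {
    a <- fp_of(sample(64, sample(1:20, 1)), 64)
    b <- fp_of(sample(64, sample(1:20, 1)), 64)
    tab <- tanimoto(a, b)
    expect_equal(tab, tanimoto(b, a))
    expect_gte(tab, 0); expect_lte(tab, 1)
  }
})

test_that("path fingerprints are deterministic and atom-order invariant", {
  lig <- make_toy_complex("Ru", 4, 1, seed = 5)
  f1 <- fingerprint(lig)
  expect_identical(f1$bits, fingerprint(lig)$bits)
  expect_gte(length(f1$bits), 1)
  set.seed(6)
  perm <- sample(nrow(lig$atoms))
  f2 <- fingerprint(new_ligand(lig$atoms[perm, ]))
  expect_identical(f1$bits, f2$bits)
  # single atom still yields a valid fingerprint
  single <- new_ligand(data.frame(element = "O", x = 0, y = 0, z = 0))
  expect_gte(length(fingerprint(single)$bits), 1)
  # distinct structures differ
  expect_lt(tanimoto(fingerprint(methane_ligand()), fingerprint(benzene_ligand())), 1)
})

test_that("TM-score is 1 for self, rigid-motion invariant, and length-scaled", {
  set.seed(42)
  A <- cbind(cumsum(rnorm(80, 1.2, 0.4)), cumsum(rnorm(80, 0, 0.8)),
             cumsum(rnorm(80, 0, 0.8)))
  self <- tm_score(A, A)
  expect_equal(self$score, 1, tolerance = 1e-9)
  R <- mcdock:::random_rotation()
  B <- sweep(A %*% t(R), 2, c(4, -7, 2), "+")
  expect_equal(tm_score(B, A)$score, 1, tolerance = 1e-6)
  # d0 closed form
  expect_equal(tm_score(A, A)$d0, 1.24 * (80 - 15)^(1 / 3) - 1.8, tolerance = 1e-12)
  expect_error(tm_score(A[1:10, ], A[1:10, ]), "20")
  # score recomputable from the reported fields
  expect_equal(self$score,
               sum(1 / (1 + (self$distances / self$d0)^2)) / nrow(A),
               tolerance = 1e-9)
})

test_that("unrelated folds score low", {
  set.seed(43)
  helixish <- cbind(3 * cos(0.6 * (1:60)), 3 * sin(0.6 * (1:60)), 1.5 * (1:60) / 4)
  extended <- cbind(3.5 * (1:60), rnorm(60, 0, 0.3), rnorm(60, 0, 0.3))
  expect_lt(tm_score(extended, helixish)$score, 0.3)
})

test_that("sequence alignment supplies the residue correspondence", {
  skip_if_not_installed("Biostrings")
  set.seed(44)
  A <- cbind(cumsum(rnorm(40, 1.5, 0.2)), cumsum(rnorm(40, 0, 0.5)),
             cumsum(rnorm(40, 0, 0.5)))
  seq_full <- paste(sample(c("A", "L", "K", "E", "G", "V"), 40, replace = TRUE),
                    collapse = "")
  # same structure with five leading residues trimmed
  res <- tm_score(A[6:40, ], A, seq_a = substr(seq_full, 6, 40), seq_b = seq_full)
  expect_equal(res$L, 35)
  expect_gt(res$score, 0.8)
})

test_that("the held-out selection takes the least-similar entry", {
  tanm <- matrix(0.9, 4, 4); diag(tanm) <- 1
  tmm <- matrix(0.8, 4, 4); diag(tmm) <- 1
  tanm[3, ] <- tanm[, 3] <- 0.1; tanm[3, 3] <- 1
  tmm[3, ] <- tmm[, 3] <- 0.2; tmm[3, 3] <- 1
  expect_equal(select_test_pair(tanm, tmm), 3)
  # all-identical -> lowest id
  expect_equal(select_test_pair(matrix(1, 3, 3), matrix(1, 3, 3)), 1)
  expect_error(select_test_pair(matrix(1), matrix(1)), "at least 2")
  # named matrices return the name
  rownames(tanm) <- colnames(tanm) <- rownames(tmm) <- colnames(tmm) <-
    c("1ABC", "2DEF", "3GHI", "4JKL")
  expect_equal(select_test_pair(tanm, tmm), "3GHI")
})

test_that("the selection matches a brute-force scan on random matrices", {
  set.seed(45)
  for (k in 1:10) {
    n <- 4
    A <- matrix(runif(n * n), n); A <- (A + t(A)) / 2; diag(A) <- 1
    B <- matrix(runif(n * n), n); B <- (B + t(B)) / 2; diag(B) <- 1
    want <- which.min(vapply(seq_len(n), function(i) {
      (mean(A[i, -i]) + mean(B[i, -i])) / 2
    }, 0))
    expect_equal(select_test_pair(A, B), want)
  }
})
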