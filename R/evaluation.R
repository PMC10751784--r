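# Pose quality: in-place all-atom RMSD versus a reference, aggregation
# into the mean-over-pairs-and-poses objective, and the RMSD-versus-
# resolution report.

#' In-place RMSD between a pose and a reference
#'
#' No re-superposition: docked poses live in the receptor frame, so the
#' RMSD is computed on the coordinates as given. Dummy atoms are excluded.
#' Mode "ordered" matches atoms by position in the list; "element-matched"
#' solves, per element, the optimal assignment (exhaustive for up to 8
#' equivalent atoms, Hungarian beyond) to handle symmetry-equivalent
#' atoms.
#'
#' @param pose,reference n x 3 coordinate matrices, or objects with
#'   coordinates ([coords()] is applied to lists/ligands).
#' @param mode "ordered" (default) or "element-matched".
#' @param elements element symbols per row (required for element-matched
#'   mode; taken from the ligand when one is passed).
#' @param dummy_index optional dummy-atom row to drop from both inputs.
#' @return RMSD in Angstrom.
#' @export
pose_rmsd <- function(pose, reference, mode = c("ordered", "element-matched"),
                      elements = NULL, dummy_index = NA) {
  mode <- match.arg(mode)
  get_xyz <- function(x) {
    if (is.matrix(x)) x else if (!is.null(x$atoms)) coords(x) else as.matrix(x)
  }
  if (!is.matrix(pose) && !is.null(pose$atoms)) {
    if (is.null(elements)) elements <- pose$atoms$element
    if (is.na(dummy_index) && !is.null(pose$dummy_index)) dummy_index <- pose$dummy_index
  }
  P <- get_xyz(pose); Q <- get_xyz(reference)
  if (!is.na(dummy_index)) {
    if (nrow(P) >= dummy_index) P <- P[-dummy_index, , drop = FALSE]
    if (nrow(Q) == nrow(P) + 1L) Q <- Q[-dummy_index, , drop = FALSE]
    if (!is.null(elements) && length(elements) == nrow(P) + 1L) {
      elements <- elements[-dummy_index]
    }
  }
  if (nrow(P) != nrow(Q)) {
    stop(sprintf("atom-count mismatch: pose has %d, reference has %d", nrow(P), nrow(Q)))
  }
  if (mode == "ordered") {
    return(sqrt(mean(rowSums((P - Q)^2))))
  }
  if (is.null(elements)) stop("element-matched mode needs element symbols")
  stopifnot(length(elements) == nrow(P))
  ss <- 0
  for (el in unique(elements)) {
    ix <- which(elements == el)
    if (length(ix) == 1L) {
      ss <- ss + sum((P[ix, ] - Q[ix, ])^2)
    } else {
      cost <- outer(ix, ix, Vectorize(function(i, j) sum((P[i, ] - Q[j, ])^2)))
      ss <- ss + .min_assignment_cost(cost)
    }
  }
  sqrt(ss / nrow(P))
}

# Minimum-cost perfect assignment on a square cost matrix: exhaustive for
# n <= 8, Hungarian algorithm otherwise.
.min_assignment_cost <- function(cost) {
  n <- nrow(cost)
  if (n <= 8L) {
    perms <- .permutations(n)
    best <- Inf
    for (k in seq_len(nrow(perms))) {
      s <- sum(cost[cbind(seq_len(n), perms[k, ])])
      if (s < best) best <- s
    }
    return(best)
  }
  sol <- .hungarian(cost)
  sum(cost[cbind(seq_len(n), sol)])
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}

# O(n^3) Hungarian algorithm (shortest augmenting path formulation,
# potentials u/v). Returns the column assigned to each row. Index 0 of the
# classic formulation is stored at slot 1 (shift by one throughout).
.hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Aggregate per-pair, per-pose RMSDs into the total objective
#'
#' The Monte Carlo fitting objective: the arithmetic mean over all N pairs
#' and M poses (equivalently, the mean of per-pair means when every pair
#' has the same number of poses).
#'
#' @param per_pair_per_pose numeric matrix, N pairs x M poses, Angstrom.
#' @return mean RMSD in Angstrom.
#' @export
total_rmsd <- function(per_pair_per_pose) {
  m <- as.matrix(per_pair_per_pose)
  if (length(m) == 0) stop("empty RMSD matrix")
  if (any(m < 0)) stop("RMSD entries must be non-negative")
  mean(m)
}

#' RMSD-versus-resolution differences per metal
#'
#' For each metal, the difference between the average docked RMSD and the
#' average crystallographic resolution of its reference structures - the
#' inherent experimental uncertainty. A difference near or below zero
#' means the docking reproduces the references within experimental error.
#'
#' @param rmsd_avg named numeric, average RMSD per metal, Angstrom.
#' @param resolution_avg named numeric, average resolution per metal,
#'   Angstrom; names must match `rmsd_avg`.
#' @return data.frame with columns `metal`, `rmsd`, `resolution`,
#'   `difference` (rounded to 3 decimals).
#' @export
resolution_report <- function(rmsd_avg, resolution_avg) {
  if (is.null(names(rmsd_avg)) || is.null(names(resolution_avg)) ||
      !setequal(names(rmsd_avg), names(resolution_avg))) {
    stop("rmsd_avg and resolution_avg must have matching metal names")
  }
  metals <- names(rmsd_avg)
  res <- resolution_avg[metals]
  data.frame(metal = metals,
             rmsd = unname(rmsd_avg),
             resolution = unname(res),
             difference = round(unname(rmsd_avg) - unname(res), 3),
             row.names = NULL)
}
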