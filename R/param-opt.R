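# Monte Carlo fitting of the four metal well depths (HD, NA, OA, SA)
# against a training set of reference complexes. The objective is the mean
# all-atom RMSD over all training pairs and docked poses; proposals are
# uniform on [0, 7] kcal/mol and accepted greedily (or by a Metropolis
# rule when requested).

EPS_RANGE <- c(0, 7)  # kcal/mol, support of the proposal distribution

#' Propose a well depth
#'
#' One uniform draw on [0, 7] kcal/mol from R's RNG stream.
#'
#' @param n number of draws (default 1).
#' @return numeric vector.
#' @export
propose_epsilon <- function(n = 1) {
  stats::runif(n, EPS_RANGE[1], EPS_RANGE[2])
}

#' Monte Carlo optimization of the metal well depths
#'
#' Coordinate-wise sweep in the fixed order HD, NA, OA, SA: each parameter
#' is sampled `samples_per_param` times; after every proposal all training
#' pairs are re-docked under the trial parameter set, the mean RMSD over
#' all pairs and poses is computed, and the proposal is accepted when it
#' does not exceed the best RMSD so far (greedy mode; `"metropolis"`
#' additionally accepts uphill moves with probability
#' exp(-(RMSD_i - RMSD_b)/T)). The best RMSD carries across sweeps.
#'
#' @param training_set list of pairs, each a list with `ligand` (typed,
#'   charged, torsion tree built), `receptor`, `reference` (coordinate
#'   matrix or ligand), and `box` (a `docking_box`).
#' @param dock_fn function(ligand, receptor, params, box, seed) returning a
#'   `dock_result`; [ga_dock()] conforms, as does [mock_dock()] for fast
#'   surrogate fitting.
#' @param init_eps starting well depths, kcal/mol (default 2 for each).
#' @param samples_per_param proposals per parameter (default 250).
#' @param acceptance "greedy" (default) or "metropolis".
#' @param temperature Metropolis temperature in Angstrom of RMSD (default
#'   0.1; unused in greedy mode).
#' @param metal metal element symbol used to build the parameter sets.
#' @param seed integer seed; every docking evaluation gets a fresh derived
#'   seed, recorded in the history for replay.
#' @param rmsd_mode RMSD matching mode, "ordered" (default) or
#'   "element-matched".
#' @param verbose print a line per accepted proposal.
#' @return an `mc_fit`: `eps` (named final well depths), `rmsd_best`,
#'   `rmsd_init`, `history` data.frame (param, proposed, rmsd, accepted,
#'   seed), `acceptance`, `seed`.
#' @export
mc_optimize <- function(training_set, dock_fn,
                        init_eps = c(HD = 2, "NA" = 2, OA = 2, SA = 2),
                        samples_per_param = 250,
                        acceptance = c("greedy", "metropolis"),
                        temperature = 0.1, metal = "Ru", seed = 1,
                        rmsd_mode = "ordered", verbose = FALSE) {
  acceptance <- match.arg(acceptance)
  if (length(training_set) == 0) stop("empty training set")
  stopifnot(all(c("HD", "NA", "OA", "SA") %in% names(init_eps)))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  eps <- init_eps[c("HD", "NA", "OA", "SA")]
  objective <- function(eps_try, eval_id) {
    params <- set_metal_eps(default_params(metal), eps_try)
    rows <- lapply(seq_along(training_set), function(pi) {
      pair <- training_set[[pi]]
      dseed <- (seed * 7919L + eval_id * 104729L + pi) %% 2147483629L
      res <- tryCatch(
        dock_fn(pair$ligand, pair$receptor, params, pair$box, seed = dseed),
        error = function(e) {
          warning(sprintf("docking failed for pair %d: %s", pi, conditionMessage(e)))
          NULL
        })
      if (is.null(res)) return(NULL)
      vapply(res$poses, function(p) {
        pose_rmsd(p$coords, pair$reference, mode = rmsd_mode,
                  elements = pair$ligand$atoms$element,
                  dummy_index = pair$ligand$dummy_index)
      }, 0)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (!length(rows)) stop("all docking evaluations failed")
    mean(unlist(rows))
  }
  eval_id <- 0L
  rmsd_init <- objective(eps, eval_id)
  rmsd_best <- rmsd_init
  hist_n <- 4L * samples_per_param
  history <- data.frame(param = character(hist_n), proposed = numeric(hist_n),
                        rmsd = numeric(hist_n), accepted = logical(hist_n),
                        seed = integer(hist_n), stringsAsFactors = FALSE)
  row <- 0L
  for (par in c("HD", "NA", "OA", "SA")) {
    for (s in seq_len(samples_per_param)) {
      eval_id <- eval_id + 1L
      prop <- propose_epsilon(1)
      eps_try <- eps
      eps_try[par] <- prop
      rmsd_i <- objective(eps_try, eval_id)
      acc <- if (rmsd_i <= rmsd_best) TRUE
      else if (acceptance == "metropolis") {
        stats::runif(1) < exp(-(rmsd_i - rmsd_best) / temperature)
      } else FALSE
      if (acc) {
        eps <- eps_try
        if (rmsd_i <= rmsd_best) rmsd_best <- rmsd_i
        if (verbose) {
          message(sprintf("accept %s = %.3f kcal/mol (RMSD %.4f A)", par, prop, rmsd_i))
        }
      }
      row <- row + 1L
      history$param[row] <- par
      history$proposed[row] <- prop
      history$rmsd[row] <- rmsd_i
      history$accepted[row] <- acc
      history$seed[row] <- eval_id
    }
  }
  structure(list(eps = eps, rmsd_best = rmsd_best, rmsd_init = rmsd_init,
                 history = history[seq_len(row), , drop = FALSE],
                 acceptance = acceptance, metal = metal, seed = seed),
            class = "mc_fit")
}

#' @export
print.mc_fit <- function(x, ...) {
  cat(sprintf("<mc_fit> metal %s, %s acceptance, %d proposals\n",
              x$metal, x$acceptance, nrow(x$history)))
  cat(sprintf("  eps (kcal/mol): HD %.3f  NA %.3f  OA %.3f  SA %.3f\n",
              x$eps["HD"], x$eps["NA"], x$eps["OA"], x$eps["SA"]))
  cat(sprintf("  RMSD %.4f -> %.4f A (%d accepted)\n",
              x$rmsd_init, x$rmsd_best, sum(x$history$accepted)))
  invisible(x)
}

#' @export
coef.mc_fit <- function(object, ...) object$eps

#' @export
summary.mc_fit <- function(object, ...) {
  h <- object$history
  agg <- do.call(rbind, lapply(split(h, h$param), function(d) {
    data.frame(param = d$param[1], proposals = nrow(d),
               accepted = sum(d$accepted),
               final_eps = object$eps[d$param[1]])
  }))
  rownames(agg) <- NULL
  agg[match(c("HD", "NA", "OA", "SA"), agg$param), ]
}

#' Write fitted parameters as a parameter-table file
#'
#' @param fit an `mc_fit`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fit_params <- function(fit, path) {
  lines <- c("# fitted metal well depths (kcal/mol)",
             vapply(c("HD", "NA", "OA", "SA"), function(t) {
               sprintf("%s %s %.4f %.2f %s", fit$metal, t, fit$eps[t],
                       METAL_RMIN[t], if (t == "HD") "12-6" else "12-10")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
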