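## Condition-level analysis: from a cohort of trajectories to the
## condition x outcome grid. Experiment 1 cells (dynamic rod motion) are
## tested within-flight: omnibus Friedman over pre/post-onset bins, followed,
## when significant, by exact all-pairs comparisons; a cell shows an altitude
## change only if some pre-vs-post pair stays significant after adjustment.
## Experiment 2 cells (static rod position) are tested between flights:
## Mann-Whitney on per-flight median altitudes against the parallel control.

#' Epoch matrix for one condition cell
#'
#' Bins every trajectory ([bin_median()]) and assembles the epoch matrix
#' around the rod onset. The default post window extends 6 bins (0.9 s) after
#' onset, covering the 0.5--0.75 s response latency seen in the tunnel
#' experiments.
#'
#' @param trajs List of `trajectory` objects from one condition.
#' @param onset Rod onset (s).
#' @param n_before,n_after Bins on each side of the onset.
#' @return An `epoch_matrix`.
#' @export
cell_epoch_matrix <- function(trajs, onset = 2, n_before = 3, n_after = 6) {
  epoch_split(lapply(trajs, bin_median), onset = onset,
              n_before = n_before, n_after = n_after)
}

#' Test one experiment-1 cell for a perturbation-locked altitude change
#'
#' Omnibus Friedman on the epoch matrix; if significant at `alpha`, exact
#' all-pairs comparisons. The cell is called significant only when some
#' pre-onset vs post-onset pair has an adjusted p below `alpha`; the direction
#' is the sign of the post minus pre column medians of that pair.
#'
#' @param trajs List of trajectories of the cell.
#' @param alpha Significance level.
#' @param onset,n_before,n_after Epoch window (see [cell_epoch_matrix()]).
#' @param mc_draws,seed Passed to [friedman_allpairs()].
#' @return List: `omnibus` (htest), `pairs` (pairwise_result or NULL),
#'   `significant` (logical), `direction` (`"increase"`, `"decrease"`,
#'   `"none"`).
#' @export
test_exp1_cell <- function(trajs, alpha = 0.01, onset = 2,
                           n_before = 3, n_after = 6,
                           mc_draws = 1e5, seed = NULL) {
  em <- cell_epoch_matrix(trajs, onset, n_before, n_after)
  omni <- friedman_test(em)
  out <- list(omnibus = omni, pairs = NULL, significant = FALSE,
              direction = "none")
  if (omni$p.value >= alpha) return(out)
  pr <- friedman_allpairs(em, mc_draws = mc_draws, seed = seed)
  out$pairs <- pr
  centers <- attr(em, "bin_centers")
  labs <- colnames(em)
  pre <- labs[centers < onset]; post <- labs[centers > onset]
  hit <- pr$p_adj < alpha &
    ((pr$treat_i %in% pre & pr$treat_j %in% post) |
     (pr$treat_i %in% post & pr$treat_j %in% pre))
  if (any(hit)) {
    q <- which(hit)[which.min(pr$p_adj[hit])]
    a <- pr$treat_i[q]; b <- pr$treat_j[q]
    pre_lab <- if (a %in% pre) a else b
    post_lab <- if (a %in% pre) b else a
    d <- stats::median(em[, post_lab]) - stats::median(em[, pre_lab])
    out$significant <- TRUE
    out$direction <- if (d > 0) "increase" else "decrease"
  }
  out
}

#' Test one experiment-2 cell against its control
#'
#' Mann-Whitney on the per-flight median altitudes of the manipulated cell
#' versus the parallel-rod control flown over the same texture.
#'
#' @param trajs Trajectories of the manipulated cell.
#' @param control_trajs Trajectories of the control cell.
#' @param alpha Significance level.
#' @return List: `test` (htest), `significant`, `direction`.
#' @export
test_exp2_cell <- function(trajs, control_trajs, alpha = 0.01) {
  med <- vapply(trajs, function(tr) stats::median(tr$z), 0)
  medc <- vapply(control_trajs, function(tr) stats::median(tr$z), 0)
  ht <- mann_whitney(med, medc)
  sig <- ht$p.value < alpha
  list(test = ht, significant = sig,
       direction = if (!sig) "none"
                   else if (stats::median(med) > stats::median(medc)) "increase"
                   else "decrease")
}

cohort_cells <- function(trajs) {
  key <- vapply(trajs, function(tr) {
    paste(attr(tr, "mode"), attr(tr, "texture"), attr(tr, "experiment"),
          sep = ".")
  }, "")
  split(trajs, key)
}

#' Condition-by-outcome grid for a full cohort
#'
#' Applies [test_exp1_cell()] to every dynamic-rod cell (and its controls) and
#' [test_exp2_cell()] to every static-rod cell, reproducing the qualitative
#' outcome pattern of the tunnel experiments: with the default controller and
#' safety on, the only significant cell is dynamic converging over white
#' ground (an increase).
#'
#' @param trajs Cohort list from [generate_cohort()] or [read_flights()].
#' @param alpha Significance level.
#' @param mc_draws,seed Passed to the pairwise comparisons.
#' @return data.frame: `mode`, `texture`, `experiment`, `p`, `significant`,
#'   `direction`.
#' @export
outcome_grid <- function(trajs, alpha = 0.01, mc_draws = 1e5, seed = NULL) {
  cells <- cohort_cells(trajs)
  info <- do.call(rbind, lapply(names(cells), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(key = k, mode = parts[1], texture = parts[2],
               experiment = parts[3], stringsAsFactors = FALSE)
  }))
  res <- info; res$p <- NA_real_; res$significant <- FALSE; res$direction <- "none"
  for (i in seq_len(nrow(info))) {
    cell <- cells[[info$key[i]]]
    if (info$experiment[i] == "exp2" &&
        grepl("^static", info$mode[i])) {
      ctrl_key <- paste("parallel", info$texture[i], "exp2", sep = ".")
      if (!ctrl_key %in% names(cells)) next
      r <- test_exp2_cell(cell, cells[[ctrl_key]], alpha)
      res$p[i] <- r$test$p.value
    } else if (info$experiment[i] == "exp2") {
      # control cells of experiment 2: compared to themselves by design; test
      # narrow against parallel for completeness
      if (info$mode[i] == "narrow") {
        ctrl_key <- paste("parallel", info$texture[i], "exp2", sep = ".")
        if (!ctrl_key %in% names(cells)) next
        r <- test_exp2_cell(cell, cells[[ctrl_key]], alpha)
        res$p[i] <- r$test$p.value
      } else {
        r <- list(significant = FALSE, direction = "none")
        res$p[i] <- 1
      }
    } else {
      r <- test_exp1_cell(cell, alpha, mc_draws = mc_draws, seed = seed)
      res$p[i] <- r$omnibus$p.value
    }
    res$significant[i] <- r$significant
    res$direction[i] <- r$direction
  }
  res$key <- NULL
  res[order(res$experiment, res$texture, res$mode), ]
}
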