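#' Parameter search grids
#'
#' The broad range spans two and a half orders of magnitude per parameter;
#' the focused range is built around the broad winner in half-octave
#' (factor sqrt(2)) steps.
#'
#' @param etas,alphas positive parameter values.
#' @return A `search_grid`.
#' @export
search_grid <- function(etas, alphas) {
  if (!length(etas) || !length(alphas) || any(etas <= 0) || any(alphas <= 0))
    stop("grids must be non-empty and positive")
  structure(list(etas = etas, alphas = alphas), class = "search_grid")
}

#' @rdname search_grid
#' @export
broad_grid <- function() {
  search_grid(etas = c(0.25, 1, 4, 16, 64), alphas = c(4, 16, 64, 256, 1024))
}

#' Focused grid around a winning combination
#'
#' Half-octave steps: eta times `2^(-1, -0.5, 0, 0.5, 1, 1.5)` and alpha
#' times `2^(-2, -1.5, -1, -0.5, 0, 0.5, 1)`, rounded to two decimals.
#'
#' @param eta,alpha center (broad-stage winner).
#' @return A `search_grid` of 6 etas x 7 alphas.
#' @export
focused_grid <- function(eta, alpha) {
  search_grid(etas = round(eta * 2^seq(-1, 1.5, by = 0.5), 2),
              alphas = round(alpha * 2^seq(-2, 1, by = 0.5), 2))
}

#' Unique combinations of two search grids
#'
#' @param broad,focused `search_grid`s.
#' @return Data frame of unique `(eta, alpha)` combinations.
#' @export
grid_union <- function(broad, focused) {
  combos <- rbind(expand.grid(eta = broad$etas, alpha = broad$alphas),
                  expand.grid(eta = focused$etas, alpha = focused$alphas))
  unique(combos)
}

#' Pair bookkeeping for a multi-case dataset
#'
#' Each case contributes one pair per moving phase (4 in a 5-phase exam).
#'
#' @param n_cases number of cases.
#' @param pairs_per_case moving phases per case.
#' @return Data frame with `case_id` and `pair_id`.
#' @export
make_pair_index <- function(n_cases, pairs_per_case = 4L) {
  expand.grid(pair_id = paste0("p", seq_len(pairs_per_case)),
              case_id = sprintf("case%02d", seq_len(n_cases)),
              stringsAsFactors = FALSE)[, c("case_id", "pair_id")]
}

#' Seeded random training split of cases
#'
#' @param case_ids all case identifiers.
#' @param n_train number of training cases (default 6).
#' @param seed RNG seed.
#' @return Character vector of training case ids.
#' @export
training_split <- function(case_ids, n_train = 6L, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sort(sample(case_ids, n_train))
}

# mean closest-of-two LD over the training cases for one (eta, alpha) combo,
# plus the total folding count
evaluate_combo <- function(training_cases, variant, eta, alpha, reg) {
  reg$alpha <- alpha
  lds <- numeric(0)
  folds <- 0
  for (case in training_cases) {
    res <- run_motion_correction(case$series, variant = variant, eta = eta,
                                 reg = reg)
    for (pid in names(res)) {
      lm <- case$landmarks[case$landmarks$pair_id == pid, , drop = FALSE]
      lds <- c(lds, landmark_distances(lm, res[[pid]]$field))
      folds <- folds + res[[pid]]$foldings
    }
  }
  list(mean_ld = mean(lds), foldings = folds)
}

#' Two-stage grid search of the registration parameters
#'
#' Stage 1 evaluates the mean closest-of-two landmark distance over all
#' training pairs for every broad-grid combination; stage 2 evaluates a
#' focused grid (half-octave steps) centered on the stage-1 winner.
#' Combinations producing any folding are flagged and excluded from winning;
#' the returned best combination is the fold-free focused-grid argmin (ties
#' broken toward larger alpha — the more regular field — then larger eta).
#'
#' @param training_cases list of `phantom_case`-like objects (each with
#'   `series` and `landmarks`), disjoint from the evaluation cases.
#' @param variant motion-correction variant (see [run_motion_correction()]).
#' @param broad broad-stage [search_grid()].
#' @param focused_factory function `(eta, alpha) -> search_grid` for stage 2
#'   (default [focused_grid()]).
#' @param reg base [reg_params()] (its `alpha` is overridden per combo).
#' @return A `search_result`: `table` (per-combo stage, mean LD, foldings),
#'   `best` (eta, alpha) or `NULL` if every combination folded.
#' @export
optimize_parameters <- function(training_cases, variant = "FM",
                                broad = broad_grid(),
                                focused_factory = focused_grid,
                                reg = reg_params()) {
  stage1 <- expand.grid(eta = broad$etas, alpha = broad$alphas)
  eval_stage <- function(combos, stage) {
    rows <- lapply(seq_len(nrow(combos)), function(i) {
      r <- evaluate_combo(training_cases, variant, combos$eta[i],
                          combos$alpha[i], reg)
      data.frame(stage = stage, eta = combos$eta[i], alpha = combos$alpha[i],
                 mean_ld = r$mean_ld, foldings = r$foldings)
    })
    do.call(rbind, rows)
  }
  t1 <- eval_stage(stage1, "broad")
  pick_best <- function(tab) {
    ok <- tab[tab$foldings == 0, , drop = FALSE]
    if (!nrow(ok)) return(NULL)
    ok <- ok[order(ok$mean_ld, -ok$alpha, -ok$eta), , drop = FALSE]
    ok[1, , drop = FALSE]
  }
  b1 <- pick_best(t1)
  if (is.null(b1))
    return(structure(list(table = t1, best = NULL), class = "search_result"))
  foc <- focused_factory(b1$eta, b1$alpha)
  stage2 <- expand.grid(eta = foc$etas, alpha = foc$alphas)
  t2 <- eval_stage(stage2, "focused")
  tab <- rbind(t1, t2)
  b2 <- pick_best(t2)
  best <- if (is.null(b2)) NULL else c(eta = b2$eta, alpha = b2$alpha)
  structure(list(table = tab, best = best), class = "search_result")
}
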