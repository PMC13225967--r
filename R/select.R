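# Characteristic-frequency selectors. All four consume calibration rows only
# and return a `selection_result` with the chosen variable indices plus the
# diagnostics needed for sampling-trace plots.

new_selection_result <- function(method, chosen, freq, rmsecv_trace,
                                 n_vars_trace, best_iteration, seed = NA_integer_,
                                 ...) {
  chosen <- sort(unique(as.integer(chosen)))
  if (length(chosen) == 0) abort_config("selection produced an empty variable set.")
  structure(
    list(method = method, chosen = chosen,
         chosen_freq_THz = if (!is.null(freq)) freq[chosen] else NULL,
         rmsecv_trace = rmsecv_trace, n_vars_trace = n_vars_trace,
         best_iteration = best_iteration, seed = seed, ...),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %s> %d variables chosen (best iteration %d, RMSECV %.5g)\n",
              x$method, length(x$chosen), x$best_iteration,
              min(x$rmsecv_trace, na.rm = TRUE)))
  invisible(x)
}

#' Serialize a selection result to JSON
#'
#' Chosen frequencies are written at 6 decimals, matching the conventional
#' THz frequency notation.
#'
#' @param result a `selection_result`.
#' @param path output file.
#' @export
write_selection <- function(result, path) {
  out <- list(
    method = result$method, chosen = result$chosen,
    chosen_freq_THz = if (!is.null(result$chosen_freq_THz))
      sprintf("%.6f", result$chosen_freq_THz),
    rmsecv_trace = result$rmsecv_trace, n_vars_trace = result$n_vars_trace,
    best_iteration = result$best_iteration, seed = result$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# exponential decay function ratio for CARS run i of n_runs over p variables:
# run 1 keeps all p, run n_runs keeps 2
cars_edf_ratio <- function(i, p, n_runs) {
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  a * exp(-k * i)
}

# enforced retention count for run i; the tiny slack absorbs floating-point
# error so the exact endpoints (p at run 1, 2 at run n_runs) are honoured
cars_keep_n <- function(i, p, n_runs) {
  min(ceiling(cars_edf_ratio(i, p, n_runs) * p - 1e-9), p)
}

#' Competitive adaptive reweighted sampling (CARS)
#'
#' Monte Carlo PLS runs with exponentially decaying enforced variable
#' retention and coefficient-weighted adaptive resampling. Each run fits a
#' PLS model (latent variables by inner cross-validation) on a random
#' `mc_fraction` row subset of the currently retained variables, weights every
#' variable by its normalised absolute regression coefficient, keeps the top
#' `ceiling(r_i p)` weights by enforced elimination (r_i the exponential decay
#' ratio, from all p at run 1 down to 2 at the last run), then redraws the
#' retained set by p weighted samples with replacement, so the survivor count
#' tracks the enforced decay schedule while low-weight variables can still
#' drop out. Each run's retained subset is scored by k-fold RMSECV on the
#' full calibration set and the minimum-RMSECV run wins, subject to
#' `tie_rule`.
#'
#' @param X calibration spectra (>= 3 variables).
#' @param y response.
#' @param n_runs Monte Carlo sampling runs (default 100).
#' @param max_lv largest latent-variable count (default 10).
#' @param cv_folds folds for the per-run RMSECV (default 10).
#' @param mc_fraction fraction of calibration rows drawn per run (default
#'   0.8).
#' @param seed integer seed for the Monte Carlo stream; the fold assignment is
#'   seeded independently so selector comparisons share folds.
#' @param tie_rule `"one_se"` (default): among runs whose RMSECV is within
#'   one standard error of the minimum, return the one with the fewest
#'   variables -- the usual parsimony rule, needed because fully pruned runs
#'   often sit on a flat RMSECV plateau; `"strict"`: return the exact
#'   minimum-RMSECV run.
#' @param freq optional frequency axis for labelling chosen variables.
#' @return a `selection_result` (extra fields: `subsets`, the per-run retained
#'   sets; `min_iteration`, the strict RMSECV argmin).
#' @export
cars_select <- function(X, y, n_runs = 100, max_lv = 10, cv_folds = 10,
                        mc_fraction = 0.8, seed = 1,
                        tie_rule = c("one_se", "strict"), freq = NULL) {
  tie_rule <- match.arg(tie_rule)
  X <- as_spectral_matrix(X)
  check_finite_or_abort(X, "cars_select")
  n <- nrow(X); p <- ncol(X)
  if (p < 3) abort_config("CARS needs at least 3 variables.")
  if (n_runs < 2) abort_config("`n_runs` must be at least 2.")
  if (mc_fraction <= 0 || mc_fraction >= 1) abort_config("`mc_fraction` must be in (0, 1).")

  fold_id <- make_folds(n, cv_folds, derive_seed(seed, 101))
  inner_folds <- 5L
  retained <- seq_len(p)
  rmsecv_trace <- rep(NA_real_, n_runs)
  se_trace <- rep(NA_real_, n_runs)
  n_vars_trace <- rep(NA_integer_, n_runs)
  subsets <- vector("list", n_runs)
  n_mc <- max(2L, round(mc_fraction * n))

  withr::with_seed(derive_seed(seed, 102), {
    for (i in seq_len(n_runs)) {
      rows <- sample(n, n_mc)
      Xi <- X[rows, retained, drop = FALSE]
      lv_cap <- min(max_lv, length(retained), n_mc - 2L)
      inner_id <- rep_len(seq_len(inner_folds), n_mc)
      lv <- pls_cv(Xi, y[rows], lv_cap, inner_id)$best_lv
      fit <- pls1_fit(Xi, y[rows], lv)
      b <- abs(fit$B[, fit$ncomp])
      if (sum(b) <= 0) b <- rep(1, length(b))
      w <- b / sum(b)

      # weights in the full variable space; unfitted variables carry zero
      w_full <- numeric(p)
      w_full[retained] <- w
      keep_n <- cars_keep_n(i, p, n_runs)
      if (keep_n < 2) break
      # enforced elimination: zero all but the top keep_n weights
      cut <- sort(w_full, decreasing = TRUE)[keep_n]
      w_full[w_full < cut] <- 0
      if (sum(w_full > 0) > keep_n) {           # ties at the cut: lowest index first
        tied <- which(w_full == cut)
        drop <- tied[order(tied)][-seq_len(keep_n - sum(w_full > cut))]
        w_full[drop] <- 0
      }
      # adaptive reweighted sampling: p weighted draws with replacement, so
      # the survivor count tracks the enforced (EDF) count while low-weight
      # variables can still drop out
      samp <- sample.int(p, p, replace = TRUE, prob = w_full)
      retained_new <- sort(unique(samp))
      if (length(retained_new) < 2) break
      retained <- retained_new

      score <- pls_cv(X[, retained, drop = FALSE], y,
                      min(max_lv, length(retained), n - 2L), fold_id)
      rmsecv_trace[i] <- score$min
      n_vars_trace[i] <- length(retained)
      subsets[[i]] <- retained
      se_trace[i] <- stats::sd((y - score$predictions[, score$best_lv])^2) /
        (2 * score$min * sqrt(n))
    }
  })
  done <- which(!is.na(rmsecv_trace))
  if (length(done) == 0) abort_config("CARS terminated before completing a run.")
  rmse <- rmsecv_trace[done]
  min_it <- which.min(rmse)
  best_it <- min_it
  if (tie_rule == "one_se") {
    ok <- which(rmse <= rmse[min_it] + se_trace[done][min_it])
    best_it <- ok[order(n_vars_trace[done][ok], rmse[ok], ok)][1]
  }
  new_selection_result("CARS", subsets[[done[best_it]]], freq,
                       rmse, n_vars_trace[done],
                       best_iteration = best_it,
                       seed = seed, subsets = subsets[done],
                       min_iteration = min_it, tie_rule = tie_rule)
}

# sequential fold assignment: SPA is fully deterministic
spa_fold_id <- function(n, folds) rep_len(seq_len(folds), n)

ols_cv_rmse <- function(X, y, fold_id) {
  n <- length(y)
  pred <- numeric(n)
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    fit <- stats::lm.fit(cbind(1, X[!te, , drop = FALSE]), y[!te])
    cf <- fit$coefficients
    if (anyNA(cf)) return(Inf)
    pred[te] <- drop(cbind(1, X[te, , drop = FALSE]) %*% cf)
  }
  sqrt(mean((y - pred)^2))
}

#' Successive projections algorithm (SPA)
#'
#' For every starting variable a chain is grown by repeatedly adding the
#' variable with the largest projection onto the orthogonal complement of the
#' span of the chain so far (which keeps collinearity minimal); every
#' (start, k) candidate subset with `k_min <= k <= k_max` is then scored by
#' the cross-validated RMSE of an ordinary least-squares fit, and the minimum
#' wins. Ties (within 1e-10) go to fewer variables, then to the earlier
#' start. Fully deterministic: fold assignment is sequential.
#'
#' @param X calibration spectra.
#' @param y response.
#' @param k_min,k_max subset-size range (`k_max <= min(n - 1, p)`).
#' @param cv_folds folds for the OLS scoring.
#' @param freq optional frequency axis.
#' @return a `selection_result`.
#' @export
spa_select <- function(X, y, k_min = 1, k_max = 10, cv_folds = 10, freq = NULL) {
  X <- as_spectral_matrix(X)
  check_finite_or_abort(X, "spa_select")
  n <- nrow(X); p <- ncol(X)
  if (k_max > min(n - 1, p)) abort_config("`k_max` must not exceed min(n - 1, p).")
  if (k_min < 1 || k_min > k_max) abort_config("need 1 <= k_min <= k_max.")
  fold_id <- spa_fold_id(n, min(cv_folds, n))
  Xc <- sweep(X, 2, colMeans(X))
  norm0 <- max(colSums(Xc^2))

  chains <- vector("list", p)
  for (s in seq_len(p)) {
    chain <- s
    R <- Xc
    v <- R[, s]
    while (length(chain) < k_max) {
      vv <- sum(v^2)
      if (vv < 1e-12 * norm0) break                  # rank collapse
      R <- R - v %*% (crossprod(v, R) / vv)
      norms <- colSums(R^2)
      norms[chain] <- -Inf
      if (max(norms) < 1e-12 * norm0) break
      nxt <- which.max(norms)
      chain <- c(chain, nxt)
      v <- R[, nxt]
    }
    chains[[s]] <- chain
  }

  best <- list(err = Inf, k = Inf, start = Inf, subset = NULL)
  best_by_k <- rep(Inf, k_max)
  for (s in seq_len(p)) {
    chain <- chains[[s]]
    for (k in seq(k_min, min(k_max, length(chain)))) {
      err <- ols_cv_rmse(X[, chain[seq_len(k)], drop = FALSE], y, fold_id)
      if (err < best_by_k[k]) best_by_k[k] <- err
      better <- err < best$err - 1e-10 ||
        (err < best$err + 1e-10 && (k < best$k || (k == best$k && s < best$start)))
      if (better) best <- list(err = err, k = k, start = s,
                               subset = chain[seq_len(k)])
    }
  }
  ks <- seq(k_min, k_max)
  trace <- best_by_k[ks]
  new_selection_result("SPA", best$subset, freq,
                       rmsecv_trace = trace, n_vars_trace = ks,
                       best_iteration = which.min(trace), seed = NA_integer_,
                       start = best$start)
}

#' Genetic-algorithm frequency selection
#'
#' Binary-chromosome GA: fitness is the negative k-fold RMSECV of a PLS model
#' on the encoded variables, with tournament selection, single-point
#' crossover, bit-flip mutation and elitism of one. After the final
#' generation each variable's selection frequency across the population is
#' computed and variables with frequency inside `[freq_lower, freq_upper]`
#' are retained (the two-threshold retention rule); if that window is empty
#' the best chromosome's variables are used and the fallback is flagged.
#'
#' @param X calibration spectra.
#' @param y response.
#' @param pop_size even population size >= 4.
#' @param n_generations generations to evolve.
#' @param p_crossover,p_mutation crossover probability per pair and mutation
#'   probability per bit.
#' @param freq_lower,freq_upper retention window on the final selection
#'   frequency.
#' @param max_lv,cv_folds PLS fitness parameters.
#' @param p_init expected fraction of bits set in the initial population.
#' @param seed integer seed.
#' @param freq optional frequency axis.
#' @return a `selection_result` (extra fields: `fallback`, `final_frequency`).
#' @export
ga_select <- function(X, y, pop_size = 30, n_generations = 40,
                      p_crossover = 0.8, p_mutation = 0.01,
                      freq_lower = 0.3, freq_upper = 1.0,
                      max_lv = 10, cv_folds = 10, p_init = 0.3,
                      seed = 1, freq = NULL) {
  X <- as_spectral_matrix(X)
  check_finite_or_abort(X, "ga_select")
  n <- nrow(X); p <- ncol(X)
  if (pop_size < 4 || pop_size %% 2 != 0) abort_config("`pop_size` must be even and >= 4.")
  fold_id <- make_folds(n, cv_folds, derive_seed(seed, 201))

  fitness_of <- function(bits) {
    vars <- which(bits)
    if (length(vars) < 1) return(-Inf)
    -pls_cv(X[, vars, drop = FALSE], y,
            min(max_lv, length(vars), n - 2L), fold_id)$min
  }

  withr::with_seed(derive_seed(seed, 202), {
    pop <- matrix(stats::rbinom(pop_size * p, 1, p_init) == 1, pop_size, p)
    for (i in seq_len(pop_size)) {
      if (sum(pop[i, ]) < 2) pop[i, sample(p, 2)] <- TRUE
    }
    fit <- apply(pop, 1, fitness_of)
    best_trace <- numeric(n_generations)
    nvar_trace <- numeric(n_generations)
    for (g in seq_len(n_generations)) {
      elite <- pop[which.max(fit), ]
      newpop <- matrix(FALSE, pop_size, p)
      tournament <- function() {
        c2 <- sample(pop_size, 2)
        c2[which.max(fit[c2])]
      }
      for (k in seq_len(pop_size / 2)) {
        a <- pop[tournament(), ]
        b <- pop[tournament(), ]
        if (stats::runif(1) < p_crossover) {
          cut <- sample(p - 1, 1)
          tmp <- a
          a <- c(a[1:cut], b[(cut + 1):p])
          b <- c(b[1:cut], tmp[(cut + 1):p])
        }
        newpop[2 * k - 1, ] <- a
        newpop[2 * k, ] <- b
      }
      if (p_mutation > 0) {
        flips <- matrix(stats::runif(pop_size * p) < p_mutation, pop_size, p)
        newpop <- xor(newpop, flips)
      }
      for (i in seq_len(pop_size)) {
        if (sum(newpop[i, ]) < 2) newpop[i, sample(p, 2)] <- TRUE
      }
      newpop[1, ] <- elite
      pop <- newpop
      fit <- apply(pop, 1, fitness_of)
      best_trace[g] <- -max(fit)
      nvar_trace[g] <- mean(rowSums(pop))
    }
    final_freq <- colMeans(pop)
    retained <- which(final_freq >= freq_lower & final_freq <= freq_upper &
                        final_freq > 0)
    fallback <- length(retained) == 0
    if (fallback) {
      rlang::warn("GA retention window is empty; falling back to the best chromosome's variables.")
      retained <- which(pop[which.max(fit), ])
    }
  })
  new_selection_result("GA", retained, freq,
                       rmsecv_trace = best_trace, n_vars_trace = nvar_trace,
                       best_iteration = which.min(best_trace), seed = seed,
                       fallback = fallback, final_frequency = final_freq)
}

#' Bootstrapping soft shrinkage (BOSS)
#'
#' Weighted bootstrap sampling of the variable space with soft shrinkage of
#' the sampling weights: each iteration draws `n_bootstrap_models` variable
#' subsets (sampling p variables with replacement with the current weights,
#' then deduplicating), fits a PLS model to each (latent variables by the
#' shared fold assignment), ranks the sub-models by RMSECV, and replaces the
#' weights with the normalised sum of absolute regression coefficients over
#' the best 10% of sub-models -- no variable is ever forcibly eliminated,
#' weights only shrink. Iteration stops at `n_iterations` or once the number
#' of sampleable (positive-weight) variables has stabilised (relative change
#' below `tol` over `patience` consecutive iterations). The sub-model with
#' the global minimum RMSECV is returned.
#'
#' @param X calibration spectra (>= 3 variables).
#' @param y response.
#' @param max_lv largest latent-variable count (default 20).
#' @param n_iterations outer-iteration cap (default 2000; the stabilisation
#'   rule normally stops far earlier).
#' @param n_bootstrap_models sub-models per iteration (default 100).
#' @param cv_folds folds for sub-model RMSECV.
#' @param tol,patience stabilisation rule parameters.
#' @param seed integer seed.
#' @param freq optional frequency axis.
#' @return a `selection_result` (extra field: `weights`, the final sampling
#'   weights, summing to 1).
#' @export
boss_select <- function(X, y, max_lv = 20, n_iterations = 2000,
                        n_bootstrap_models = 100, cv_folds = 10,
                        tol = 1e-3, patience = 10, seed = 1, freq = NULL) {
  X <- as_spectral_matrix(X)
  check_finite_or_abort(X, "boss_select")
  n <- nrow(X); p <- ncol(X)
  if (p < 3) abort_config("BOSS needs at least 3 variables.")
  fold_id <- make_folds(n, cv_folds, derive_seed(seed, 301))

  w <- rep(1 / p, p)
  best <- list(err = Inf, subset = NULL)
  rmsecv_trace <- numeric(0)
  n_vars_trace <- integer(0)
  size_hist <- numeric(0)

  withr::with_seed(derive_seed(seed, 302), {
    for (it in seq_len(n_iterations)) {
      if (sum(w > 0) < 2) {
        rlang::abort(sprintf("BOSS weights collapsed to fewer than 2 variables at iteration %d.", it),
                     class = "thzash_boss_collapse")
      }
      coef_sum <- numeric(p)
      errs <- numeric(n_bootstrap_models)
      subs <- vector("list", n_bootstrap_models)
      coefs <- vector("list", n_bootstrap_models)
      for (m in seq_len(n_bootstrap_models)) {
        vars <- sort(unique(sample.int(p, p, replace = TRUE, prob = w)))
        if (length(vars) < 2) vars <- sort(unique(c(vars, sample.int(p, 2))))
        sc <- pls_cv(X[, vars, drop = FALSE], y,
                     min(max_lv, length(vars), n - 2L), fold_id)
        fitm <- pls1_fit(X[, vars, drop = FALSE], y, sc$best_lv)
        errs[m] <- sc$min
        subs[[m]] <- vars
        coefs[[m]] <- abs(fitm$B[, fitm$ncomp])
      }
      ord <- order(errs)
      top <- ord[seq_len(max(1L, ceiling(0.1 * n_bootstrap_models)))]
      for (m in top) coef_sum[subs[[m]]] <- coef_sum[subs[[m]]] + coefs[[m]]
      if (sum(coef_sum) <= 0) {
        rlang::abort(sprintf("BOSS weight update vanished at iteration %d.", it),
                     class = "thzash_boss_collapse")
      }
      w <- coef_sum / sum(coef_sum)

      it_best <- which.min(errs)
      rmsecv_trace <- c(rmsecv_trace, errs[it_best])
      n_vars_trace <- c(n_vars_trace, sum(w > 0))
      if (errs[it_best] < best$err) {
        best <- list(err = errs[it_best], subset = subs[[it_best]])
      }
      size_hist <- c(size_hist, sum(w > 0))
      if (length(size_hist) > patience) {
        recent <- tail(size_hist, patience + 1)
        rel <- abs(diff(recent)) / pmax(recent[-length(recent)], 1)
        if (all(rel < tol)) break
      }
    }
  })
  new_selection_result("BOSS", best$subset, freq,
                       rmsecv_trace = rmsecv_trace, n_vars_trace = n_vars_trace,
                       best_iteration = which.min(rmsecv_trace), seed = seed,
                       weights = w)
}
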