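# Stochastic wavelength selection for one data block: VCPA (binary matrix
# sampling + model population analysis + exponentially decreasing pool),
# IRIV (paired with/without fitness comparison per variable, iterated, plus
# backward elimination), and the hybrid mVCPA-IRIV. Fitness is the
# cross-validated misclassification rate of a PLS-DA evaluator.

#' Fitness evaluator settings for the selectors
#'
#' @param folds stratified CV folds (default 5).
#' @param max_comp cap on PLS-DA components; the effective cap is
#'   `min(max_comp, n_vars, n - 1)` and the count is chosen by CV.
#' @param seed integer seed controlling fold assignment and selector draws.
#' @return An object of class `fitness_spec`.
#' @export
fitness_spec <- function(folds = 5, max_comp = 10, seed = 1L) {
  stopifnot(folds >= 2, max_comp >= 1)
  structure(list(folds = as.integer(folds), max_comp = as.integer(max_comp),
                 seed = as.integer(seed)), class = "fitness_spec")
}

# internal: deterministic stratified fold assignment
stratified_folds <- function(y, k, seed) {
  y <- as.factor(y)
  fold <- integer(length(y))
  set.seed(seed)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated PLS-DA misclassification rate of a column subset
#'
#' Stratified k-fold CV error of a PLS-DA classifier restricted to the given
#' columns, with the component count chosen by CV up to the cap.
#' Deterministic given the spec's seed.
#'
#' @param X samples x columns matrix.
#' @param y class labels (factor or coercible).
#' @param subset column indices (nonempty).
#' @param spec a [fitness_spec].
#' @param folds optional precomputed fold assignment (recycled across many
#'   calls inside a selector run).
#' @return Misclassification rate in `[0, 1]`.
#' @export
cv_fitness <- function(X, y, subset = seq_len(ncol(X)), spec = fitness_spec(),
                       folds = NULL) {
  stopifnot(length(subset) >= 1)
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("need at least 2 classes")
  if (is.null(folds)) folds <- stratified_folds(y, spec$folds, spec$seed)
  Xs <- X[, subset, drop = FALSE]
  cap <- min(spec$max_comp, ncol(Xs), nrow(Xs) - 1L)
  cpp_cv_plsda(Xs, as.integer(y), as.integer(folds), as.integer(cap))
}

# internal: fitness of many column subsets in one compiled call
batch_fitness <- function(X, y, subsets, spec, folds) {
  y <- as.factor(y)
  as.vector(cpp_cv_plsda_batch(X, as.integer(y), as.integer(folds),
                               as.integer(spec$max_comp), subsets))
}

# internal: K x p binary inclusion matrix, every row with >= min_inc ones
binary_inclusion <- function(K, p, prob = 0.5, min_inc = 2L) {
  A <- matrix(runif(K * p) < prob, K, p)
  short <- which(rowSums(A) < min_inc)
  for (r in short) {
    add <- sample.int(p, min_inc)
    A[r, add] <- TRUE
  }
  A
}

new_feature_selection <- function(algorithm, indices, fitness, trace, seed,
                                  params, flagged = FALSE) {
  structure(list(algorithm = algorithm,
                 indices = sort(unique(as.integer(indices))),
                 fitness = fitness, trace = trace, seed = seed,
                 params = params, flagged = flagged),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat(sprintf("<feature_selection> %s: %d variables, CV error %.4f\n",
              x$algorithm, length(x$indices), x$fitness))
  invisible(x)
}

# internal: VCPA's exponentially decreasing pool-size schedule, ending at L
edf_schedule <- function(p, L, iterations) {
  i <- seq_len(iterations)
  w <- round(p * exp(-i * log(p / L) / iterations))
  w <- pmax(pmin(w, p), L)
  w[iterations] <- L
  cummin(w)
}

# internal: one frequency-ranking EDF/BMS phase, shrinking pool to target L.
# Returns list(pool, trace); RNG state is consumed sequentially.
vcpa_edf_phase <- function(X, y, spec, folds, pool, L, edf_iterations,
                           bms_runs, top_fraction) {
  p0 <- length(pool)
  sched <- edf_schedule(p0, L, edf_iterations)
  trace <- numeric(0)
  for (it in seq_len(edf_iterations)) {
    pc <- length(pool)
    if (pc <= L) break
    A <- binary_inclusion(bms_runs, pc)
    subs <- lapply(seq_len(bms_runs), function(r) pool[A[r, ]])
    fit <- batch_fitness(X, y, subs, spec, folds)
    n_top <- max(1L, round(top_fraction * bms_runs))
    best <- order(fit)[seq_len(n_top)]
    freq <- colSums(A[best, , drop = FALSE])
    trace <- c(trace, min(fit))
    keep <- order(-freq, seq_len(pc))[seq_len(min(sched[it], pc))]
    pool <- pool[sort(keep)]
    if (length(pool) < 2) break
  }
  list(pool = pool, trace = trace)
}

# internal: exhaustive search over all nonempty subsets of a small pool
exhaustive_best_subset <- function(X, y, spec, folds, pool) {
  L <- length(pool)
  stopifnot(L <= 20)
  bit <- 2^(0:(L - 1))
  subs <- lapply(seq_len(2^L - 1), function(s) pool[bitwAnd(s, bit) > 0])
  fit <- batch_fitness(X, y, subs, spec, folds)
  sizes <- lengths(subs)
  best <- order(fit, sizes)[1]   # ties toward fewer variables
  list(indices = subs[[best]], fitness = fit[best])
}

#' Variable combination population analysis (VCPA)
#'
#' Iteratively samples `bms_runs` random variable combinations from the
#' current pool (binary matrix sampling), scores each by CV fitness, computes
#' each variable's inclusion frequency among the best `top_fraction` of
#' combinations, and shrinks the pool along an exponentially decreasing
#' size schedule, keeping the highest-frequency variables. Once the pool is
#' down to `final_pool` variables, every nonempty subset is evaluated and the
#' minimum-fitness subset is returned (ties broken toward fewer variables).
#'
#' @param X samples x columns matrix (`ncol(X) >= final_pool`).
#' @param y class labels.
#' @param spec a [fitness_spec].
#' @param edf_iterations length of the pool-shrinking schedule (default 50;
#'   reduced-budget runs use 15).
#' @param bms_runs combinations sampled per iteration (default 500; reduced
#'   budget 100).
#' @param top_fraction fraction of best combinations used for frequencies.
#' @param final_pool pool size for exhaustive evaluation (default 14).
#' @return A `feature_selection`.
#' @export
vcpa <- function(X, y, spec = fitness_spec(), edf_iterations = 50,
                 bms_runs = 500, top_fraction = 0.1, final_pool = 14) {
  p <- ncol(X)
  stopifnot(p >= final_pool)
  folds <- stratified_folds(y, spec$folds, spec$seed)
  set.seed(spec$seed)
  phase <- vcpa_edf_phase(X, y, spec, folds, seq_len(p), final_pool,
                          edf_iterations, bms_runs, top_fraction)
  ex <- exhaustive_best_subset(X, y, spec, folds, phase$pool)
  new_feature_selection("vcpa", ex$indices, ex$fitness,
                        trace = c(phase$trace, ex$fitness), seed = spec$seed,
                        params = list(edf_iterations = edf_iterations,
                                      bms_runs = bms_runs,
                                      top_fraction = top_fraction,
                                      final_pool = final_pool))
}

# internal: backward elimination — drop the variable whose removal most
# improves fitness, while a strict improvement exists
backward_eliminate <- function(X, y, spec, folds, subset) {
  cur <- subset
  fit_cur <- cv_fitness(X, y, cur, spec, folds)
  trace <- fit_cur
  while (length(cur) > 1) {
    fits <- batch_fitness(X, y,
                          lapply(seq_along(cur), function(i) cur[-i]),
                          spec, folds)
    i_best <- which.min(fits)
    if (fits[i_best] < fit_cur) {
      cur <- cur[-i_best]
      fit_cur <- fits[i_best]
      trace <- c(trace, fit_cur)
    } else break
  }
  list(indices = cur, fitness = fit_cur, trace = trace)
}

#' Iteratively retains informative variables (IRIV)
#'
#' Each round draws a random binary inclusion matrix, scores every row's
#' subset, and for each variable compares the fitness of the rows including
#' it against the paired pseudo-population with that variable flipped out.
#' Variables whose inclusion lowers the error (strongly informative when the
#' rank-sum test is significant at `alpha`, weakly informative otherwise) are
#' retained; uninformative and interfering variables are dropped. Rounds
#' repeat until nothing is dropped or `max_rounds`; a backward-elimination
#' sweep then removes variables while removal strictly improves fitness.
#'
#' @param X samples x columns matrix (>= 2 columns).
#' @param y class labels.
#' @param spec a [fitness_spec].
#' @param rows inclusion-matrix rows per round (default 500; reduced 100).
#' @param inclusion_prob per-variable inclusion probability.
#' @param alpha rank-sum significance level.
#' @param max_rounds cap on dropping rounds.
#' @return A `feature_selection`; `flagged` is `TRUE` when every variable was
#'   dropped and the best single variable by marginal fitness is returned.
#' @export
iriv <- function(X, y, spec = fitness_spec(), rows = 500,
                 inclusion_prob = 0.5, alpha = 0.05, max_rounds = 20) {
  p <- ncol(X)
  stopifnot(p >= 2)
  folds <- stratified_folds(y, spec$folds, spec$seed)
  set.seed(spec$seed)
  surviving <- seq_len(p)
  trace <- numeric(0)
  categories <- list()
  for (round in seq_len(max_rounds)) {
    pc <- length(surviving)
    if (pc < 2) break
    # fresh fold assignment each round: keeps spurious variables from
    # persisting by chance agreement with a single CV split
    folds <- stratified_folds(y, spec$folds, spec$seed + round)
    A <- binary_inclusion(rows, pc, inclusion_prob)
    f0 <- batch_fitness(X, y,
                        lapply(seq_len(rows), function(r) surviving[A[r, ]]),
                        spec, folds)
    keep <- logical(pc)
    category <- character(pc)
    for (j in seq_len(pc)) {
      flip_subs <- lapply(seq_len(rows), function(r) {
        sub <- A[r, ]
        sub[j] <- !sub[j]
        surviving[sub]
      })
      empty <- lengths(flip_subs) == 0
      fflip <- numeric(rows)
      fflip[empty] <- 1
      if (any(!empty))
        fflip[!empty] <- batch_fitness(X, y, flip_subs[!empty], spec, folds)
      with_j <- ifelse(A[, j], f0, fflip)
      without_j <- ifelse(A[, j], fflip, f0)
      dmean <- mean(with_j) - mean(without_j)
      pval <- tryCatch(
        wilcox.test(with_j, without_j, exact = FALSE)$p.value,
        error = function(e) 1)
      if (is.na(pval)) pval <- 1
      # inclusion lowers CV error -> informative (kept); the rank-sum test
      # splits strong vs weak / uninformative vs interfering
      keep[j] <- dmean < 0
      category[j] <- if (dmean < 0) {
        if (pval < alpha) "strong" else "weak"
      } else {
        if (pval < alpha) "interfering" else "uninformative"
      }
    }
    trace <- c(trace, min(f0))
    categories[[round]] <- table(factor(category, levels = c(
      "strong", "weak", "uninformative", "interfering")))
    if (all(keep)) break
    surviving <- surviving[keep]
    if (length(surviving) == 0) {
      marg <- batch_fitness(X, y, as.list(seq_len(p)), spec, folds)
      return(new_feature_selection("iriv", which.min(marg), min(marg),
                                   trace, spec$seed,
                                   params = list(rows = rows,
                                                 inclusion_prob = inclusion_prob,
                                                 alpha = alpha,
                                                 max_rounds = max_rounds),
                                   flagged = TRUE))
    }
    if (length(surviving) == 1) break
  }
  be <- backward_eliminate(X, y, spec, folds, surviving)
  out <- new_feature_selection("iriv", be$indices, be$fitness,
                        trace = c(trace, be$trace), seed = spec$seed,
                        params = list(rows = rows,
                                      inclusion_prob = inclusion_prob,
                                      alpha = alpha, max_rounds = max_rounds))
  out$round_categories <- categories
  out
}

#' Hybrid mVCPA-IRIV selection
#'
#' Runs VCPA's frequency-ranking EDF/BMS phase only, shrinking the pool to
#' `intermediate_pool` variables, then runs [iriv()] on that pool and maps
#' the result back to the original column indices. When the block already
#' has at most `intermediate_pool` columns the VCPA phase is skipped and the
#' call reduces to [iriv()] exactly.
#'
#' @param X samples x columns matrix.
#' @param y class labels.
#' @param spec a [fitness_spec].
#' @param intermediate_pool pool size handed to IRIV (default 50).
#' @param edf_iterations,bms_runs,top_fraction VCPA-phase settings.
#' @param rows,inclusion_prob,alpha,max_rounds IRIV settings.
#' @return A `feature_selection` with algorithm `"mvcpa_iriv"`.
#' @export
mvcpa_iriv <- function(X, y, spec = fitness_spec(), intermediate_pool = 50,
                       edf_iterations = 50, bms_runs = 500,
                       top_fraction = 0.1, rows = 500,
                       inclusion_prob = 0.5, alpha = 0.05, max_rounds = 20) {
  p <- ncol(X)
  if (p <= intermediate_pool) {
    sel <- iriv(X, y, spec, rows, inclusion_prob, alpha, max_rounds)
    sel$algorithm <- "mvcpa_iriv"
    return(sel)
  }
  folds <- stratified_folds(y, spec$folds, spec$seed)
  set.seed(spec$seed)
  phase <- vcpa_edf_phase(X, y, spec, folds, seq_len(p), intermediate_pool,
                          edf_iterations, bms_runs, top_fraction)
  sub <- iriv(X[, phase$pool, drop = FALSE], y, spec, rows,
              inclusion_prob, alpha, max_rounds)
  new_feature_selection("mvcpa_iriv", phase$pool[sub$indices], sub$fitness,
                        trace = c(phase$trace, sub$trace), seed = spec$seed,
                        params = list(intermediate_pool = intermediate_pool,
                                      vcpa = list(edf_iterations = edf_iterations,
                                                  bms_runs = bms_runs,
                                                  top_fraction = top_fraction),
                                      iriv = sub$params),
                        flagged = sub$flagged)
}
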