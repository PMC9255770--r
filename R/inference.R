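# Model-variant lattice and Monte-Carlo cross-validated fitting. All fits
# pool trials across participants and operate on the myopic-frame choice
# coding (+1 = upper bound = myopic-satisfying choice).

#' Extract the diffusion-model fitting table from preprocessed data
#'
#' Keeps identified-route IA trials and returns the columns the likelihood
#' consumes: advantage magnitudes in the myopic frame, the goal side
#' indicator, condition, the +1/-1 choice and the standardized RT.
#'
#' @param data kept-trial data frame from [preprocess_observations()], or
#'   any frame with `participant_id`, `condition`, `myopic_adv`,
#'   `future_adv`, `goal_sign`, `chose_myopic` and `rt_std` columns.
#' @return fitting data frame with columns `participant_id`, `condition`,
#'   `mAdv`, `fAdv`, `goal_sign`, `choice`, `rt`.
#' @export
make_ddm_data <- function(data) {
  ia <- !is.na(data$chose_myopic)
  d <- data[ia, ]
  data.frame(participant_id = d$participant_id,
             condition = ifelse(d$condition == "subgoal", "subgoal", "base"),
             mAdv = abs(d$myopic_adv), fAdv = abs(d$future_adv),
             goal_sign = d$goal_sign, choice = as.integer(d$chose_myopic),
             rt = d$rt_std)
}

#' Specify a constraint-weighting model variant
#'
#' @param name variant label.
#' @param equal_weights tie the two advantage weights (`md = fd`).
#' @param free_z free mean starting point (otherwise fixed at 0).
#' @param variability free inter-trial variabilities `sz`, `sd`
#'   (otherwise fixed at 0).
#' @param subgoal_mode how the subgoal condition modifies the drift:
#'   "none" (shared parameters, no goal weight), "gd_only" (adds the goal
#'   weight `gd`), "gd_additive" (goal weight plus a shared additive change
#'   to both advantage weights), "gd_independent" (goal weight plus freely
#'   refit advantage weights), "gd_proportional" (goal weight plus a shared
#'   proportional multiplier `p`).
#' @param separate_t0 free separate non-decision time for subgoal trials.
#' @return `variant_spec` object with the free-parameter bookkeeping.
#' @export
variant_spec <- function(name, equal_weights = FALSE, free_z = FALSE,
                         variability = TRUE,
                         subgoal_mode = c("none", "gd_only", "gd_additive",
                                          "gd_independent", "gd_proportional"),
                         separate_t0 = FALSE) {
  subgoal_mode <- match.arg(subgoal_mode)
  pars <- c("t0", "a")
  lower <- c(t0 = 0, a = 0.1)
  upper <- c(t0 = 0.45, a = 5)
  if (equal_weights) {
    pars <- c(pars, "md")
    lower <- c(lower, md = 0); upper <- c(upper, md = 5)
  } else {
    pars <- c(pars, "md", "fd")
    lower <- c(lower, md = 0, fd = 0); upper <- c(upper, md = 5, fd = 5)
  }
  if (free_z) { pars <- c(pars, "z"); lower <- c(lower, z = -2); upper <- c(upper, z = 2) }
  if (variability) {
    pars <- c(pars, "sz", "sd")
    lower <- c(lower, sz = 0, sd = 0); upper <- c(upper, sz = 4.9, sd = 3)
  }
  if (subgoal_mode != "none") {
    pars <- c(pars, "gd"); lower <- c(lower, gd = -5); upper <- c(upper, gd = 5)
  }
  if (subgoal_mode == "gd_additive") {
    pars <- c(pars, "dw"); lower <- c(lower, dw = -4.9); upper <- c(upper, dw = 4.9)
  }
  if (subgoal_mode == "gd_independent") {
    pars <- c(pars, "md2", "fd2")
    lower <- c(lower, md2 = 0, fd2 = 0); upper <- c(upper, md2 = 5, fd2 = 5)
  }
  if (subgoal_mode == "gd_proportional") {
    pars <- c(pars, "p"); lower <- c(lower, p = 0.05); upper <- c(upper, p = 3)
  }
  if (separate_t0) {
    pars <- c(pars, "t0_sub"); lower <- c(lower, t0_sub = 0); upper <- c(upper, t0_sub = 0.45)
  }
  structure(list(name = name, equal_weights = equal_weights, free_z = free_z,
                 variability = variability, subgoal_mode = subgoal_mode,
                 separate_t0 = separate_t0, par_names = pars,
                 lower = lower[pars], upper = upper[pars],
                 free_parameter_count = length(pars)),
            class = "variant_spec")
}

#' The candidate model lattices
#'
#' For the simple task the lattice crosses equal versus different
#' advantage weights, fixed versus free starting bias, and absent versus
#' present inter-trial variabilities (eight variants). For the complex
#' task the lattice is built on the different-weights-with-variability
#' baseline and varies how the subgoal condition modifies the drift: no
#' change, an added goal weight, the goal weight with a shared additive,
#' independent, or shared proportional change to the advantage weights,
#' plus a separate-non-decision-time version of the proportional variant.
#'
#' @param experiment "exp1" or "exp2".
#' @return list of [variant_spec()] objects.
#' @export
make_variant_lattice <- function(experiment = c("exp1", "exp2")) {
  experiment <- match.arg(experiment)
  if (experiment == "exp1") {
    out <- list()
    for (vr in c(FALSE, TRUE))
      for (zf in c(FALSE, TRUE))
        for (ew in c(TRUE, FALSE)) {
          nm <- paste0(if (ew) "equal" else "diff", "_w",
                       if (zf) "_z" else "", if (vr) "_var" else "")
          out[[nm]] <- variant_spec(nm, equal_weights = ew, free_z = zf,
                                    variability = vr, subgoal_mode = "none")
        }
    out
  } else {
    modes <- c(baseline = "none", gd = "gd_only", gd_additive = "gd_additive",
               gd_independent = "gd_independent",
               gd_proportional = "gd_proportional")
    out <- lapply(seq_along(modes), function(i)
      variant_spec(names(modes)[i], subgoal_mode = modes[[i]]))
    names(out) <- names(modes)
    out$gd_proportional_t0 <- variant_spec("gd_proportional_t0",
                                           subgoal_mode = "gd_proportional",
                                           separate_t0 = TRUE)
    out
  }
}

# Map a named parameter vector of a variant onto per-trial drift and t0
# plus the shared scalars; returns NULL if the geometry constraint
# |z| + sz/2 < a is violated.
variant_unpack <- function(theta, variant, data) {
  g <- function(nm, default) if (nm %in% names(theta)) theta[[nm]] else default
  a <- theta[["a"]]
  z <- g("z", 0); sz <- g("sz", 0); sd <- g("sd", 0)
  if (abs(z) + sz / 2 >= a) return(NULL)
  md <- theta[["md"]]
  fd <- if (variant$equal_weights) md else theta[["fd"]]
  gd <- g("gd", 0)
  sub <- data$condition == "subgoal"
  md_s <- switch(variant$subgoal_mode,
                 none = md, gd_only = md,
                 gd_additive = md + theta[["dw"]],
                 gd_independent = theta[["md2"]],
                 gd_proportional = theta[["p"]] * md)
  fd_s <- switch(variant$subgoal_mode,
                 none = fd, gd_only = fd,
                 gd_additive = fd + theta[["dw"]],
                 gd_independent = theta[["fd2"]],
                 gd_proportional = theta[["p"]] * fd)
  if (md_s < 0 || fd_s < 0) return(NULL)
  drift <- ifelse(sub, md_s * data$mAdv - fd_s * data$fAdv + gd * data$goal_sign,
                  md * data$mAdv - fd * data$fAdv)
  t0 <- rep.int(theta[["t0"]], nrow(data))
  if (variant$separate_t0) t0[sub] <- theta[["t0_sub"]]
  list(drift = drift, t0 = t0, a = a, z = z, sz = sz, sd = sd)
}

variant_nll <- function(theta, variant, data, quad) {
  names(theta) <- variant$par_names
  up <- variant_unpack(theta, variant, data)
  if (is.null(up)) return(1e10)
  ddm_negloglik_cpp(as.numeric(data$rt), as.integer(data$choice),
                    as.numeric(up$drift), up$t0, up$a, up$z, up$sz, up$sd,
                    quad$ghx, quad$ghw, quad$glx, quad$glw, 1e-7, 1e-10)
}

random_start <- function(variant, data) {
  lo <- variant$lower; hi <- variant$upper
  th <- stats::runif(length(lo), lo, hi)
  names(th) <- variant$par_names
  # draw from plausible sub-ranges so most starts are in the likelihood's
  # informative region
  th[["t0"]] <- stats::runif(1, 0, min(0.45, max(0.05, min(data$rt) - 0.02)))
  th[["a"]] <- stats::runif(1, 0.4, 2.5)
  th[["md"]] <- stats::runif(1, 0.2, 3)
  if ("fd" %in% names(th)) th[["fd"]] <- stats::runif(1, 0.2, 3)
  if ("z" %in% names(th)) th[["z"]] <- stats::runif(1, -th[["a"]] / 2, th[["a"]] / 2)
  if ("sz" %in% names(th)) th[["sz"]] <- stats::runif(1, 0, th[["a"]] / 2)
  if ("sd" %in% names(th)) th[["sd"]] <- stats::runif(1, 0, 1.5)
  if ("gd" %in% names(th)) th[["gd"]] <- stats::runif(1, -1, 1)
  if ("dw" %in% names(th)) th[["dw"]] <- stats::runif(1, -1, 1)
  if ("md2" %in% names(th)) th[["md2"]] <- stats::runif(1, 0.2, 3)
  if ("fd2" %in% names(th)) th[["fd2"]] <- stats::runif(1, 0.2, 3)
  if ("p" %in% names(th)) th[["p"]] <- stats::runif(1, 0.3, 1.5)
  if ("t0_sub" %in% names(th)) th[["t0_sub"]] <- th[["t0"]]
  th
}

#' Fit one model variant by bounded multi-start optimization
#'
#' Minimizes the summed negative log-likelihood (sNLL) of the pooled
#' training trials with `nlminb` from random initial parameter values.
#' After the initial runs, runs are extended in batches of 5 (up to
#' `max_starts`) until the best sNLL is replicated within `replicate_tol`
#' by a second run, to guard against local minima.
#'
#' @param data fitting data frame from [make_ddm_data()].
#' @param variant a [variant_spec()].
#' @param n_starts initial number of random starts.
#' @param rng_seed integer seed for the random starts.
#' @param init optional named start vector tried in addition to the
#'   random starts (e.g. a warm start from a full-data fit).
#' @param max_starts cap on total runs.
#' @param replicate_tol sNLL replication tolerance for the extension rule.
#' @param quad quadrature nodes.
#' @param control `nlminb` control list.
#' @return list with `params` (named vector), `snll`, `runs_used`,
#'   `convergence`, and `variant`.
#' @export
fit_variant <- function(data, variant, n_starts = 10L, rng_seed = NULL,
                        init = NULL, max_starts = 30L, replicate_tol = 0.1,
                        quad = ddm_quadrature(),
                        control = list(eval.max = 500, iter.max = 300)) {
  if (nrow(data) == 0L) stop("fit-failure: no trials to fit", call. = FALSE)
  run_one <- function(start) {
    fit <- tryCatch(
      stats::nlminb(start, variant_nll, variant = variant, data = data,
                    quad = quad, lower = variant$lower,
                    upper = variant$upper, control = control),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(par = stats::setNames(fit$par, variant$par_names),
         snll = fit$objective, conv = fit$convergence)
  }
  do_fit <- function() {
    runs <- list()
    if (!is.null(init)) {
      st <- init[variant$par_names]
      names(st) <- variant$par_names
      r <- run_one(st)
      if (!is.null(r)) runs[[length(runs) + 1L]] <- r
    }
    add_runs <- function(k) {
      for (i in seq_len(k)) {
        r <- run_one(random_start(variant, data))
        if (!is.null(r)) runs[[length(runs) + 1L]] <<- r
      }
    }
    add_runs(n_starts)
    repeat {
      if (length(runs) == 0L) stop("fit-failure: no run converged", call. = FALSE)
      snlls <- vapply(runs, function(r) r$snll, numeric(1))
      best <- min(snlls)
      replicated <- sum(snlls <= best + replicate_tol) >= 2L
      if (replicated || length(runs) >= max_starts) break
      add_runs(min(5L, max_starts - length(runs)))
    }
    best_run <- runs[[which.min(vapply(runs, function(r) r$snll, numeric(1)))]]
    list(params = best_run$par, snll = best_run$snll,
         runs_used = length(runs), convergence = best_run$conv,
         variant = variant)
  }
  if (is.null(rng_seed)) do_fit() else withr::with_seed(rng_seed, do_fit())
}

#' Evaluate a variant's summed negative log-likelihood on data
#'
#' @param params named parameter vector (as returned by [fit_variant()]).
#' @inheritParams fit_variant
#' @return sNLL (numeric scalar).
#' @export
variant_snll <- function(params, variant, data, quad = ddm_quadrature()) {
  variant_nll(params[variant$par_names], variant, data, quad)
}

#' Random train/test participant splits for Monte-Carlo cross-validation
#'
#' @param participant_ids vector of participant identifiers.
#' @param n_folds number of independent random splits.
#' @param test_size participants held out per fold.
#' @param rng_seed integer seed.
#' @return list of `list(train, test)` id vectors, shared across variants.
#' @export
make_folds <- function(participant_ids, n_folds, test_size, rng_seed) {
  ids <- unique(participant_ids)
  if (test_size >= length(ids))
    stop("test_size must be smaller than the cohort", call. = FALSE)
  withr::with_seed(rng_seed, {
    lapply(seq_len(n_folds), function(i) {
      test <- sample(ids, test_size)
      list(train = setdiff(ids, test), test = test)
    })
  })
}

#' Monte-Carlo cross-validation of model variants
#'
#' For every fold and variant, fits the variant on the training
#' participants' pooled trials and evaluates the summed negative
#' log-likelihood on the held-out participants. All variants share the
#' same folds so fold-level variability is controlled. Failed fits are
#' recorded with `NA` and excluded pairwise downstream.
#'
#' @param data fitting data frame from [make_ddm_data()].
#' @param variants list of [variant_spec()] objects.
#' @param folds folds from [make_folds()].
#' @param n_starts,max_starts,control,quad passed to [fit_variant()].
#' @param rng_seed integer seed (fans out per fold x variant).
#' @param warm_start if TRUE, each variant is first fitted once on the
#'   full data (with `warm_n_starts` random starts) and every fold run
#'   adds that estimate as an extra start; with `n_starts = 0` the fold
#'   fits use the warm start alone.
#' @param warm_n_starts random starts for the full-data warm fits.
#' @return data frame with one row per fold x variant: `fold_id`,
#'   `variant`, `n_free`, `train_snll`, `test_snll`, `runs_used`, and a
#'   `params` list-column.
#' @export
cross_validate <- function(data, variants, folds, n_starts = 10L,
                           rng_seed = 1L, warm_start = FALSE,
                           warm_n_starts = max(n_starts, 5L),
                           max_starts = 30L, quad = ddm_quadrature(),
                           control = list(eval.max = 500, iter.max = 300)) {
  inits <- vector("list", length(variants))
  if (warm_start) {
    for (v in seq_along(variants))
      inits[[v]] <- tryCatch(
        fit_variant(data, variants[[v]], n_starts = warm_n_starts,
                    rng_seed = rng_seed * 1000L + v, max_starts = max_starts,
                    quad = quad, control = control)$params,
        error = function(e) NULL)
  }
  if (n_starts == 0L && !warm_start)
    stop("n_starts = 0 requires warm_start", call. = FALSE)
  rows <- list()
  for (f in seq_along(folds)) {
    train <- data[data$participant_id %in% folds[[f]]$train, ]
    test <- data[data$participant_id %in% folds[[f]]$test, ]
    for (v in seq_along(variants)) {
      variant <- variants[[v]]
      fit <- tryCatch(
        fit_variant(train, variant, n_starts = n_starts,
                    rng_seed = rng_seed + 7919L * f + 104729L * v,
                    init = inits[[v]], max_starts = max_starts, quad = quad,
                    control = control),
        error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        fold_id = f, variant = variant$name,
        n_free = variant$free_parameter_count,
        train_snll = if (is.null(fit)) NA_real_ else fit$snll,
        test_snll = if (is.null(fit)) NA_real_
                    else variant_snll(fit$params, variant, test, quad),
        runs_used = if (is.null(fit)) NA_integer_ else fit$runs_used)
      rows[[length(rows)]]$params <- if (is.null(fit)) list(NULL)
                                     else list(fit$params)
    }
  }
  do.call(rbind, rows)
}

#' Compare cross-validated variants and select a winner
#'
#' Held-out sNLL values are compared across variants with fold-blocked
#' paired tests (equivalent, in this balanced one-observation-per-cell
#' design, to contrasts under a fold-random-intercept mixed model),
#' Bonferroni-adjusted over variant pairs. The winner is the variant with
#' reliably lowest mean test sNLL, or the variant with fewest free
#' parameters among those statistically indistinguishable from the lowest.
#'
#' @param fold_table output of [cross_validate()].
#' @param alpha significance level for the adjusted pairwise tests.
#' @return list with `means` (per-variant mean test sNLL), `pairwise`
#'   (data frame of adjusted p-values), `winner`, `rationale`
#'   ("lower_sNLL" or "fewer_params_tie").
#' @export
compare_models <- function(fold_table, alpha = 0.05) {
  tab <- fold_table[!is.na(fold_table$test_snll), ]
  variants <- unique(tab$variant)
  if (length(variants) < 2L)
    stop("model comparison needs at least two variants", call. = FALSE)
  wide <- stats::reshape(tab[, c("fold_id", "variant", "test_snll")],
                         idvar = "fold_id", timevar = "variant",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^test_snll\\.", "", colnames(mat))
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  means <- colMeans(mat)
  nfree <- stats::setNames(tab$n_free[!duplicated(tab$variant)],
                           tab$variant[!duplicated(tab$variant)])
  pairs <- utils::combn(colnames(mat), 2L)
  paired_p <- function(x, y) {
    d <- x - y
    if (stats::sd(d) < 1e-12) return(if (abs(mean(d)) < 1e-9) 1 else 0)
    stats::t.test(d)$p.value
  }
  pr <- data.frame(a = pairs[1, ], b = pairs[2, ])
  pr$p_raw <- mapply(function(a, b) paired_p(mat[, a], mat[, b]), pr$a, pr$b)
  pr$p_adj <- pmin(1, pr$p_raw * nrow(pr))
  best <- names(means)[which.min(means)]
  indist <- vapply(colnames(mat), function(v) {
    if (v == best) return(TRUE)
    row <- pr[(pr$a == best & pr$b == v) | (pr$a == v & pr$b == best), ]
    row$p_adj[1] >= alpha
  }, logical(1))
  contenders <- colnames(mat)[indist]
  winner <- contenders[order(nfree[contenders], means[contenders])][1]
  rationale <- if (length(contenders) == 1L) "lower_sNLL" else "fewer_params_tie"
  list(means = means, n_free = nfree, pairwise = pr, winner = winner,
       rationale = rationale, n_folds = nrow(mat))
}
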