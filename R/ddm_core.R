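#' @useDynLib mazeddm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# cache for quadrature nodes so repeated likelihood calls share them
.quad_cache <- new.env(parent = emptyenv())

#' Quadrature nodes for inter-trial variability mixing
#'
#' Gaussian drift variability is integrated by Gauss-Hermite quadrature and
#' uniform starting-point variability by Gauss-Legendre quadrature. Node
#' counts default to 31 (Hermite) and 16 (Legendre), which reproduce
#' brute-force quadrature of the mixed density to well below the 1e-4
#' conservation tolerance used throughout.
#'
#' @param n_hermite number of Gauss-Hermite nodes.
#' @param n_legendre number of Gauss-Legendre nodes.
#' @return list with elements `ghx`, `ghw` (Hermite nodes/weights for weight
#'   function `exp(-x^2)`) and `glx`, `glw` (Legendre nodes/weights on
#'   `[-1, 1]`).
#' @export
ddm_quadrature <- function(n_hermite = 31L, n_legendre = 16L) {
  key <- paste0("q", n_hermite, "_", n_legendre)
  if (!is.null(.quad_cache[[key]])) return(.quad_cache[[key]])
  gh <- pracma::gaussHermite(n_hermite)
  gl <- pracma::gaussLegendre(n_legendre, -1, 1)
  q <- list(ghx = gh$x, ghw = gh$w, glx = gl$x, glw = gl$w)
  .quad_cache[[key]] <- q
  q
}

#' Construct a drift-diffusion parameter vector
#'
#' Parameters of the weighted-constraint diffusion process. The decision
#' variable starts at `z` (mean), drifts with mean rate set per trial by the
#' advantage weights, has unit diffusion coefficient, and terminates at
#' bounds `+a` (choice satisfying the myopic advantage) or `-a` (choice
#' satisfying the future advantage). All time-like quantities are in
#' standardized response-time units.
#'
#' @param t0 non-decision time (>= 0).
#' @param a bound magnitude (> 0); bounds sit at `+a` and `-a`.
#' @param md,fd drift weight per unit of myopic / future advantage.
#' @param z mean starting point (default 0).
#' @param sz full range of uniform starting-point variability (>= 0; must
#'   satisfy `abs(z) + sz/2 < a`).
#' @param sd standard deviation of trial-level Gaussian drift variability.
#' @param gd goal drift weight (subgoal condition only; default 0).
#' @param p proportional multiplier on `md` and `fd` in the subgoal
#'   condition (default 1).
#' @return object of class `ddm_params` (a named list).
#' @export
ddm_params <- function(t0, a, md, fd, z = 0, sz = 0, sd = 0, gd = 0, p = 1) {
  stopifnot(is.numeric(t0), is.numeric(a), is.numeric(md), is.numeric(fd))
  if (a <= 0) stop("bound magnitude `a` must be positive", call. = FALSE)
  if (t0 < 0) stop("non-decision time `t0` must be non-negative", call. = FALSE)
  if (sz < 0 || sd < 0) stop("`sz` and `sd` must be non-negative", call. = FALSE)
  if (abs(z) + sz / 2 >= a)
    stop("starting-point range must lie strictly inside the bounds: |z| + sz/2 < a",
         call. = FALSE)
  if (p <= 0) stop("proportional multiplier `p` must be positive", call. = FALSE)
  structure(list(t0 = t0, a = a, z = z, md = md, fd = fd, sz = sz, sd = sd,
                 gd = gd, p = p),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Drift-diffusion parameters (standardized RT units):\n")
  print(unlist(x))
  invisible(x)
}

#' Trial covariates for the drift rate
#'
#' @param mAdv,fAdv magnitudes of the myopic and future advantage in the
#'   myopic reference frame (positive integers for IA trials).
#' @param goal_sign +1 if the final goal lies on the side of the
#'   myopic-advantage-satisfying move, -1 on the opposite side, 0 for the
#'   base condition.
#' @param condition "base" or "subgoal".
#' @return a `trial_covariates` list.
#' @export
trial_covariates <- function(mAdv, fAdv, goal_sign = 0,
                             condition = c("base", "subgoal")) {
  condition <- match.arg(condition)
  if (condition == "base" && goal_sign != 0)
    stop("goal_sign must be 0 in the base condition", call. = FALSE)
  if (condition == "subgoal" && !goal_sign %in% c(-1, 1))
    stop("goal_sign must be +1 or -1 in the subgoal condition", call. = FALSE)
  structure(list(mAdv = mAdv, fAdv = fAdv, goal_sign = goal_sign,
                 condition = condition),
            class = "trial_covariates")
}

#' Mean drift rate for one trial
#'
#' In the base condition the mean drift is `md * mAdv - fd * fAdv`; a
#' positive value drives the process toward the upper bound, i.e. the choice
#' satisfying the myopic advantage. In the subgoal condition both advantage
#' weights are scaled by the proportional multiplier `p` and the
#' (initially irrelevant) final goal adds `gd * goal_sign`.
#'
#' @param params a [ddm_params()] object.
#' @param cov a [trial_covariates()] object.
#' @return mean drift rate (numeric scalar).
#' @export
drift_rate <- function(params, cov) {
  stopifnot(inherits(params, "ddm_params"), inherits(cov, "trial_covariates"))
  if (cov$condition == "base") {
    params$md * cov$mAdv - params$fd * cov$fAdv
  } else {
    params$p * (params$md * cov$mAdv - params$fd * cov$fAdv) +
      params$gd * cov$goal_sign
  }
}

#' First-passage-time densities of the Wiener process between two bounds
#'
#' Defective absorption-time densities at the upper (+a) and lower (-a)
#' bound for a unit-diffusion Wiener process with constant drift, evaluated
#' by small-time / large-time series expansions with an error-bound
#' switching rule (target absolute accuracy `eps` per term set).
#'
#' @param d mean drift rate.
#' @param a bound magnitude.
#' @param z starting point, `abs(z) < a`.
#' @param t vector of decision times (> 0).
#' @param eps series truncation target.
#' @return matrix with columns `upper` and `lower` of densities at `t`.
#' @export
wiener_fpt_density <- function(d, a, z, t, eps = 1e-7) {
  if (a <= 0 || abs(z) >= a) stop("need a > 0 and |z| < a", call. = FALSE)
  if (any(t <= 0)) stop("decision times must be positive", call. = FALSE)
  wiener_fpt_density_cpp(as.numeric(t), d, a, z, eps)
}

#' Closed-form absorption probability at the upper bound
#'
#' For a unit-diffusion Wiener process with drift `d` between bounds at
#' `+a` and `-a` started at `z`, the probability of absorption at the upper
#' bound is `(1 - exp(-2 d (z + a))) / (1 - exp(-4 d a))`, with the
#' drift-free limit `(z + a) / (2 a)`.
#'
#' @inheritParams wiener_fpt_density
#' @return probability of hitting the upper bound.
#' @export
prob_upper <- function(d, a, z = 0) {
  if (abs(d) < 1e-10) return((z + a) / (2 * a))
  expm1(-2 * d * (z + a)) / expm1(-4 * d * a)
}

#' Defective choice/RT density with inter-trial variability
#'
#' Evaluates the first-passage density at the bound indicated by `choice`
#' at decision time `rt - t0`, averaged over the uniform starting-point
#' distribution (full range `sz`) and the Gaussian trial-level drift
#' distribution (SD `sd`). Returns the floor value `1e-10` (never zero)
#' when `rt <= t0` or on underflow, so likelihood optimization never sees
#' `-Inf`.
#'
#' @param params a [ddm_params()] object.
#' @param cov a [trial_covariates()] object.
#' @param choice +1 (upper bound, myopic-satisfying) or -1 (lower bound).
#' @param rt response time(s), standardized units.
#' @param quad quadrature nodes from [ddm_quadrature()].
#' @param floor_val density floor.
#' @return vector of density values at `rt`.
#' @export
defective_density <- function(params, cov, choice, rt,
                              quad = ddm_quadrature(), floor_val = 1e-10) {
  stopifnot(inherits(params, "ddm_params"), choice %in% c(-1, 1))
  d <- drift_rate(params, cov)
  n <- length(rt)
  defective_density_cpp(as.numeric(rt), rep.int(as.integer(choice), n),
                        rep.int(d, n), rep.int(params$t0, n),
                        params$a, params$z, params$sz, params$sd,
                        quad$ghx, quad$ghw, quad$glx, quad$glw,
                        1e-7, floor_val)
}

#' Joint log-likelihood of choice/RT data
#'
#' Sums log defective densities over trials. `data` is a data frame with
#' columns `mAdv`, `fAdv`, `goal_sign`, `condition`, `choice` (+1/-1, coded
#' in the myopic frame) and `rt` (standardized units).
#'
#' @param params a [ddm_params()] object; `t0_subgoal` optionally overrides
#'   the non-decision time in subgoal trials.
#' @param data trial data frame (see above). Empty data gives 0.
#' @param quad quadrature nodes from [ddm_quadrature()].
#' @param t0_subgoal optional separate non-decision time for subgoal trials.
#' @return log-likelihood (numeric scalar, always finite).
#' @export
ddm_loglik <- function(params, data, quad = ddm_quadrature(),
                       t0_subgoal = NULL) {
  stopifnot(inherits(params, "ddm_params"))
  if (nrow(data) == 0) return(0)
  sub <- data$condition == "subgoal"
  drift <- ifelse(sub,
                  params$p * (params$md * data$mAdv - params$fd * data$fAdv) +
                    params$gd * data$goal_sign,
                  params$md * data$mAdv - params$fd * data$fAdv)
  t0 <- rep.int(params$t0, nrow(data))
  if (!is.null(t0_subgoal)) t0[sub] <- t0_subgoal
  -ddm_negloglik_cpp(as.numeric(data$rt), as.integer(data$choice),
                     as.numeric(drift), t0, params$a, params$z, params$sz,
                     params$sd, quad$ghx, quad$ghw, quad$glx, quad$glw,
                     1e-7, 1e-10)
}

#' Simulate choices and response times from the diffusion process
#'
#' Euler-Maruyama forward simulation with unit diffusion coefficient and
#' step `dt`. Each path draws its starting point from the `sz` uniform and
#' its drift from the `sd` normal. The returned `rt` is the bound hitting
#' time plus `t0`. Paths that do not terminate by `max_t` are flagged
#' `censored` (choice 0). Reproducible under `set.seed()` / `rng_seed`.
#'
#' @param params a [ddm_params()] object.
#' @param cov a [trial_covariates()] object, or a data frame of covariates
#'   (one simulated path per row).
#' @param n number of paths when `cov` is a single covariate set.
#' @param rng_seed optional integer seed.
#' @param dt Euler step (default 1e-3).
#' @param max_t simulation horizon in decision-time units.
#' @return data frame with columns `choice` (+1 upper / -1 lower / 0
#'   censored), `rt`, and `censored`.
#' @export
ddm_simulate <- function(params, cov, n = 1L, rng_seed = NULL, dt = 1e-3,
                         max_t = 30) {
  stopifnot(inherits(params, "ddm_params"))
  if (inherits(cov, "trial_covariates")) {
    drift <- rep.int(drift_rate(params, cov), n)
  } else {
    sub <- cov$condition == "subgoal"
    drift <- ifelse(sub,
                    params$p * (params$md * cov$mAdv - params$fd * cov$fAdv) +
                      params$gd * cov$goal_sign,
                    params$md * cov$mAdv - params$fd * cov$fAdv)
  }
  run <- function() ddm_simulate_cpp(as.numeric(drift), params$t0, params$a,
                                     params$z, params$sz, params$sd, dt, max_t)
  sim <- if (is.null(rng_seed)) run() else withr::with_seed(rng_seed, run())
  data.frame(choice = sim$choice, rt = sim$rt, censored = sim$choice == 0L)
}
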