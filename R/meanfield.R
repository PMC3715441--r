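## Mean-field (well-mixed) limit: every local density is replaced by the
## corresponding global probability, giving a smooth ODE flow on the
## 4-simplex. Fixed points are found by damped Newton iteration with the
## analytic Jacobian assembled from the channel table.

# integer-coded channel table for fast evaluation
compile_channels <- function(params) {
  ch <- canonical_reaction_set(params)
  list(src = state_code(ch$source),
       tgt = state_code(ch$target),
       basal = ch$basal,
       coop = ch$coop,
       cm = {
         cm <- integer(nrow(ch))
         has <- !is.na(ch$coop_mark)
         cm[has] <- state_code(ch$coop_mark[has])
         cm
       },
       tit = ch$titrated)
}

#' Mean-field time derivatives
#'
#' The right-hand side of the well-mixed five-state master equation:
#' local densities in every cooperative channel are replaced by the global
#' state probabilities. The components always sum to zero (probability
#' conservation).
#'
#' @param state numeric probability 5-vector in the order (S, U, A, M, E);
#'   names are ignored.
#' @param params a [rate_params()] object.
#' @param rho_free ambient free-Sir density; Sir-binding channels are
#'   scaled by `rho_free / rho_ref`.
#' @return Named numeric 5-vector of time derivatives.
#' @export
meanfield_rhs <- function(state, params, rho_free = params$rho_ref) {
  stopifnot(length(state) == 5L, all(is.finite(state)), rho_free >= 0)
  cc <- compile_channels(params)
  mf_rhs_core(as.numeric(state), cc, rho_free / params$rho_ref)
}

mf_rhs_core <- function(p, cc, fac) {
  rate <- cc$basal + ifelse(cc$cm > 0L, cc$coop * p[pmax(cc$cm, 1L)], 0)
  rate[cc$tit] <- rate[cc$tit] * fac
  flux <- rate * p[cc$src]
  d <- numeric(5)
  for (k in seq_along(flux)) {
    d[cc$src[k]] <- d[cc$src[k]] - flux[k]
    d[cc$tgt[k]] <- d[cc$tgt[k]] + flux[k]
  }
  names(d) <- NUC_STATES
  d
}

# full 5x5 Jacobian of mf_rhs_core at p
mf_jac_core <- function(p, cc, fac) {
  J <- matrix(0, 5, 5)
  for (k in seq_along(cc$src)) {
    s <- cc$src[k]; t <- cc$tgt[k]; cm <- cc$cm[k]
    f <- if (cc$tit[k]) fac else 1
    rate <- cc$basal[k] + if (cm > 0L) cc$coop[k] * p[cm] else 0
    # d flux / d p_s
    J[s, s] <- J[s, s] - f * rate
    J[t, s] <- J[t, s] + f * rate
    if (cm > 0L) {
      g <- f * cc$coop[k] * p[s]
      J[s, cm] <- J[s, cm] - g
      J[t, cm] <- J[t, cm] + g
    }
  }
  J
}

# reduced 4D system in x = (p_s, p_a, p_m, p_e), p_u = 1 - sum(x)
RED_IDX <- c(1L, 3L, 4L, 5L)  # S, A, M, E positions in the 5-vector

# Hand-expanded reduced RHS and Jacobian for speed in scans. Must agree
# with the channel-assembled mf_rhs_core / mf_jac_core (tested).
mf_fast_funs <- function(params, fac) {
  al <- params$alpha_sir_basal * fac
  de <- params$delta_sir_coop * fac
  ga <- params$gamma_sas2
  b0 <- params$beta0_dot1_basal
  be <- params$beta_dot1_coop
  et <- params$eta_sir2_coop
  la <- params$lambda_loss
  Ffun <- function(x) {
    s <- x[1]; a <- x[2]; m <- x[3]; e <- x[4]
    u <- 1 - s - a - m - e
    c(al * u + de * s * u - la * s,
      ga * u - (b0 + be * e + et * s + la) * a,
      (b0 + be * e) * u + et * s * e - (ga + la) * m,
      ga * m + (b0 + be * e) * a - (et * s + la) * e)
  }
  Jfun <- function(x) {
    s <- x[1]; a <- x[2]; m <- x[3]; e <- x[4]
    u <- 1 - s - a - m - e
    bb <- b0 + be * e
    matrix(c(
      -al + de * (u - s) - la, -al - de * s, -al - de * s, -al - de * s,
      -ga - et * a, -ga - (bb + et * s + la), -ga, -ga - be * a,
      -bb + et * e, -bb, -bb - ga - la, be * u - bb + et * s,
      -et * e, bb, ga, be * a - et * s - la
    ), nrow = 4, byrow = TRUE)
  }
  list(F = Ffun, J = Jfun)
}

mf_expand <- function(x) {
  p <- numeric(5)
  p[RED_IDX] <- x
  p[2L] <- 1 - sum(x)
  p
}

mf_red_F <- function(x, cc, fac) mf_rhs_core(mf_expand(x), cc, fac)[RED_IDX]

mf_red_J <- function(x, cc, fac) {
  J <- mf_jac_core(mf_expand(x), cc, fac)
  J[RED_IDX, RED_IDX, drop = FALSE] - J[RED_IDX, 2L]
}

#' Classify a mean-field fixed point
#'
#' Labels a steady state by where its probability weight sits:
#' *silenced* if `p_s >= theta_hi` and `p_e < theta_lo`; *active* if
#' `p_e >= theta_hi` and `p_s < theta_lo`; *bivalent* if both `p_s` and
#' `p_e` exceed `theta_lo` (without either exclusive dominance test
#' passing); otherwise *intermediate* (weight spread over U, A, M).
#'
#' @param fp probability 5-vector in the order (S, U, A, M, E).
#' @param theta_hi dominance threshold (default 0.5).
#' @param theta_lo co-occurrence threshold (default 0.2).
#' @return One of `"silenced"`, `"active"`, `"bivalent"`, `"intermediate"`.
#' @export
classify_fixed_point <- function(fp, theta_hi = 0.5, theta_lo = 0.2) {
  if (theta_lo >= theta_hi) stop("theta_lo must be < theta_hi")
  ps <- fp[[1L]]; pe <- fp[[5L]]
  if (ps >= theta_hi && pe < theta_lo) return("silenced")
  if (pe >= theta_hi && ps < theta_lo) return("active")
  if (ps >= theta_lo && pe >= theta_lo) return("bivalent")
  "intermediate"
}

#' Find all mean-field fixed points
#'
#' Multi-start damped Newton iteration on the reduced four-dimensional
#' system (p_u eliminated). Starts are the five pure-state corners, the
#' barycenter, and `n_random` random points of the simplex; converged
#' roots are deduplicated at sup-norm tolerance 1e-6 and every returned
#' root has residual below 1e-10. Stability is judged by the largest real
#' part of the reduced Jacobian's eigenvalues: stable if below -1e-8,
#' flagged `marginal` when within 1e-8 of zero (bifurcation boundary).
#'
#' @inheritParams meanfield_rhs
#' @param n_random number of random simplex starts (>= 20 recommended).
#' @param theta_hi,theta_lo label thresholds, see [classify_fixed_point()].
#' @return A `data.frame` with columns `p_s`, `p_u`, `p_a`, `p_m`, `p_e`,
#'   `max_re` (largest real eigenvalue part), `stable`, `marginal`,
#'   `label`.
#' @examples
#' # loss only: everything decays to the unmodified state
#' p <- rate_params(alpha_sir_basal = 0, delta_sir_coop = 0, gamma_sas2 = 0,
#'                  beta0_dot1_basal = 0, beta_dot1_coop = 0, eta_sir2_coop = 0)
#' find_fixed_points(p)
#' @export
find_fixed_points <- function(params, rho_free = params$rho_ref,
                              n_random = 20L,
                              theta_hi = 0.5, theta_lo = 0.2) {
  validate_rate_params(params)
  fac <- rho_free / params$rho_ref
  funs <- mf_fast_funs(params, fac)
  starts <- list()
  for (i in 1:5) {  # pure-state corners
    p <- numeric(5); p[i] <- 1
    starts[[length(starts) + 1L]] <- p[RED_IDX]
  }
  starts[[length(starts) + 1L]] <- rep(0.2, 5)[RED_IDX]
  for (i in seq_len(n_random)) {  # Dirichlet(1) draws
    g <- stats::rexp(5)
    starts[[length(starts) + 1L]] <- (g / sum(g))[RED_IDX]
  }
  sm <- do.call(rbind, starts)
  rts <- mf_newton_multi(
    c(params$alpha_sir_basal * fac, params$delta_sir_coop * fac,
      params$gamma_sas2, params$beta0_dot1_basal, params$beta_dot1_coop,
      params$eta_sir2_coop, params$lambda_loss),
    sm, tol = 1e-13, maxit = 100L)
  roots <- list()
  for (i in seq_len(nrow(rts))) {
    p <- mf_expand(rts[i, ])
    p <- pmin(pmax(p, 0), 1); p <- p / sum(p)
    dup <- FALSE
    for (r in roots) if (max(abs(r - p)) < 1e-6) { dup <- TRUE; break }
    if (!dup) roots[[length(roots) + 1L]] <- p
  }
  if (!length(roots))
    stop("no converged mean-field root; flow should always have one")
  out <- do.call(rbind, lapply(roots, function(p) {
    ev <- eigen(funs$J(p[RED_IDX]), only.values = TRUE)$values
    mre <- max(Re(ev))
    data.frame(p_s = p[1], p_u = p[2], p_a = p[3], p_m = p[4], p_e = p[5],
               max_re = mre,
               stable = mre < -1e-8,
               marginal = abs(mre) < 1e-8,
               label = classify_fixed_point(p, theta_hi, theta_lo))
  }))
  out[order(-out$p_s), , drop = FALSE]
}

phase_class_from_labels <- function(labels) {
  labels <- sort(labels)
  if (length(labels) == 1L) return(paste0(labels, "-mono"))
  if (length(labels) == 2L) {
    if (identical(labels, c("active", "silenced")))
      return("silenced-active-bistable")
    if (identical(labels, c("intermediate", "silenced")))
      return("silenced-intermediate-bistable")
  }
  "other"
}

#' Phase report at one parameter point
#'
#' Runs [find_fixed_points()] and condenses the stable-label multiset into
#' a phase class: `<label>-mono` for one stable state,
#' `silenced-active-bistable` or `silenced-intermediate-bistable` for the
#' two bistability types the model supports, `other` otherwise. Marginal
#' roots (on a bifurcation boundary) are excluded from the label count.
#'
#' @inheritParams find_fixed_points
#' @return A list of class `"phase_report"`: `params`, `rho_free`,
#'   `fixed_points` (the full table), `stable_labels`, `phase_class`.
#' @export
phase_report <- function(params, rho_free = params$rho_ref,
                         n_random = 20L, theta_hi = 0.5, theta_lo = 0.2) {
  fps <- find_fixed_points(params, rho_free, n_random, theta_hi, theta_lo)
  stab <- fps[fps$stable & !fps$marginal, , drop = FALSE]
  structure(list(params = params, rho_free = rho_free, fixed_points = fps,
                 stable_labels = stab$label,
                 phase_class = phase_class_from_labels(stab$label)),
            class = "phase_report")
}

#' @export
print.phase_report <- function(x, ...) {
  cat("Phase:", x$phase_class, "\n")
  print(x$fixed_points, digits = 4)
  invisible(x)
}

#' Scan the mean-field phase diagram
#'
#' Evaluates [phase_report()] on the Cartesian grid of 1-4 axes over the
#' cooperative rates (`gamma_sas2`, `beta_dot1_coop`, `eta_sir2_coop`,
#' `delta_sir_coop`), holding the remaining parameters at their values in
#' `params`.
#'
#' @param axes named list of numeric grid vectors; names must be among the
#'   four cooperative rates.
#' @param params baseline [rate_params()] supplying all fixed values.
#' @inheritParams find_fixed_points
#' @return A `data.frame` with one row per grid point: the swept values,
#'   `n_stable`, `labels` (semicolon-joined stable labels) and
#'   `phase_class`. Scan metadata (fixed parameters, thresholds) is
#'   attached as attribute `"meta"`.
#' @export
scan_phase_diagram <- function(axes, params, rho_free = params$rho_ref,
                               n_random = 20L,
                               theta_hi = 0.5, theta_lo = 0.2) {
  allowed <- c("gamma_sas2", "beta_dot1_coop", "eta_sir2_coop",
               "delta_sir_coop")
  if (!length(axes) || !all(names(axes) %in% allowed))
    stop("axes must be a named list over: ", paste(allowed, collapse = ", "))
  for (a in axes) {
    if (!all(is.finite(a)) || any(a < 0)) stop("grid values must be finite and >= 0")
  }
  grid <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    pi <- do.call(update_params, c(list(params), as.list(grid[i, , drop = FALSE])))
    rep <- phase_report(pi, rho_free, n_random, theta_hi, theta_lo)
    rows[[i]] <- cbind(grid[i, , drop = FALSE],
                       data.frame(n_stable = length(rep$stable_labels),
                                  labels = paste(sort(rep$stable_labels),
                                                 collapse = ";"),
                                  phase_class = rep$phase_class))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "meta") <- list(fixed = unclass(params), rho_free = rho_free,
                            theta_hi = theta_hi, theta_lo = theta_lo,
                            n_random = n_random)
  out
}

#' Integrate the mean-field flow
#'
#' Forward ODE integration of [meanfield_rhs()] with `deSolve::ode`
#' (lsoda). Used for hysteresis checks and as an independent cross-check
#' of the Newton fixed points.
#'
#' @param state0 initial probability 5-vector (S, U, A, M, E).
#' @inheritParams meanfield_rhs
#' @param t_end final time in loss-rate units.
#' @param n_out number of output times.
#' @return Matrix of class `deSolve`: time plus the five probabilities.
#' @export
integrate_meanfield <- function(state0, params, rho_free = params$rho_ref,
                                t_end = 200, n_out = 101L) {
  cc <- compile_channels(params)
  fac <- rho_free / params$rho_ref
  deSolve::ode(y = as.numeric(state0),
               times = seq(0, t_end, length.out = n_out),
               func = function(t, y, parms) list(mf_rhs_core(y, cc, fac)),
               parms = NULL, rtol = 1e-10, atol = 1e-12)
}

#' Critical cooperative Dot1 rate between the two bistability types
#'
#' In the sharp-transition regime (`beta0_dot1_basal` and
#' `alpha_sir_basal` both zero) the label of the stable non-silenced
#' branch is a step function of `beta_dot1_coop`: *intermediate* below a
#' critical value, *active* above it. This locates the step by bisection.
#' With positive basal rates the step broadens into a crossover; the
#' function then scans the interval and reports the crossover window (the
#' range of `beta_dot1_coop` where the non-silenced branch is labeled
#' *bivalent*, i.e. neither cleanly intermediate nor cleanly active).
#'
#' @param params a [rate_params()]; for the sharp mode its
#'   `beta0_dot1_basal` and `alpha_sir_basal` must be zero.
#' @param interval numeric length-2 search interval for `beta_dot1_coop`.
#' @inheritParams find_fixed_points
#' @param tol bisection tolerance on the rate.
#' @param n_scan grid size for the crossover scan (basal-rate mode).
#' @return Sharp mode: a list with `critical_beta` and mode `"sharp"`.
#'   Crossover mode: a list with `interval` (the window), `width`, and
#'   mode `"crossover"`.
#' @export
critical_dot1_rate <- function(params, interval, rho_free = params$rho_ref,
                               n_random = 20L, tol = 1e-4, n_scan = 41L) {
  stopifnot(length(interval) == 2L, interval[1] <= interval[2])
  branch_state <- function(beta) {
    p <- update_params(params, beta_dot1_coop = beta)
    fps <- find_fixed_points(p, rho_free, n_random)
    st <- fps[fps$stable & !fps$marginal & fps$label != "silenced", , drop = FALSE]
    if (!nrow(st)) return(NA_character_)
    st$label[which.max(st$p_e + st$p_a + st$p_m)]
  }
  sharp <- params$beta0_dot1_basal == 0 && params$alpha_sir_basal == 0
  if (!sharp) {
    betas <- seq(interval[1], interval[2], length.out = n_scan)
    lab <- vapply(betas, branch_state, character(1))
    biv <- which(lab == "bivalent")
    win <- if (length(biv)) range(betas[biv]) else {
      # no bivalent labels resolved at this grid: window between the last
      # intermediate and the first active label
      i1 <- max(which(lab == "intermediate"), 0)
      i2 <- min(which(lab == "active"), n_scan + 1)
      if (i1 == 0 || i2 > n_scan) stop("no label change in interval")
      c(betas[i1], betas[i2])
    }
    return(list(mode = "crossover", interval = win, width = diff(win),
                scan = data.frame(beta = betas, label = lab)))
  }
  is_active <- function(beta) {
    lab <- branch_state(beta)
    if (is.na(lab)) stop("non-silenced stable branch lost at beta = ", beta)
    lab == "active"
  }
  lo <- interval[1]; hi <- interval[2]
  a_lo <- is_active(lo); a_hi <- is_active(hi)
  if (a_lo == a_hi) {
    if (lo == hi) stop("degenerate interval does not straddle the label change")
    stop("label change not bracketed by interval")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_active(mid) == a_lo) lo <- mid else hi <- mid
  }
  list(mode = "sharp", critical_beta = (lo + hi) / 2)
}
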