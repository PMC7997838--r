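# Internal: map observation times onto the Euler grid. Times that do not
# fall on a grid node (within fp tolerance) are linearly interpolated
# between the bracketing nodes; `inform()` reports this once per call site.
obs_grid_weights <- function(obs_times, dt, n_steps, quiet = FALSE) {
  pos <- obs_times / dt
  lo <- pmin(floor(pos + 1e-9), n_steps)
  w <- pos - lo
  on_grid <- w < 1e-8
  w[on_grid] <- 0
  hi <- ifelse(on_grid, lo, pmin(lo + 1, n_steps))
  if (!quiet && any(!on_grid)) {
    inform(sprintf(
      "%d observation time(s) off the dt = %g grid; using linear interpolation",
      sum(!on_grid), dt))
  }
  keep <- sort(unique(c(lo, hi))) + 1L  # 1-based grid rows
  list(keep = as.integer(keep),
       lo_pos = match(lo + 1L, keep), hi_pos = match(hi + 1L, keep), w = w)
}

# Internal: resolve dataset column names against network compounds,
# case-insensitively. Unknown columns are an error.
match_compounds <- function(cols, net) {
  cp <- net$compounds$compound
  idx <- match(tolower(cols), tolower(cp))
  if (anyNA(idx)) {
    abort(paste0("compound column(s) not in the network: ",
                 paste(cols[is.na(idx)], collapse = ", ")))
  }
  cp[idx]
}

#' Residual sum of squares between observations and a simulated trajectory
#'
#' The goodness-of-fit measure of the whole package: for each measurable
#' compound, the sum over observation times of the squared difference
#' between observed and simulated concentration (umol^2 l^-2). Unmeasured
#' compounds (the CoA-ligated intermediates) contribute nothing, and missing
#' observations (`NA` cells) are excluded. Observation times that do not lie
#' on the trajectory grid are linearly interpolated.
#'
#' @param observed data frame with column `time_h` and one column per
#'   observed compound (umol/l); compound names are matched
#'   case-insensitively against the network.
#' @param traj an `aromkin_trajectory` from [simulate_network()] whose grid
#'   spans the observation times.
#' @param net the [aromatic_network()] the trajectory was simulated from.
#' @return A list with `rss_per_compound` (tibble `compound`, `rss`, ordered
#'   as in the network, measurable compounds present in `observed` only) and
#'   `rss_total` (their sum).
#' @export
trajectory_rss <- function(observed, traj, net) {
  observed <- tibble::as_tibble(observed)
  if (!"time_h" %in% names(observed)) abort("`observed` needs a `time_h` column")
  times <- attr(traj, "times")
  conc <- attr(traj, "conc")
  if (max(observed$time_h) > max(times) + 1e-9 || min(observed$time_h) < min(times) - 1e-9) {
    abort("observation times fall outside the trajectory range")
  }
  cols <- setdiff(names(observed), "time_h")
  canon <- match_compounds(cols, net)
  measurable <- net$compounds$compound[net$compounds$measurable]
  use <- canon %in% measurable
  dt <- times[2] - times[1]
  gw <- obs_grid_weights(observed$time_h, dt, length(times) - 1L, quiet = TRUE)
  rss <- purrr::map_dbl(which(use), function(i) {
    sim <- conc[gw$keep, canon[i]]
    pred <- (1 - gw$w) * sim[gw$lo_pos] + gw$w * sim[gw$hi_pos]
    sum((observed[[cols[i]]] - pred)^2, na.rm = TRUE)
  })
  per <- tibble::tibble(compound = canon[use], rss = rss)
  per <- per[order(match(per$compound, net$compounds$compound)), ]
  list(rss_per_compound = per, rss_total = sum(per$rss))
}

# Internal: fast RSS objective over the free parameters (log scale).
# Precomputes the biomass grid, observation masks and interpolation weights
# so each evaluation is one compiled Euler pass plus a masked sum.
make_objective <- function(net, data, biomass, dt, k_floor = 1e-12) {
  cc <- compile_network(net)
  fp <- net$free_parameters
  rx_idx <- match(fp$substrate, net$reactions$substrate)
  is_k <- fp$param == "k"
  t_end <- max(data$time_h)
  n_steps <- as.integer(ceiling(t_end / dt - 1e-9))
  times <- seq(0, by = dt, length.out = n_steps + 1)
  x <- biomass_grid(biomass, times)
  gw <- obs_grid_weights(data$time_h, dt, n_steps)
  cols <- setdiff(names(data), "time_h")
  canon <- match_compounds(cols, net)
  use <- canon %in% cc$compounds[cc$measurable]
  obs <- as.matrix(data[, cols[use], drop = FALSE])
  col_idx <- match(canon[use], cc$compounds)
  na_mask <- is.na(obs)
  obs0 <- ifelse(na_mask, 0, obs)

  k <- cc$k; ki <- cc$ki
  eval_params <- function(theta) {
    val <- exp(theta)
    val[is_k] <- pmax(val[is_k], k_floor)
    val[!is_k] <- pmax(val[!is_k], 1e-9)
    val
  }
  objective <- function(theta) {
    val <- eval_params(theta)
    k[rx_idx[is_k]] <- val[is_k]
    ki[rx_idx[!is_k]] <- val[!is_k]
    res <- euler_core(cc$s0, x, dt, cc$sub, cc$prod, cc$inhib, k, ki,
                      keep = gw$keep, clip = TRUE)
    sim <- res$conc[, col_idx, drop = FALSE]
    pred <- (1 - gw$w) * sim[gw$lo_pos, , drop = FALSE] +
      gw$w * sim[gw$hi_pos, , drop = FALSE]
    resid <- obs0 - pred
    resid[na_mask] <- 0
    s <- sum(resid * resid)
    if (!is.finite(s)) 1e300 else s
  }
  list(objective = objective, eval_params = eval_params,
       par_names = paste0(fp$param, "[", fp$substrate, "]"),
       is_k = is_k, n_par = nrow(fp))
}

#' Estimate rate constants by RSS minimization
#'
#' Fits all free parameters of a network jointly to the observed time series
#' of every measurable compound, by minimizing the total residual sum of
#' squares with a multi-start Nelder-Mead simplex search. The search runs in
#' log-parameter space, which enforces positivity; `k` values may fall to a
#' floor of `k_floor` (1e-12 l mg^-1 h^-1), interpreted as "no degradation".
#' Each start runs up to `cycles` consecutive simplex searches (each
#' restarted from the previous optimum, which rebuilds the simplex and
#' escapes premature collapse); the first start is the initial guess itself
#' and the remaining `restarts - 1` are log-normal jitters of it. The best
#' start wins; the returned RSS never exceeds the RSS at the initial guess.
#' All randomness derives from `seed`, so identical inputs give identical
#' results.
#'
#' @param data observations: data frame with `time_h` plus one column per
#'   measured compound (umol/l); strictly increasing times; `NA` cells are
#'   allowed and excluded from the RSS.
#' @param net an [aromatic_network()]; its free-parameter list defines what
#'   is estimated, its current parameter values are the default start.
#' @param biomass a [biomass_model()] or a constant (mg/l).
#' @param init optional named (or ordered) vector of starting values.
#' @param seed integer; drives the jittered restarts.
#' @param restarts number of starts (first one unjittered).
#' @param dt Euler step used inside the objective, h.
#' @param cycles simplex restarts per start.
#' @param max_evals iteration cap per simplex cycle.
#' @param reltol relative convergence tolerance on the RSS.
#' @param k_floor positivity floor for rate constants.
#' @param extra_starts optional list of named parameter vectors appended as
#'   additional unjittered starts (used by [compare_cases()] to seed nested
#'   models from simpler ones).
#' @return An object of class `aromkin_fit`: the fitted network, the
#'   parameter estimates, per-compound and total RSS, evaluation counts,
#'   convergence flag and the seed. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
fit_network <- function(data, net, biomass, init = NULL, seed = 1L,
                        restarts = 5, dt = 1, cycles = 3, max_evals = 5000,
                        reltol = 1e-8, k_floor = 1e-12, extra_starts = NULL) {
  data <- tibble::as_tibble(data)
  if (!"time_h" %in% names(data)) abort("`data` needs a `time_h` column")
  if (is.unsorted(data$time_h, strictly = TRUE)) {
    abort("observation times must be strictly increasing")
  }
  ob <- make_objective(net, data, biomass, dt, k_floor)
  if (ob$n_par == 0) abort("network has no free parameters")

  start0 <- network_params(net)
  if (!is.null(init)) {
    if (is.null(names(init))) {
      if (length(init) != ob$n_par) abort("`init` length must match free parameters")
      start0 <- setNames(as.numeric(init), ob$par_names)
    } else {
      start0[names(init)] <- init
    }
  }
  start0 <- start0[ob$par_names]
  if (anyNA(start0) || any(start0 <= 0)) {
    abort("starting values must be positive for every free parameter")
  }
  theta0 <- log(start0)

  set.seed(seed)
  starts <- c(
    list(theta0),
    purrr::map(seq_len(max(restarts - 1, 0)), function(i) {
      theta0 + rnorm(ob$n_par, sd = log(3))
    }),
    purrr::map(extra_starts %||% list(), function(p) {
      th <- theta0
      p <- p[names(p) %in% ob$par_names]
      th[names(p)] <- log(pmax(as.numeric(p), 1e-300))
      th
    })
  )

  best <- NULL
  n_evals <- 0L
  n_failed <- 0L
  for (th in starts) {
    f0 <- ob$objective(th)
    n_evals <- n_evals + 1L
    if (f0 >= 1e300) { n_failed <- n_failed + 1L; next }
    cur <- list(par = th, value = f0, converged = FALSE)
    for (cy in seq_len(cycles)) {
      opt <- optim(cur$par, ob$objective, method = "Nelder-Mead",
                   control = list(maxit = max_evals, reltol = reltol))
      n_evals <- n_evals + opt$counts[["function"]]
      improved <- cur$value - opt$value
      conv <- opt$convergence == 0 &&
        improved <= reltol * abs(cur$value) + 1e-12
      if (opt$value <= cur$value) cur <- list(par = opt$par, value = opt$value,
                                              converged = conv)
      if (conv && cy > 1) break
    }
    if (is.null(best) || cur$value < best$value) best <- cur
  }
  if (is.null(best)) abort("all starts produced a non-finite objective")

  params <- setNames(ob$eval_params(best$par), ob$par_names)
  fitted_net <- set_network_params(net, params)
  traj <- simulate_network(fitted_net, biomass, t_end = max(data$time_h),
                           dt = dt, warn_clip = FALSE)
  rss <- trajectory_rss(data, traj, fitted_net)
  structure(
    list(network = fitted_net, params = params,
         rss_per_compound = rss$rss_per_compound, rss_total = rss$rss_total,
         n_evals = n_evals, n_starts = length(starts) - n_failed,
         converged = best$converged, seed = seed, dt = dt,
         data = data, biomass = biomass),
    class = "aromkin_fit")
}

#' @export
print.aromkin_fit <- function(x, ...) {
  cat(sprintf(
    "<aromkin_fit> %d parameters, total RSS = %.6g (umol^2 l^-2), %d evaluations, %s\n",
    length(x$params), x$rss_total, x$n_evals,
    if (x$converged) "converged" else "not converged"))
  print(tidy(x), n = length(x$params))
  invisible(x)
}

#' Tidy a network fit
#'
#' @param x an `aromkin_fit`.
#' @param zero_floor estimates at or below this value are reported as 0
#'   ("no degradation"); set to 0 to disable.
#' @param ... unused.
#' @return A tibble with `term`, `substrate`, `parameter` (`"k"` or
#'   `"k_i"`), `estimate` and `unit`.
#' @export
tidy.aromkin_fit <- function(x, zero_floor = 1e-10, ...) {
  fp <- x$network$free_parameters
  est <- unname(x$params)
  est[fp$param == "k" & est <= zero_floor] <- 0
  tibble::tibble(
    term = names(x$params),
    substrate = fp$substrate,
    parameter = fp$param,
    estimate = est,
    unit = ifelse(fp$param == "k", "l/mg/h", "umol/l")
  )
}

#' One-row fit summary
#'
#' @param x an `aromkin_fit`.
#' @param ... unused.
#' @export
glance.aromkin_fit <- function(x, ...) {
  tibble::tibble(
    rss_total = x$rss_total,
    n_params = length(x$params),
    n_obs = sum(!is.na(as.matrix(x$data[setdiff(names(x$data), "time_h")]))),
    n_evals = x$n_evals,
    converged = x$converged,
    seed = x$seed
  )
}

#' Fit and compare the five pathway-structure hypotheses
#'
#' Fits each requested case to the same dataset and reports the per-compound
#' and total RSS side by side, in the standard compound order of the H + G
#' comparison. The cases are nested — an inhibited rate law reduces to
#' first-order as `k_i` grows — so each case's start set includes, besides
#' its own jittered restarts, the optima of all previously fitted cases with
#' absent inhibition factors set large (`1e6` umol/l, far above any
#' concentration in the system). This warm-start chain makes the fitted RSS
#' respect the nesting ordering within the restart budget.
#'
#' @param data observations covering the measurable H + G compounds (see
#'   [fit_network()]).
#' @param biomass a [biomass_model()] or constant biomass, mg/l.
#' @param cases integer vector, subset of 1:5, fitted in ascending order.
#' @param seed,restarts,dt,... passed to [fit_network()].
#' @return An object of class `case_comparison`: a tibble with one row per
#'   case, one RSS column per measurable compound and a `total` column;
#'   attribute `fits` holds the underlying `aromkin_fit` objects. Methods:
#'   [tidy()], [autoplot()], [parameter_table()].
#' @export
compare_cases <- function(data, biomass, cases = 1:5, seed = 1L,
                          restarts = 3, dt = 1, ...) {
  cases <- sort(unique(as.integer(cases)))
  if (!all(cases %in% 1:5)) abort("`cases` must be a subset of 1:5")
  fits <- list()
  for (cs in cases) {
    net <- case_network(cs)
    ki_names <- paste0(
      "k_i[", net$free_parameters$substrate[net$free_parameters$param == "k_i"], "]")
    embeds <- purrr::flatten(purrr::map(fits, function(f) {
      p <- f$params
      missing_ki <- setdiff(ki_names, names(p))
      list(
        # carry over everything that matches; absent inhibitions start off
        c(p, setNames(rep(1e6, length(missing_ki)), missing_ki)),
        # rate constants only, all inhibitions off: the first-order limit
        c(p[!startsWith(names(p), "k_i")],
          setNames(rep(1e6, length(ki_names)), ki_names))
      )
    }))
    fits[[paste0("case", cs)]] <- fit_network(
      data, net, biomass, seed = seed + cs, restarts = restarts, dt = dt,
      extra_starts = unname(embeds), ...)
  }
  order_cols <- intersect(hg_compound_order(),
                          unique(unlist(purrr::map(fits, ~ .x$rss_per_compound$compound))))
  tab <- purrr::imap_dfr(fits, function(f, nm) {
    wide <- setNames(as.list(f$rss_per_compound$rss), f$rss_per_compound$compound)
    dplyr::bind_cols(tibble::tibble(case = nm), tibble::as_tibble(wide),
                     tibble::tibble(total = f$rss_total))
  })
  tab <- tab[, c("case", order_cols, setdiff(names(tab), c("case", order_cols, "total")), "total")]
  structure(tab, fits = fits, class = c("case_comparison", class(tab)))
}

#' @export
tidy.case_comparison <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(x), -"case",
                      names_to = "compound", values_to = "rss")
}

#' Fitted parameters of a case comparison or single fit
#'
#' One row per estimated parameter, with rate constants at the positivity
#' floor displayed as 0 (no degradation).
#'
#' @param x an `aromkin_fit` or `case_comparison`.
#' @param zero_floor see [tidy.aromkin_fit()].
#' @return A tibble with `case` (for comparisons), `substrate`, `parameter`,
#'   `estimate`, `unit`.
#' @export
parameter_table <- function(x, zero_floor = 1e-10) {
  if (inherits(x, "aromkin_fit")) {
    return(dplyr::select(tidy(x, zero_floor), -"term"))
  }
  if (!inherits(x, "case_comparison")) {
    abort("`x` must be an aromkin_fit or case_comparison")
  }
  purrr::imap_dfr(attr(x, "fits"), function(f, nm) {
    dplyr::bind_cols(tibble::tibble(case = nm),
                     dplyr::select(tidy(f, zero_floor), -"term"))
  })
}
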