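# Internal: flatten a network into integer-indexed vectors for the Euler
# core. Substrate indices are unique (single consuming reaction), products
# and inhibitors may be 0 (none).
compile_network <- function(net) {
  cp <- net$compounds
  rx <- net$reactions
  list(
    compounds = cp$compound,
    measurable = cp$measurable,
    s0 = cp$initial,
    sub = match(rx$substrate, cp$compound),
    prod = ifelse(is.na(rx$product), 0L, match(rx$product, cp$compound)),
    inhib = ifelse(rx$law == "inhibited", match(rx$inhibitor, cp$compound), 0L),
    k = rx$k,
    ki = ifelse(is.na(rx$k_i), 1, rx$k_i)
  )
}

# Internal: biomass forcing on a time grid. `biomass` is either a
# biomass_model or a single non-negative number (constant forcing, useful
# for analytical checks).
biomass_grid <- function(biomass, times) {
  if (inherits(biomass, "biomass_model")) {
    gompertz_biomass(times, biomass)
  } else if (is.numeric(biomass) && length(biomass) == 1 && biomass >= 0) {
    rep(biomass, length(times))
  } else {
    abort("`biomass` must be a biomass_model or a single non-negative number")
  }
}

#' Network ODE right-hand side
#'
#' Assembles dS/dt for every compound: the sum of the rates of the reactions
#' producing it minus the rate of its single consuming reaction, each rate
#' evaluated by its law on the current concentrations, all scaled by the
#' biomass concentration `X`:
#' \deqn{\frac{dS}{dt} = r_p X - r_s X.}
#' A compound with neither producers nor a consumer has dS/dt = 0.
#'
#' This is the reference R implementation of the right-hand side; the
#' integrator itself runs a compiled equivalent.
#'
#' @param net an [aromatic_network()] with all rate constants set.
#' @param conc named or unnamed concentration vector, umol/l, in the
#'   network's compound order, `>= 0`.
#' @param X biomass concentration, mg/l, `>= 0`.
#' @return Named vector dS/dt, umol l^-1 h^-1.
#' @export
network_rhs <- function(net, conc, X) {
  cc <- compile_network(net)
  nc <- length(cc$compounds)
  if (length(conc) != nc) {
    abort(sprintf("`conc` must have %d elements (one per compound)", nc))
  }
  if (any(conc < 0)) abort("`conc` must be >= 0")
  if (length(X) != 1 || X < 0) abort("`X` must be a single value >= 0")
  conc <- unname(conc)
  d <- numeric(nc)
  for (j in seq_along(cc$sub)) {
    r <- if (cc$inhib[j] > 0) {
      rate_inhibited(cc$k[j], cc$ki[j], conc[cc$sub[j]], conc[cc$inhib[j]])
    } else {
      rate_first_order(cc$k[j], conc[cc$sub[j]])
    }
    d[cc$sub[j]] <- d[cc$sub[j]] - r
    if (cc$prod[j] > 0) d[cc$prod[j]] <- d[cc$prod[j]] + r
  }
  setNames(d * X, cc$compounds)
}

#' Simulate a pathway network by fixed-step Euler integration
#'
#' Integrates the network ODEs with the explicit Euler scheme
#' `S(t + dt) = S(t) + dt * dS/dt(S(t), X(t))` on a uniform grid from 0 to
#' `t_end`. The default step of 1 h matches the batch-culture timescale; a
#' finer step is available wherever discretization error matters (the
#' synthetic-data generator uses 0.01 h). Because the explicit scheme can
#' overshoot zero for fast reactions, any component driven negative by a
#' step is clipped to 0; a warning reports how many updates were clipped
#' (suppress with `warn_clip = FALSE`).
#'
#' @param net an [aromatic_network()] with all rate constants set.
#' @param biomass a [biomass_model()], or a single number for constant
#'   biomass forcing (useful for analytical checks).
#' @param t_end end of the simulation, h, `> 0`.
#' @param dt Euler step, h, `> 0`.
#' @param clip_negative clip negative overshoot to 0 (default TRUE).
#' @param warn_clip warn when any update was clipped.
#' @return A tibble of class `aromkin_trajectory` in tidy form with columns
#'   `time_h`, `compound`, `conc_umol_per_l`, `measurable`, plus attributes
#'   `times` (the grid), `conc` (time x compound matrix) and `network`.
#' @export
simulate_network <- function(net, biomass, t_end, dt = 1,
                             clip_negative = TRUE, warn_clip = TRUE) {
  if (!is.finite(t_end) || t_end <= 0) abort("`t_end` must be > 0")
  if (!is.finite(dt) || dt <= 0) abort("`dt` must be > 0")
  cc <- compile_network(net)
  if (any(is.na(cc$k))) abort("network has unset rate constants; use set_network_params()")
  n_steps <- as.integer(ceiling(t_end / dt - 1e-9))
  times <- seq(0, by = dt, length.out = n_steps + 1)
  x <- biomass_grid(biomass, times)
  res <- euler_core(cc$s0, x, dt, cc$sub, cc$prod, cc$inhib, cc$k, cc$ki,
                    keep = seq_len(n_steps + 1L), clip = clip_negative)
  if (warn_clip && res$n_clipped > 0) {
    warn(sprintf(
      "%d Euler update(s) overshot below zero and were clipped; consider a smaller dt",
      res$n_clipped))
  }
  conc <- res$conc
  colnames(conc) <- cc$compounds
  out <- tibble::tibble(
    time_h = rep(times, times = length(cc$compounds)),
    compound = rep(cc$compounds, each = length(times)),
    conc_umol_per_l = as.vector(conc),
    measurable = rep(cc$measurable, each = length(times))
  )
  structure(out, times = times, conc = conc, network = net,
            class = c("aromkin_trajectory", class(out)))
}

#' Time x compound concentration matrix of a trajectory
#'
#' @param traj an `aromkin_trajectory` from [simulate_network()].
#' @return Numeric matrix (rows = grid times, columns = compounds), with the
#'   grid in attribute-free `rownames`-less form; get the grid from
#'   `attr(traj, "times")`.
#' @export
trajectory_matrix <- function(traj) {
  if (!inherits(traj, "aromkin_trajectory")) {
    abort("`traj` must come from simulate_network()")
  }
  attr(traj, "conc")
}
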