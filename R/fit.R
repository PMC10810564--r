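#' Default fitting bounds for a regime
#'
#' Box bounds for the six free parameters of a regime: the metabolic gain
#' (`supps` or `uf`) in `[-0.5, 0.5]`, the vascular CO2 gain `R_autc` in
#' 0.25-4 times its calibrated default, the two CO2 filter time constants,
#' normal arterial pressure, and normal CBF in 0.6-1.4 times nominal.
#'
#' @param regime `"supply"` or `"demand"`.
#' @param params Parameter set supplying the nominal `R_autc` and `CBF_n`.
#' @return Named list of `c(lo, hi)` bounds.
#' @export
default_bounds <- function(regime = c("supply", "demand"),
                           params = bc_params()) {
  regime <- match.arg(regime)
  gain <- if (regime == "supply") "supps" else "uf"
  b <- list(c(-0.5, 0.5),
            R_autc = c(0.25, 4) * params$R_autc,
            tau_c = c(1, 60), tau_c2 = c(1, 600),
            P_an = c(70, 110),
            CBF_n = c(0.6, 1.4) * params$CBF_n)
  names(b)[1] <- gain
  b
}

bc_regime_free <- function(regime) {
  c(if (regime == "supply") "supps" else "uf",
    "R_autc", "tau_c", "tau_c2", "P_an", "CBF_n")
}

#' Fit one CO2-metabolism regime to observed data
#'
#' Runs the seeded genetic algorithm over the regime's six free parameters
#' (`supps` or `uf`, plus `R_autc`, `tau_c`, `tau_c2`, `P_an`, `CBF_n`),
#' minimizing the weighted mean-absolute-difference cost of
#' [evaluate_cost()] over the chosen target signals. Every candidate is a
#' freshly calibrated parameter set, so the baseline steady state always sits
#' on the nominal targets implied by the candidate. Candidates whose forward
#' simulation fails are penalized with infinite cost and the run continues.
#'
#' @param observed Observed trace (`t`, `dCBF_pct`, `TOI`, `oxCCO`).
#' @param inputs Input trace driving the model.
#' @param regime `"supply"` (fits `supps`) or `"demand"` (fits `uf`).
#' @param target_set Channels entering the cost, a subset of
#'   `c("oxCCO", "TOI", "dCBF_pct")`.
#' @param bounds Named list of `c(lo, hi)` per free parameter; defaults to
#'   [default_bounds()]. Must cover exactly the regime's six free parameters.
#' @param ga A [ga_control()] object.
#' @param seed Integer seed; the fit is deterministic given it.
#' @param fixed Named list of non-free parameter overrides applied to every
#'   candidate.
#' @param init Optional numeric matrix (or vector) of starting candidates in
#'   free-parameter order, injected into the initial population (warm start).
#' @param polish If `TRUE` (default), refine the GA's best candidate with a
#'   bounded Nelder-Mead simplex search (hybrid global/local optimization).
#' @param polish_maxit Maximum simplex iterations for the polish step.
#' @return An object of class `bc_fit`: fitted parameters, cost breakdown,
#'   the fitted model's simulation, and GA convergence history. Supports
#'   [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @examples
#' \donttest{
#' inp <- make_inputs(challenge_spec())
#' obs <- make_observations(inp, mode = "descriptive")
#' fit <- fit_regime(obs, inp, "supply",
#'                   ga = ga_control(pop_size = 16, generations = 10), seed = 1)
#' tidy(fit)
#' }
#' @export
fit_regime <- function(observed, inputs, regime = c("supply", "demand"),
                       target_set = c("oxCCO", "TOI", "dCBF_pct"),
                       bounds = NULL, ga = ga_control(), seed = 1,
                       fixed = list(), init = NULL, polish = TRUE,
                       polish_maxit = 400) {
  regime <- match.arg(regime)
  target_set <- match.arg(target_set, c("oxCCO", "TOI", "dCBF_pct"),
                          several.ok = TRUE)
  free <- bc_regime_free(regime)
  bounds <- bounds %||% default_bounds(regime)
  if (!setequal(names(bounds), free)) {
    abort(paste0("bounds must cover exactly the regime's free parameters: ",
                 paste(free, collapse = ", ")))
  }
  bounds <- bounds[free]
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  if (any(!is.finite(c(lower, upper))) || any(upper <= lower)) {
    abort("bounds must be finite with lo < hi")
  }
  weights <- cost_weights(observed, target_set)

  # warm start at the unmodified model (gain 0, nominal circulation values),
  # clamped into the bounds, alongside any user-supplied candidates
  nominal <- do.call(bc_params, fixed)
  start <- pmin(pmax(c(0, nominal$R_autc, nominal$tau_c, nominal$tau_c2,
                       nominal$P_an, nominal$CBF_n), lower), upper)
  init <- rbind(start, if (!is.null(init)) matrix(init, ncol = length(free)))

  candidate_sim <- function(x) {
    pars <- c(as.list(setNames(x, free)), fixed)
    bc_simulate(inputs, do.call(bc_params, pars))
  }
  objective <- function(x) {
    sim <- tryCatch(candidate_sim(x), error = function(e) NULL)
    if (is.null(sim)) return(Inf)
    cost_total(evaluate_cost(observed, sim, target_set, weights))
  }

  sol <- ga_minimize(objective, lower, upper, control = ga, seed = seed,
                     init = init)
  if (polish) {
    # bounded simplex refinement of the GA's best candidate, in the GA's
    # unit-box coordinates (well conditioned across parameter magnitudes);
    # candidates outside the box are clamped
    span <- upper - lower
    clamped <- function(u) {
      u <- pmin(pmax(u, 0), 1)
      objective(lower + u * span)
    }
    u0 <- (sol$par - lower) / span
    pol <- stats::optim(u0, clamped, method = "Nelder-Mead",
                        control = list(maxit = polish_maxit,
                                       reltol = 1e-9))
    if (pol$value <= sol$value) {
      sol <- list(par = lower + pmin(pmax(pol$par, 0), 1) * span,
                  value = pol$value,
                  history = c(sol$history, pol$value))
    }
  }
  par <- setNames(sol$par, free)
  best_params <- do.call(bc_params, c(as.list(par), fixed))
  best_sim <- bc_simulate(inputs, best_params)
  structure(list(
    regime = regime, target_set = target_set,
    par = par, cost = evaluate_cost(observed, best_sim, target_set, weights),
    params = best_params, sim = best_sim, observed = as_tibble(observed),
    inputs = as_tibble(inputs), history = sol$history,
    bounds = bounds, seed = seed, ga = ga
  ), class = "bc_fit")
}

#' @export
print.bc_fit <- function(x, ...) {
  cat(sprintf("<bc_fit> %s regime, targets {%s}\n", x$regime,
              paste(x$target_set, collapse = ", ")))
  cat("  fitted parameters:\n")
  for (nm in names(x$par)) cat(sprintf("    %-8s %.5g\n", nm, x$par[[nm]]))
  cat(sprintf("  total cost: %.5g\n", cost_total(x$cost)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.bc_fit <- function(x, ...) {
  tibble(term = names(x$par), estimate = unname(x$par),
         lower = vapply(x$bounds, `[`, numeric(1), 1),
         upper = vapply(x$bounds, `[`, numeric(1), 2))
}

#' @export
glance.bc_fit <- function(x, ...) {
  pc <- plateau_change(x$sim, c("oxCCO", "CMRO2"))
  tibble(regime = x$regime,
         targets = paste(x$target_set, collapse = "+"),
         total_cost = cost_total(x$cost),
         oxCCO_plateau = pc$change[pc$channel == "oxCCO"],
         dCMRO2_pct = 100 * pc$change[pc$channel == "CMRO2"] /
           pc$baseline[pc$channel == "CMRO2"],
         generations = length(x$history), seed = x$seed)
}

#' Repeated genetic-algorithm fits with parameter-spread statistics
#'
#' Re-runs [fit_regime()] `repeats` times with seeds `seed + i - 1` and
#' aggregates the per-repeat fitted parameters. The standard deviation of a
#' parameter across repeats measures how reliably the optimization pins it
#' down (the study-scale setting is 200 repeats; desk-scale suites use
#' 5-20).
#'
#' @inheritParams fit_regime
#' @param repeats Number of independent GA runs (>= 2).
#' @return An object of class `bc_repeat` with the per-repeat parameter
#'   table, per-parameter mean/SD, and the best fit. Supports `tidy()`
#'   (summary statistics), `glance()` and `autoplot()`.
#' @export
repeat_fits <- function(observed, inputs, regime = c("supply", "demand"),
                        target_set = c("oxCCO", "TOI", "dCBF_pct"),
                        bounds = NULL, ga = ga_control(), seed = 1,
                        repeats = 200, fixed = list(), polish = TRUE) {
  if (repeats < 2) abort("repeats must be >= 2")
  regime <- match.arg(regime)
  fits <- purrr::map(seq_len(repeats), function(i) {
    fit_regime(observed, inputs, regime, target_set, bounds, ga,
               seed = seed + i - 1, fixed = fixed, polish = polish)
  })
  free <- bc_regime_free(regime)
  table <- purrr::map_dfr(seq_along(fits), function(i) {
    f <- fits[[i]]
    dplyr::bind_cols(tibble(repeat_id = i, cost = cost_total(f$cost)),
                     as_tibble(as.list(f$par)))
  })
  stats <- table |>
    tidyr::pivot_longer(dplyr::all_of(free), names_to = "term",
                        values_to = "value") |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$term, free))
  best <- fits[[which.min(table$cost)]]
  structure(list(regime = regime, target_set = best$target_set,
                 table = table, stats = stats, best = best,
                 repeats = as.integer(repeats), seed = seed),
            class = "bc_repeat")
}

#' @export
print.bc_repeat <- function(x, ...) {
  cat(sprintf("<bc_repeat> %s regime, targets {%s}, %d repeats\n",
              x$regime, paste(x$target_set, collapse = ", "), x$repeats))
  print(x$stats)
  cat(sprintf("  best cost: %.5g\n", min(x$table$cost)))
  invisible(x)
}

#' @export
tidy.bc_repeat <- function(x, ...) x$stats

#' @export
glance.bc_repeat <- function(x, ...) {
  g <- glance(x$best)
  g$repeats <- x$repeats
  g$cost_sd <- sd(x$table$cost)
  g
}
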