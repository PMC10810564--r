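#' Weighted mean-absolute-difference cost between observed and modelled traces
#'
#' The distance for each target signal is the mean absolute difference between
#' the observed and modelled channel over the full record. Because the
#' channels have different scales, each is weighted by the reciprocal of the
#' observed channel's standard deviation, which makes the three signals
#' contribute on equal, unit-free terms; the total is the weighted sum over
#' the target set only.
#'
#' @param observed Observed trace (columns `t`, `dCBF_pct`, `TOI`, `oxCCO`).
#' @param modelled Modelled trace on the same grid (e.g. a [bc_simulate()]
#'   result).
#' @param target_set Character vector of channels entering the total, from
#'   `c("oxCCO", "TOI", "dCBF_pct")`.
#' @param weights Optional named numeric vector of per-channel weights
#'   `gamma`; defaults to `1/sd(observed channel)`.
#' @return A tibble of class `bc_cost` with one row per target channel
#'   (`signal`, `distance`, `gamma`, `term`) and the weighted total as
#'   attribute `total` (also returned by [cost_total()]).
#' @examples
#' inp <- make_inputs(challenge_spec())
#' obs <- make_observations(inp, mode = "descriptive")
#' sim <- bc_simulate(inp, bc_params())
#' evaluate_cost(obs, sim, c("oxCCO", "TOI", "dCBF_pct"))
#' @export
evaluate_cost <- function(observed, modelled,
                          target_set = c("oxCCO", "TOI", "dCBF_pct"),
                          weights = NULL) {
  target_set <- match.arg(target_set, c("oxCCO", "TOI", "dCBF_pct"),
                          several.ok = TRUE)
  if (!length(target_set)) abort("target set must not be empty")
  if (nrow(observed) != nrow(modelled) ||
      max(abs(observed$t - modelled$t)) > 1e-9) {
    abort("observed and modelled traces must share the same time grid")
  }
  rows <- purrr::map_dfr(target_set, function(ch) {
    o <- observed[[ch]]; m <- modelled[[ch]]
    if (is.null(o) || is.null(m)) abort(paste0("missing channel ", ch))
    g <- if (!is.null(weights) && ch %in% names(weights)) {
      weights[[ch]]
    } else {
      s <- sd(o)
      if (!is.finite(s) || s == 0) {
        abort(paste0("cannot weight flat/degenerate observed channel ", ch))
      }
      1 / s
    }
    d <- mean(abs(o - m))
    tibble(signal = ch, distance = d, gamma = g, term = g * d)
  })
  structure(rows, class = c("bc_cost", class(rows)), total = sum(rows$term))
}

#' @rdname evaluate_cost
#' @param cost A `bc_cost` object.
#' @export
cost_total <- function(cost) attr(cost, "total")

#' Channel weights for a set of observations
#'
#' Inverse-SD weights frozen from an observed trace, so that repeated cost
#' evaluations against the same data use identical scaling.
#'
#' @param observed Observed trace.
#' @param target_set Channels to weight.
#' @return Named numeric vector of weights.
#' @export
cost_weights <- function(observed, target_set = c("oxCCO", "TOI", "dCBF_pct")) {
  sds <- vapply(target_set, function(ch) sd(observed[[ch]]), numeric(1))
  if (any(!is.finite(sds) | sds == 0)) {
    abort("cannot weight flat/degenerate observed channel")
  }
  setNames(1 / sds, target_set)
}
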