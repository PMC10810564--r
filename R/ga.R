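#' Genetic-algorithm settings
#'
#' Hyperparameters of the real-coded genetic algorithm used for parameter
#' fitting: tournament selection, simulated-binary (SBX) crossover, per-gene
#' Gaussian mutation and elitism. Defaults are conventional desk-scale
#' values; the study-scale optimization simply raises `pop_size` and
#' `generations`.
#'
#' @param pop_size Population size.
#' @param generations Number of generations.
#' @param p_crossover Per-pair SBX crossover probability.
#' @param p_mutation Per-gene mutation probability.
#' @param eta_c SBX distribution index (larger = offspring closer to parents).
#' @param mut_sd Mutation SD as a fraction of each parameter's bound range.
#' @param tournament Tournament size.
#' @param n_elite Number of elites copied unchanged each generation.
#' @return A list of class `bc_ga_control`.
#' @export
ga_control <- function(pop_size = 40, generations = 60,
                       p_crossover = 0.9, p_mutation = 0.1,
                       eta_c = 10, mut_sd = 0.1, tournament = 3,
                       n_elite = 2) {
  stopifnot(pop_size >= 4, generations >= 1, n_elite < pop_size)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 eta_c = eta_c, mut_sd = mut_sd,
                 tournament = as.integer(tournament),
                 n_elite = as.integer(n_elite)),
            class = "bc_ga_control")
}

# Minimize fn over box bounds with a seeded real-coded GA. The search runs
# in unit-box coordinates (all genes scaled to [0,1]) so crossover, mutation
# and the downstream simplex polish are well conditioned across parameters
# of very different magnitudes.
# init: optional matrix of candidate rows (original units) injected into the
# first population.
ga_minimize <- function(fn, lower, upper, control = ga_control(), seed = 1,
                        init = NULL) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  ctl <- control
  set.seed(as.integer(seed %% .Machine$integer.max))
  span <- upper - lower
  to_real <- function(u) lower + u * span

  pop <- matrix(runif(ctl$pop_size * d), nrow = ctl$pop_size)
  best_inject <- NULL
  if (!is.null(init)) {
    init <- matrix(init, ncol = d)
    n <- min(nrow(init), ctl$pop_size)
    u0 <- sweep(sweep(init[seq_len(n), , drop = FALSE], 2, lower), 2, span, "/")
    pop[seq_len(n), ] <- pmin(pmax(u0, 0), 1)
    # evaluate the injected candidates at their exact real coordinates as
    # well (the unit-box round trip is not bit-exact)
    for (k in seq_len(n)) {
      v <- fn(init[k, ])
      if (is.finite(v) && (is.null(best_inject) || v < best_inject$value)) {
        best_inject <- list(par = init[k, ], value = v)
      }
    }
  }
  clip <- function(m) pmin(pmax(m, 0), 1)
  evaluate <- function(m) apply(m, 1, function(u) {
    v <- fn(to_real(u))
    if (!is.finite(v)) Inf else v
  })

  cost <- evaluate(pop)
  if (all(!is.finite(cost))) abort("all initial GA candidates failed evaluation")
  history <- numeric(ctl$generations)

  for (g in seq_len(ctl$generations)) {
    ord <- order(cost)
    elite <- pop[ord[seq_len(ctl$n_elite)], , drop = FALSE]
    elite_cost <- cost[ord[seq_len(ctl$n_elite)]]

    pick <- function() {
      idx <- sample.int(ctl$pop_size, ctl$tournament, replace = TRUE)
      idx[which.min(cost[idx])]
    }
    n_child <- ctl$pop_size - ctl$n_elite
    children <- matrix(NA_real_, n_child, d)
    i <- 1
    while (i <= n_child) {
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (runif(1) < ctl$p_crossover) {
        # SBX crossover
        uu <- runif(d)
        beta <- ifelse(uu <= 0.5, (2 * uu)^(1 / (ctl$eta_c + 1)),
                       (1 / (2 * (1 - uu)))^(1 / (ctl$eta_c + 1)))
        c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
        c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
      } else {
        c1 <- p1; c2 <- p2
      }
      children[i, ] <- c1
      if (i + 1 <= n_child) children[i + 1, ] <- c2
      i <- i + 2
    }
    mut <- matrix(runif(n_child * d) < ctl$p_mutation, n_child, d)
    noise <- matrix(rnorm(n_child * d, 0, ctl$mut_sd), n_child, d)
    children <- clip(children + mut * noise)

    child_cost <- evaluate(children)
    pop <- rbind(elite, children)
    cost <- c(elite_cost, child_cost)
    if (all(!is.finite(cost))) abort("entire GA population failed evaluation")
    history[g] <- min(cost)
  }
  best <- which.min(cost)
  out <- list(par = to_real(pop[best, ]), value = cost[best],
              history = history)
  if (!is.null(best_inject) && best_inject$value < out$value) {
    out$par <- best_inject$par
    out$value <- best_inject$value
  }
  out
}
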