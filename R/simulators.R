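#' Default driver gradients for the built-in simulators
#'
#' Ten driver values per model, unequally spaced and denser near the
#' transition, running from benign conditions toward (but not past) the
#' tipping point. Data set 1: rainfall for the local positive feedback
#' lattice; data set 2: environmental quality `b` for the facilitation
#' cellular automaton; data set 3: rainfall (mm/day) for the
#' scale-dependent feedback model.
#'
#' @param model One of `"local_feedback"`, `"facilitation_ca"`,
#'   `"turing_pde"`.
#' @return Numeric vector of 10 driver values (benign first).
#' @export
default_driver_values <- function(model = c("local_feedback",
                                            "facilitation_ca",
                                            "turing_pde")) {
  model <- match.arg(model)
  switch(model,
    local_feedback = c(3.0, 2.6, 2.3, 2.1, 1.98, 1.92, 1.88, 1.85, 1.82, 1.80),
    facilitation_ca = c(0.90, 0.80, 0.70, 0.62, 0.55, 0.50, 0.46, 0.43, 0.41, 0.39),
    turing_pde = c(1.30, 1.24, 1.18, 1.12, 1.06, 1.01, 0.96, 0.92, 0.88, 0.85))
}

# internal: shared driver/seed validation
check_driver_values <- function(driver_values) {
  if (length(driver_values) < 2L) {
    abort_spatialews("Need at least two driver values.", "validation")
  }
  d <- diff(driver_values)
  if (!(all(d > 0) || all(d < 0))) {
    abort_spatialews("Driver values must be monotone.", "validation")
  }
  driver_values
}

make_sequence <- function(mats, driver_values, value_kind, model) {
  snaps <- lapply(seq_along(mats), function(i) {
    spatial_grid(mats[[i]], value_kind = value_kind, boundary = "periodic",
                 label = sprintf("%s driver=%g", model, driver_values[[i]]))
  })
  out <- gradient_sequence(snaps, stress = seq_along(snaps),
                           direction = "toward_transition")
  attr(out, "driver_values") <- driver_values
  attr(out, "model") <- model
  out
}

#' Simulate the local positive feedback lattice (data set 1)
#'
#' A stochastic lattice of vegetation biomass coupled to local water:
#' biomass grows logistically at a rate set by the local water level
#' (replenished by rainfall, depleted by plant uptake), is lost to a
#' saturating grazing term, and both biomass and water diffuse between
#' 4-neighbour sites (periodic boundary); multiplicative noise forces the
#' biomass. The non-spatial skeleton is the classic grazed-logistic fold:
#' as rainfall drops below a threshold the vegetated state vanishes and the
#' lattice collapses nearly synchronously to a bare state, with no patchy
#' structure on the way — the textbook setting for the generic indicators.
#'
#' The state is carried from one driver value to the next (as along a slow
#' degradation gradient) with a relaxation period before each snapshot.
#'
#' @param grid_size Lattice edge (default 100).
#' @param driver_values Rainfall gradient, decreasing (default
#'   [default_driver_values()]).
#' @param params Named overrides of the model rates: `rw` (water loss),
#'   `lambda` (uptake), `rho` (growth conversion), `K` (carrying capacity),
#'   `c`, `h2` (grazing maximum and half-saturation squared), `Dv`, `Dw`
#'   (diffusion), `sigma` (noise), `v0` (initial biomass).
#' @param dt Euler step (default 0.1).
#' @param relax_first,relax_next Relaxation time before the first / each
#'   subsequent snapshot.
#' @param seed Optional integer seed (fixed seed => identical sequence).
#' @return A `gradient_sequence` of continuous biomass snapshots, stress =
#'   degradation rank, with attributes `driver_values` and `model`.
#' @export
simulate_local_feedback <- function(grid_size = 100L,
                                    driver_values = NULL,
                                    params = list(), dt = 0.1,
                                    relax_first = 100, relax_next = 50,
                                    seed = NULL) {
  if (is.null(driver_values)) driver_values <- default_driver_values("local_feedback")
  check_driver_values(driver_values)
  p <- utils::modifyList(list(rw = 1, lambda = 0.12, rho = 0.7, K = 10,
                              c = 2, h2 = 0.25, Dv = 0.05, Dw = 0.05,
                              sigma = 0.05, v0 = 8), params)
  if (any(unlist(p[c("rw", "lambda", "rho", "K", "c", "h2", "Dv", "Dw")]) < 0)) {
    abort_spatialews("All rate parameters must be non-negative.", "validation")
  }
  if (!is.null(seed)) set.seed(seed)
  mats <- sim_local_cpp(as.integer(grid_size), as.numeric(driver_values), p,
                        dt, relax_first, relax_next)
  make_sequence(mats, driver_values, "continuous", "local_feedback")
}

#' Simulate the facilitation cellular automaton (data set 2)
#'
#' A three-state stochastic cellular automaton — vegetated (+), empty (o),
#' degraded (-) — on a periodic lattice with 4-neighbour interactions.
#' Empty cells are colonized at a rate increasing in both global and local
#' vegetated density (seed dispersal) and capped by environmental quality
#' `b` net of global competition; vegetated cells die at rate `m`; empty
#' cells erode to degraded at rate `d`; degraded cells regenerate at a base
#' rate `r` boosted by vegetated neighbours (`f * q`): that local
#' facilitation is what makes vegetated cells cluster into scale-free
#' patches. As `b` drops, vegetation collapses to a desert.
#'
#' Updates are synchronous with transition probabilities evaluated on the
#' previous state (default) or asynchronous single-cell updates
#' (`async = TRUE`, one step = `grid_size^2` single updates).
#'
#' @param grid_size Lattice edge (default 100).
#' @param driver_values Environmental quality `b`, decreasing.
#' @param params Named overrides: `m`, `d`, `r`, `f`, `delta`
#'   (global-dispersal fraction), `c` (global competition).
#' @param steps_first,steps_next Update steps before the first / each
#'   subsequent snapshot.
#' @param async Asynchronous updating.
#' @param seed Optional integer seed.
#' @return A `gradient_sequence` of occupancy (0/1) snapshots (vegetated vs
#'   not); the raw three-state lattices (+1/0/-1) are in
#'   `attr(, "state_grids")`.
#' @export
simulate_facilitation_ca <- function(grid_size = 100L,
                                     driver_values = NULL,
                                     params = list(),
                                     steps_first = 300L, steps_next = 150L,
                                     async = FALSE, seed = NULL) {
  if (is.null(driver_values)) driver_values <- default_driver_values("facilitation_ca")
  check_driver_values(driver_values)
  p <- utils::modifyList(list(m = 0.1, d = 0.2, r = 0.01, f = 0.9,
                              delta = 0.1, c = 0.3), params)
  probs <- unlist(p[c("m", "d", "r", "delta", "c", "f")])
  if (any(probs < 0) || any(unlist(p[c("m", "d", "r", "delta")]) > 1)) {
    abort_spatialews("CA probabilities must lie in [0, 1].", "validation")
  }
  if (p$r + p$f > 1) {
    abort_spatialews("Regeneration r + f must not exceed 1.", "validation")
  }
  if (any(driver_values > 1) || any(driver_values < 0)) {
    abort_spatialews("Environmental quality b must lie in [0, 1].",
                     "validation")
  }
  if (!is.null(seed)) set.seed(seed)
  states <- sim_ca_cpp(as.integer(grid_size), as.numeric(driver_values), p,
                       as.integer(steps_first), as.integer(steps_next), async)
  occ <- lapply(states, function(s) (s == 1L) * 1.0)
  out <- make_sequence(occ, driver_values, "discrete_occupancy",
                       "facilitation_ca")
  attr(out, "state_grids") <- states
  out
}

#' Simulate the scale-dependent feedback model (data set 3)
#'
#' Three coupled PDEs for plant biomass, soil water and surface water on a
#' periodic lattice (explicit Euler, 5-point Laplacian): plants grow by
#' soil-water uptake and die at a constant rate; infiltration of surface
#' into soil water is enhanced under vegetation; surface water arrives as
#' rainfall and diffuses fast. Short-range facilitation (infiltration)
#' plus long-range competition (water depletion) is the Turing mechanism
#' that produces the canonical gaps -> labyrinths -> spots sequence as
#' rainfall declines, before a collapse to bare soil.
#'
#' The time step must satisfy the explicit diffusion stability bound
#' `dt <= dx^2 / (4 max(D))`; violating it is a configuration error.
#'
#' @param grid_size Lattice edge (default 100).
#' @param driver_values Rainfall gradient (mm/day), decreasing.
#' @param params Named overrides of the standard parameterization: `c`
#'   (conversion), `gmax`, `k1` (uptake), `d` (mortality), `alpha`, `W0`,
#'   `k2` (infiltration), `rw` (soil-water loss), `Dp`, `Dw`, `Do`
#'   (diffusion, m^2/day), `sigma` (noise), `p0` (initial biomass).
#' @param dx Cell size in metres (default 5; the pattern wavelength is
#'   ~40-60 m, so the default grid spans ~8-10 wavelengths).
#' @param dt Euler step in days (default 0.05).
#' @param relax_first,relax_next Relaxation time (days) before the first /
#'   each subsequent snapshot.
#' @param seed Optional integer seed.
#' @return A `gradient_sequence` of continuous biomass snapshots.
#' @export
simulate_turing_pde <- function(grid_size = 100L,
                                driver_values = NULL,
                                params = list(), dx = 5, dt = 0.05,
                                relax_first = 500, relax_next = 150,
                                seed = NULL) {
  if (is.null(driver_values)) driver_values <- default_driver_values("turing_pde")
  check_driver_values(driver_values)
  p <- utils::modifyList(list(c = 10, gmax = 0.05, k1 = 5, d = 0.25,
                              alpha = 0.2, W0 = 0.2, k2 = 5, rw = 0.2,
                              Dp = 0.1, Dw = 0.1, Do = 100,
                              sigma = 0.01, p0 = 10), params)
  if (any(unlist(p[c("c", "gmax", "k1", "d", "alpha", "W0", "k2", "rw",
                     "Dp", "Dw", "Do")]) < 0)) {
    abort_spatialews("All rate parameters must be non-negative.", "validation")
  }
  cfl <- dx^2 / (4 * max(p$Dp, p$Dw, p$Do))
  if (dt > cfl) {
    abort_spatialews(
      sprintf("dt = %g violates the diffusion stability bound dx^2/(4 max D) = %g.",
              dt, cfl),
      "configuration")
  }
  if (!is.null(seed)) set.seed(seed)
  mats <- sim_turing_cpp(as.integer(grid_size), as.numeric(driver_values), p,
                         dx, dt, relax_first, relax_next)
  make_sequence(mats, driver_values, "continuous", "turing_pde")
}
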