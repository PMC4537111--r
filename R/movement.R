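#' Movement decision parameters
#'
#' The three heritable traits of the foraging decision rule:
#' * `alpha` — neighbor-discount: weight given to second-tier information
#'   (the neighborhood means of a candidate cell) in the cell-value function.
#' * `delta` — competition-tradeoff: per-competitor penalty converting
#'   occupancy counts into resource-equivalent value.
#' * `rho` — movement threshold: an agent leaves its cell only when some
#'   neighbor's value reaches `1/rho` times its current cell's (positive)
#'   value; see [decide_move()].
#'
#' No bounds are enforced: these values evolve freely and mutation can drive
#' them negative (negative evolved competition-tradeoff values do occur).
#'
#' @param alpha,delta,rho finite numeric trait values.
#' @return An object of class `movement_params`.
#' @export
movement_params <- function(alpha, delta, rho) {
  v <- c(alpha = alpha, delta = delta, rho = rho)
  if (any(!is.finite(v))) stop("movement traits must be finite", call. = FALSE)
  structure(as.list(v), class = "movement_params")
}

#' Perceive the local environment
#'
#' Builds the environmental vector an agent uses to decide its move: for
#' slot 0 (its current cell) and each Moore neighbor, the cell's resource
#' `R`, occupancy `J`, neighborhood-mean resource `R_M` and neighborhood-mean
#' occupancy `J_M`, all read from the synchronous time-`t` landscape state
#' (occupancy counts are pre-movement).
#'
#' @param agent_location the agent's cell index.
#' @param landscape a `landscape` with up-to-date `R` and `J`.
#' @param self_excluded if `TRUE` (default) the focal agent is subtracted
#'   from the occupancy field before any occupancy quantity is computed, so
#'   `J` and `J_M` count competitors only (a lone agent perceives an empty
#'   world); if `FALSE` the raw occupancy counts are used.
#' @return list of class `environment_vector` with elements `cells` (cell
#'   indices, first entry the current cell), `R`, `J`, `R_M`, `J_M`; each of
#'   length 1 + number of Moore neighbors (9 on a toroidal grid).
#' @export
sense_environment <- function(agent_location, landscape, self_excluded = TRUE) {
  grid <- landscape$grid
  cells <- c(agent_location, moore_neighbors(agent_location, grid))
  J_field <- as.numeric(landscape$J)
  if (self_excluded) J_field[agent_location] <- J_field[agent_location] - 1
  structure(list(
    cells = cells,
    R = landscape$R[cells],
    J = J_field[cells],
    R_M = vapply(cells, function(k) neighborhood_mean(landscape$R, k, grid),
                 numeric(1)),
    J_M = vapply(cells, function(k) neighborhood_mean(J_field, k, grid),
                 numeric(1))
  ), class = "environment_vector")
}

#' Value assigned to a candidate cell
#'
#' \deqn{V = R - \delta J + \alpha (R_M - \delta J_M)}
#' Resources count positively, competitors are penalized at `delta`
#' resource-equivalents each, and the same tradeoff applied to the cell's
#' neighborhood means is discounted by `alpha`. The value may be negative.
#'
#' @param R resource in the cell.
#' @param J occupancy of the cell.
#' @param R_M neighborhood-mean resource.
#' @param J_M neighborhood-mean occupancy.
#' @param params a [movement_params()].
#' @return scalar (vectorized over its arguments).
#' @export
cell_value <- function(R, J, R_M, J_M, params) {
  R - params$delta * J + params$alpha * (R_M - params$delta * J_M)
}

#' Stay-or-move decision
#'
#' Computes the value `V` of the current cell (slot 0) and of each Moore
#' neighbor, then applies the movement rule: **stay** if and only if the
#' current cell's value is positive and `rho * V_l < V_0` strictly for
#' every neighbor `l` — i.e. an agent leaves only when some neighbor is at
#' least `1/rho` times as valuable as its current cell. Small `rho` thus
#' means a sedentary type that resists moving; `rho` near 1 means a
#' restless type that moves whenever any neighbor is merely better.
#' Otherwise it **relocates** to the slot with the largest value (slot 0
#' meaning "move in place": the agent keeps its cell but is charged the
#' movement cost and does not extract that tick). Argmax ties are broken
#' uniformly at random.
#'
#' A neighbor with negative value always satisfies the stay test when the
#' current value is positive and `rho >= 0`; the equality case
#' `rho * V_l = V_0` triggers a move.
#'
#' @param env an `environment_vector` from [sense_environment()].
#' @param params a [movement_params()].
#' @return list of class `move_decision` with elements `kind` (`"STAY"` or
#'   `"RELOCATE"`), `target` (slot index, 0-based; `NA` for STAY), `cell`
#'   (destination cell index) and `V` (the computed values).
#' @export
decide_move <- function(env, params) {
  V <- cell_value(env$R, env$J, env$R_M, env$J_M, params)
  n_nb <- length(V) - 1L
  if (V[1L] > 0 && all(params$rho * V[-1L] < V[1L])) {
    return(structure(list(kind = "STAY", target = NA_integer_,
                          cell = env$cells[1L], V = V),
                     class = "move_decision"))
  }
  target <- .argmax_random_tie(V) - 1L
  structure(list(kind = "RELOCATE", target = target,
                 cell = env$cells[target + 1L], V = V),
            class = "move_decision")
}

# argmax with uniform random tie-break; a single unif draw is spent only
# when a tie exists so seeded trajectories stay reproducible and the
# compiled engine can mirror the draw order exactly
.argmax_random_tie <- function(V) {
  idx <- which(V == max(V))
  if (length(idx) == 1L) return(idx)
  idx[floor(stats::runif(1) * length(idx)) + 1L]
}
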