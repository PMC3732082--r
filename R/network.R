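#' Reaction-network construction and mass-action derivatives
#'
#' A `rod_network` is the single executable model object: a species table, a
#' list of elementary reactions, a parameter set and a compartment volume.
#' Reversible processes are stored as two irreversible reactions. Every rate
#' law is either strict mass action (`k` times the product of the rate-species
#' state values) or one of a small set of auxiliary laws used by the
#' cGMP/Ca2+ back end and by the stimulus:
#'
#' * `"mass_action"`: `k * prod(y[rate_species])`
#' * `"hill_inhib"` : `k / (1 + (y[s]/K)^m)` (Ca2+-inhibited cGMP synthesis)
#' * `"power"`      : `k * y[s]^m` (channel-gated Ca2+ influx)
#' * `"constant"`   : `k`
#' * `"gated"`      : `k * y[s]` inside a time window, 0 outside (photon flux)
#'
#' Species changes are real-valued weights per unit reaction rate, so a
#' reaction whose rate is computed in molecules/s can increment a micromolar
#' species with weight `1/MOLEC_PER_UM` (the model's mixed-unit scheme).
#'
#' @name rod_network
NULL

law_codes <- c(mass_action = 0, hill_inhib = 1, gated = 2, constant = 3,
               power = 4, mass_exp = 5)

#' Create a single reaction
#'
#' @param name Reaction identifier (unique within a network).
#' @param k Non-negative rate constant (units depend on the rate law and on the
#'   units of the rate species).
#' @param rate_species Character vector (length 0-3) of species whose state
#'   values enter the rate law; repeat a name for a squared dependence.
#' @param changes Named numeric vector: per-unit-rate increments of species.
#' @param law One of `"mass_action"`, `"hill_inhib"`, `"power"`, `"constant"`,
#'   `"gated"`.
#' @param p1,p2 Auxiliary parameters (`hill_inhib`: K and m; `power`: exponent
#'   in p1; `gated`: window start/end in seconds).
#' @param k_name Optional name of the parameter this `k` was drawn from (used
#'   by diagnostics and SBML export).
#' @return A `rod_reaction` list.
#' @export
reaction <- function(name, k, rate_species, changes, law = "mass_action",
                     p1 = 0, p2 = 0, k_name = NA_character_) {
  if (!law %in% names(law_codes)) stop("unknown rate law: ", law, call. = FALSE)
  if (!is.numeric(k) || length(k) != 1 || is.na(k) || k < 0)
    stop("reaction '", name, "': rate constant must be a single non-negative number",
         call. = FALSE)
  if (length(rate_species) > 3)
    stop("at most 3 rate species are supported", call. = FALSE)
  stopifnot(is.numeric(changes), !is.null(names(changes)))
  structure(list(name = name, k = k, rate_species = as.character(rate_species),
                 changes = changes, law = law, p1 = p1, p2 = p2,
                 k_name = k_name),
            class = "rod_reaction")
}

#' Create a mass-action reaction from reactant/product stoichiometries
#'
#' Builds the rate law (`k` times the product of reactant state values with
#' stoichiometric multiplicity) and the signed species increments.
#'
#' @param name Reaction identifier.
#' @param k Rate constant (per-molecule units when reactants are counts).
#' @param reactants,products Named numeric vectors of stoichiometries.
#' @param k_name Optional source parameter name.
#' @return A `rod_reaction`.
#' @export
mass_action <- function(name, k, reactants, products = numeric(), k_name = NA_character_) {
  rs <- rep(names(reactants), times = reactants)
  ch <- -reactants
  for (p in names(products)) {
    ch[p] <- if (p %in% names(ch)) ch[p] + products[[p]] else products[[p]]
  }
  ch <- ch[ch != 0]
  reaction(name, k, rs, ch, k_name = k_name)
}

#' Assemble a reaction network
#'
#' @param species A data frame with columns `name`, `initial` (state value in
#'   the species' own unit), `unit` (`"count"` or `"uM"`).
#' @param reactions List of [reaction()] objects.
#' @param params Named list/vector of model parameters (kept for provenance).
#' @param volume_pl Compartment volume in pL.
#' @param conservation Named list; each element is a named numeric vector of
#'   subunit weights defining a conserved weighted total.
#' @return A `rod_network` object.
#' @export
rod_network <- function(species, reactions, params = list(), volume_pl = 1,
                        conservation = list()) {
  species <- tibble::as_tibble(species)
  stopifnot(all(c("name", "initial", "unit") %in% names(species)))
  if (anyDuplicated(species$name)) stop("species names must be unique", call. = FALSE)
  if (any(species$initial < 0)) stop("initial amounts must be non-negative", call. = FALSE)
  idx <- stats::setNames(seq_len(nrow(species)), species$name)
  for (r in reactions) {
    bad <- setdiff(c(r$rate_species, names(r$changes)), species$name)
    if (length(bad))
      stop("reaction '", r$name, "' references unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  for (g in names(conservation)) {
    bad <- setdiff(names(conservation[[g]]), species$name)
    if (length(bad))
      stop("conserved group '", g, "' references unknown species", call. = FALSE)
  }
  structure(list(species = species, reactions = reactions, params = params,
                 volume_pl = volume_pl, conservation = conservation,
                 .index = idx),
            class = "rod_network")
}

#' @export
print.rod_network <- function(x, ...) {
  cat("<rod_network>: ", nrow(x$species), " species, ", length(x$reactions),
      " reactions, volume ", x$volume_pl, " pL\n", sep = "")
  invisible(x)
}

#' Dark-state (initial) vector of a network
#'
#' @param network A `rod_network`.
#' @return Named numeric state vector in model units.
#' @export
initial_state <- function(network) {
  stats::setNames(network$species$initial, network$species$name)
}

reaction_rate <- function(r, t, y, idx) {
  switch(r$law,
    mass_action = r$k * prod(y[idx[r$rate_species]]),
    hill_inhib = r$k / (1 + (y[idx[r$rate_species[1]]] / r$p1)^r$p2),
    power = r$k * max(y[idx[r$rate_species[1]]], 0)^r$p1,
    constant = r$k,
    gated = if (t >= r$p1 && t < r$p2) r$k * y[idx[r$rate_species[1]]] else 0,
    mass_exp = {
      # mass action over all but the last rate species, times
      # exp(p1 * (x_last / p2 - 1)) -- the Ca2+-modulated forward law
      ns <- length(r$rate_species)
      r$k * prod(y[idx[r$rate_species[-ns]]]) *
        exp(r$p1 * (y[idx[r$rate_species[ns]]] / r$p2 - 1))
    }
  )
}

#' Build the derivative function of a network
#'
#' Returns a pure-R function `f(t, y)` giving d(state)/dt as the signed sum of
#' all reaction rates. This is the reference implementation; [integrate_network()]
#' normally evaluates the same network through the compiled back end.
#'
#' @param network A `rod_network`.
#' @return Function of `(t, y)` returning a named derivative vector.
#' @export
build_derivatives <- function(network) {
  idx <- network$.index
  reactions <- network$reactions
  n <- nrow(network$species)
  # precompute integer indices
  pre <- lapply(reactions, function(r) {
    list(r = r, ci = unname(idx[names(r$changes)]), cw = unname(r$changes))
  })
  function(t, y) {
    dy <- numeric(n)
    for (p in pre) {
      v <- reaction_rate(p$r, t, y, idx)
      dy[p$ci] <- dy[p$ci] + p$cw * v
    }
    names(dy) <- network$species$name
    dy
  }
}

# Pack the network into a flat double vector for the compiled derivative
# evaluator (see src/massaction.c). Fixed record width per reaction.
REC_W <- 21
pack_network <- function(network) {
  idx <- network$.index
  nr <- length(network$reactions)
  out <- numeric(1 + nr * REC_W)
  out[1] <- nr
  for (i in seq_len(nr)) {
    r <- network$reactions[[i]]
    ci <- unname(idx[names(r$changes)])
    cw <- unname(r$changes)
    if (length(ci) > 6) stop("reaction '", r$name, "': more than 6 species changes")
    rs <- unname(idx[r$rate_species])
    rec <- c(law_codes[[r$law]], r$k, r$p1, r$p2,
             length(rs), c(rs, numeric(3 - length(rs))),
             length(ci),
             as.vector(rbind(c(ci, numeric(6 - length(ci))),
                             c(cw, numeric(6 - length(cw))))))
    out[(2 + (i - 1) * REC_W):(1 + i * REC_W)] <- rec
  }
  out
}

#' Integrate a network trajectory
#'
#' Adaptive stiff integration (LSODA via \pkg{deSolve}) of the network ODEs.
#' Defaults follow the package's integration contract: `rtol = 1e-8`,
#' `atol = 1e-12` on the molecule-count scale.
#'
#' @param network A `rod_network`.
#' @param state0 Initial named state vector (defaults to the species table).
#' @param t_grid Strictly increasing output times (s).
#' @param rtol,atol Relative/absolute solver tolerances.
#' @param compiled Use the compiled derivative evaluator (default TRUE).
#' @param ... Passed to [deSolve::lsoda()].
#' @return A tibble with column `time` and one column per species.
#' @export
integrate_network <- function(network, state0 = initial_state(network),
                              t_grid, rtol = 1e-8, atol = 1e-12,
                              compiled = TRUE, ...) {
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing", call. = FALSE)
  if (any(state0 < 0)) stop("initial state must be non-negative", call. = FALSE)
  state0 <- state0[network$species$name]
  if (anyNA(state0)) stop("state0 must name every species", call. = FALSE)
  # tcrit stops the solver from stepping past the grid end into a stimulus
  # gate discontinuity (trajectories are integrated piecewise between gates)
  if (compiled) {
    out <- deSolve::lsoda(y = unname(state0), times = t_grid,
                          func = "rc_derivs", dllname = "rodcascade",
                          initfunc = "rc_initmod", parms = pack_network(network),
                          rtol = rtol, atol = atol, tcrit = max(t_grid),
                          maxsteps = 20000, ...)
  } else {
    f <- build_derivatives(network)
    out <- deSolve::lsoda(y = unname(state0), times = t_grid,
                          func = function(t, y, p) list(unname(f(t, y))),
                          parms = NULL, rtol = rtol, atol = atol,
                          tcrit = max(t_grid), maxsteps = 20000, ...)
  }
  if (out[nrow(out), 1] < max(t_grid) ||
      (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0))
    stop("stiff integration failed at t = ", signif(out[nrow(out), 1], 6),
         " s (istate = ", attr(out, "istate")[1],
         "); consider loosening tolerances or shortening the horizon",
         call. = FALSE)
  colnames(out) <- c("time", network$species$name)
  tibble::as_tibble(as.data.frame(out))
}

#' Conservation residuals of a trajectory
#'
#' For every conserved group, the maximum relative deviation of the weighted
#' total from its value at the first output time.
#'
#' @param network A `rod_network` with declared conservation groups.
#' @param traj Trajectory tibble from [integrate_network()].
#' @return Named numeric vector of maximum relative deviations.
#' @export
conservation_residuals <- function(network, traj) {
  vapply(network$conservation, function(w) {
    tot <- as.matrix(traj[names(w)]) %*% w
    ref <- tot[1]
    if (ref == 0) return(max(abs(tot)))
    max(abs(tot - ref) / abs(ref))
  }, numeric(1))
}

#' Solve for a steady state by relaxation
#'
#' Integrates the network (with no stimulus window active) until the maximum
#' scaled derivative falls below `tol`, respecting all conserved totals of the
#' initial guess.
#'
#' @param network A `rod_network`.
#' @param guess Initial named state (defaults to the species table).
#' @param tol Convergence tolerance on `max |dy| / max(|y|, 1)`.
#' @param t_relax Relaxation block length in seconds.
#' @param max_blocks Maximum number of relaxation blocks.
#' @return Named steady-state vector.
#' @export
find_steady_state <- function(network, guess = initial_state(network),
                              tol = 1e-7, t_relax = 200, max_blocks = 20) {
  if (any(guess < 0)) stop("guess must be non-negative", call. = FALSE)
  f <- build_derivatives(network)
  y <- guess[network$species$name]
  resid <- function(y) max(abs(f(0, y)) / pmax(abs(y), 1))
  if (resid(y) < tol) return(y)
  for (i in seq_len(max_blocks)) {
    traj <- integrate_network(network, y, t_grid = c(0, t_relax / 2, t_relax))
    y <- pmax(unlist(traj[nrow(traj), -1]), 0)
    if (resid(y) < tol) return(y)
  }
  stop("steady state did not converge (residual ", signif(resid(y), 3),
       "); a longer relaxation may be needed", call. = FALSE)
}
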