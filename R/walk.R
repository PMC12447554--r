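## Lattice Markov model of four-way branch migration with bulge diffusion.
##
## The junction coordinate j runs over 0..N base pairs of the branch
## migration domain.  Bulge coordinates x run over 0..M in the
## displacement-domain frame: 0 = adjacent to the junction (where the
## bulge assists migration), M = beyond the final position.  With a bulge
## at 0 the junction migrates through half-steps: full state j, an
## intermediate "edge" state between j and j+1 (half_step = TRUE), then
## j+1; each elementary half-step fires at rate_half_step, so two
## half-steps complete one migration step and return the bulge to 0.
## Without a bulge at the core the junction takes full steps at
## rate_migration_nobulge.  Bulges hop x -> x +/- 1 at rate_bulge_hop
## (modulated by an optional per-position energy table via the symmetric
## rule r = rate * exp(-(E_y - E_x)/2), which obeys detailed balance with
## stationary weights exp(-E)); hops are suspended while a half-step is in
## flight.  This is a coarse abstract analogue of the molecular picture,
## with free rate parameters -- not a nucleotide-level model.

#' Configuration of the branch-migration lattice walk
#'
#' @param domain_length Number of branch-migration steps `N` (>= 2); the
#'   junction coordinate runs over `0..N` and `N` is complete displacement.
#' @param n_bulges Number of bulges: 0, 1, or 2.
#' @param rate_migration_nobulge Elementary full junction step rate
#'   (s^-1) when no bulge sits at the core.
#' @param rate_half_step Elementary half-migration step rate (s^-1) when
#'   a bulge sits at position 0.
#' @param rate_bulge_hop Elementary bulge diffusion hop rate (s^-1).
#' @param bulge_domain_length Rightmost bulge coordinate `M`; defaults to
#'   20 for one bulge and 21 for two bulges.
#' @param absorb_at_end If `TRUE`, `j = N` (complete displacement) is
#'   absorbing; otherwise it reflects.
#' @param freeze_junction If `TRUE` the junction never moves and only
#'   bulge hops occur (the setting used for occupancy profiles).
#' @param energy Optional numeric vector of per-position bulge energies
#'   (units of kT, length `M + 1`) biasing the hops; default unbiased.
#' @param seed Integer seed used by [gillespie_run()].
#' @return An object of class `fw_walk_config`.
#' @export
walk_config <- function(domain_length, n_bulges = 1L,
                        rate_migration_nobulge = 0.1,
                        rate_half_step = 10,
                        rate_bulge_hop = 1,
                        bulge_domain_length = NULL,
                        absorb_at_end = TRUE,
                        freeze_junction = FALSE,
                        energy = NULL,
                        seed = 1L) {
  N <- as.integer(domain_length)
  if (is.na(N) || N < 2L) .fw_stop("'domain_length' must be an integer >= 2")
  n_bulges <- as.integer(n_bulges)
  if (!(n_bulges %in% 0:2)) .fw_stop("'n_bulges' must be 0, 1, or 2")
  for (nm in c("rate_migration_nobulge", "rate_half_step", "rate_bulge_hop")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      .fw_stop("'%s' must be a single non-negative rate", nm)
  }
  if (is.null(bulge_domain_length))
    bulge_domain_length <- if (n_bulges == 2L) 21L else 20L
  M <- as.integer(bulge_domain_length)
  if (is.na(M) || M < n_bulges) .fw_stop("'bulge_domain_length' too small")
  if (is.null(energy)) energy <- rep(0, M + 1L)
  if (!is.numeric(energy) || length(energy) != M + 1L || anyNA(energy))
    .fw_stop("'energy' must be a numeric vector of length bulge_domain_length + 1")
  structure(list(domain_length = N, n_bulges = n_bulges,
                 rate_migration_nobulge = rate_migration_nobulge,
                 rate_half_step = rate_half_step,
                 rate_bulge_hop = rate_bulge_hop,
                 bulge_domain_length = M,
                 absorb_at_end = isTRUE(absorb_at_end),
                 freeze_junction = isTRUE(freeze_junction),
                 energy = as.numeric(energy),
                 seed = as.integer(seed)),
            class = "fw_walk_config")
}

#' Lattice state of the walk
#'
#' @param junction Junction position `j` in `0..N`.
#' @param bulges Integer vector of bulge positions (length `n_bulges`,
#'   distinct, each in `0..M`); `NULL` means no bulges.
#' @param half_step `TRUE` if the junction is in the intermediate
#'   configuration between `junction` and `junction + 1` (only possible
#'   with a bulge at position 0).
#' @return An object of class `fw_walk_state`.
#' @export
walk_state <- function(junction = 0L, bulges = NULL, half_step = FALSE) {
  structure(list(junction = as.integer(junction),
                 bulges = if (is.null(bulges)) integer(0) else
                   sort(as.integer(bulges)),
                 half_step = isTRUE(half_step)),
            class = "fw_walk_state")
}

#' Default initial state: junction at 0, bulges packed at the junction
#' @param config A [walk_config()].
#' @return A [walk_state()].
#' @export
initial_state <- function(config) {
  walk_state(junction = 0L,
             bulges = if (config$n_bulges > 0L) seq_len(config$n_bulges) - 1L
             else NULL,
             half_step = FALSE)
}

.fw_check_walk_state <- function(state, config) {
  if (!inherits(state, "fw_walk_state")) .fw_stop("'state' must be an fw_walk_state")
  N <- config$domain_length; M <- config$bulge_domain_length
  if (state$junction < 0L || state$junction > N)
    .fw_stop("junction position %d outside 0..%d", state$junction, N)
  if (length(state$bulges) != config$n_bulges)
    .fw_stop("state has %d bulge position(s), config expects %d",
             length(state$bulges), config$n_bulges)
  if (length(state$bulges) > 0L &&
      (any(state$bulges < 0L) || any(state$bulges > M)))
    .fw_stop("bulge position outside 0..%d", M)
  if (anyDuplicated(state$bulges))
    .fw_stop("bulge positions must be distinct")
  if (state$half_step) {
    if (state$junction >= N)
      .fw_stop("half-step intermediate cannot sit at the absorbing end")
    if (!any(state$bulges == 0L))
      .fw_stop("half-step intermediate requires a bulge at position 0")
  }
  invisible(state)
}

.fw_state_key <- function(state) {
  paste(state$junction, as.integer(state$half_step),
        paste(state$bulges, collapse = ","), sep = "|")
}

#' Enumerate all allowed transitions out of a state
#'
#' Returns every move the walk can make from `state`:
#' junction half-steps at `rate_half_step` when a bulge occupies position
#' 0 (entering or resolving the intermediate configuration; two
#' half-steps advance the junction one step and return the bulge to 0),
#' plain junction steps at `rate_migration_nobulge` when no bulge is at
#' the core, and bulge hops at `rate_bulge_hop` (suspended while a
#' half-step is in flight; under `freeze_junction` only hops are
#' returned).  `j = N` is absorbing when `absorb_at_end` and yields no
#' moves.
#'
#' @param state A [walk_state()], valid under `config`.
#' @param config A [walk_config()].
#' @return A list of `list(state = <fw_walk_state>, rate = <numeric>)`.
#' @export
enumerate_moves <- function(state, config) {
  if (!inherits(config, "fw_walk_config")) .fw_stop("'config' must be an fw_walk_config")
  .fw_check_walk_state(state, config)
  N <- config$domain_length; M <- config$bulge_domain_length
  j <- state$junction; b <- state$bulges
  moves <- list()
  add <- function(st, rate) {
    if (rate > 0) moves[[length(moves) + 1L]] <<- list(state = st, rate = rate)
  }

  if (config$absorb_at_end && j == N && !state$half_step) return(list())

  if (state$half_step) {
    ## resolve the intermediate forward or back; bulge stays at the core
    add(walk_state(j, b, FALSE), config$rate_half_step)
    add(walk_state(j + 1L, b, FALSE), config$rate_half_step)
    return(moves)
  }

  if (!config$freeze_junction) {
    assisted <- any(b == 0L)
    if (assisted) {
      if (j < N) add(walk_state(j, b, TRUE), config$rate_half_step)
      if (j > 0L) add(walk_state(j - 1L, b, TRUE), config$rate_half_step)
    } else {
      if (j < N) add(walk_state(j + 1L, b, FALSE), config$rate_migration_nobulge)
      if (j > 0L) add(walk_state(j - 1L, b, FALSE), config$rate_migration_nobulge)
    }
  }

  ## bulge diffusion (never during a half-step, which returns above)
  E <- config$energy
  for (k in seq_along(b)) {
    for (dx in c(-1L, 1L)) {
      y <- b[k] + dx
      if (y < 0L || y > M || y %in% b) next
      rate <- config$rate_bulge_hop * exp(-(E[y + 1L] - E[b[k] + 1L]) / 2)
      nb <- b; nb[k] <- y
      add(walk_state(j, nb, FALSE), rate)
    }
  }
  moves
}

## Build the reachable chain from a starting state: unique states plus,
## per state, integer target indices, individual rates, cumulative rates.
.fw_build_chain <- function(config, state0, max_states = 20000L) {
  key0 <- .fw_state_key(state0)
  states <- list(state0)
  index <- new.env(parent = emptyenv())
  assign(key0, 1L, envir = index)
  trans <- list()
  queue <- 1L
  while (length(queue) > 0L) {
    i <- queue[1L]; queue <- queue[-1L]
    mv <- enumerate_moves(states[[i]], config)
    tgt <- integer(length(mv)); rt <- numeric(length(mv))
    for (m in seq_along(mv)) {
      k <- .fw_state_key(mv[[m]]$state)
      id <- get0(k, envir = index)
      if (is.null(id)) {
        states[[length(states) + 1L]] <- mv[[m]]$state
        id <- length(states)
        assign(k, id, envir = index)
        queue <- c(queue, id)
        if (id > max_states)
          .fw_stop("state space exceeds %d states; reduce domain sizes", max_states)
      }
      tgt[m] <- id; rt[m] <- mv[[m]]$rate
    }
    trans[[i]] <- list(targets = tgt, rates = rt,
                       total = sum(rt), cum = cumsum(rt))
  }
  list(states = states, trans = trans)
}

#' Exact stochastic (Gillespie) simulation of the walk
#'
#' Simulates the continuous-time chain defined by [enumerate_moves()]
#' with exponential waiting times, reproducibly for a given
#' `config$seed`.  The run ends at absorption or at `t_max`, whichever
#' comes first.  A non-absorbing state with zero total outgoing rate
#' stalls the walk: the trajectory dwells there until `t_max` and is
#' flagged `stalled`.
#'
#' @param config A [walk_config()].
#' @param t_max Maximum simulated time (s), > 0.
#' @param state0 Starting state; default [initial_state()].
#' @return An object of class `fw_trajectory`: list with `chain_states`
#'   (unique visited states), `visited` (index sequence), `dwell`
#'   (seconds per visit), `absorbed`, `stalled`, `t_end`, `config`.
#' @export
gillespie_run <- function(config, t_max, state0 = NULL) {
  if (!inherits(config, "fw_walk_config")) .fw_stop("'config' must be an fw_walk_config")
  if (!is.numeric(t_max) || t_max <= 0) .fw_stop("'t_max' must be > 0")
  if (is.null(state0)) state0 <- initial_state(config)
  .fw_check_walk_state(state0, config)
  chain <- .fw_build_chain(config, state0)
  set.seed(config$seed)
  .fw_gillespie_core(chain, config, t_max, start = 1L)
}

.fw_gillespie_core <- function(chain, config, t_max, start) {
  visited <- integer(0); dwell <- numeric(0)
  t <- 0; s <- start
  absorbed <- FALSE; stalled <- FALSE
  repeat {
    tr <- chain$trans[[s]]
    if (tr$total == 0) {
      st <- chain$states[[s]]
      if (config$absorb_at_end && st$junction == config$domain_length &&
          !st$half_step) {
        absorbed <- TRUE
        visited <- c(visited, s); dwell <- c(dwell, 0)
      } else {
        stalled <- TRUE
        visited <- c(visited, s); dwell <- c(dwell, t_max - t)
        t <- t_max
      }
      break
    }
    dt <- rexp(1L, tr$total)
    if (t + dt >= t_max) {
      visited <- c(visited, s); dwell <- c(dwell, t_max - t)
      t <- t_max
      break
    }
    visited <- c(visited, s); dwell <- c(dwell, dt)
    t <- t + dt
    s <- tr$targets[findInterval(runif(1L) * tr$total, tr$cum) + 1L]
  }
  structure(list(chain_states = chain$states, visited = visited,
                 dwell = dwell, absorbed = absorbed, stalled = stalled,
                 t_end = t, config = config),
            class = "fw_trajectory")
}

#' @export
print.fw_trajectory <- function(x, ...) {
  cat(sprintf("<fw_trajectory> %d transitions over %g s; absorbed: %s%s\n",
              length(x$visited) - 1L, x$t_end, x$absorbed,
              if (x$stalled) " (stalled)" else ""))
  invisible(x)
}

#' Sample first-passage times to complete displacement
#'
#' Runs independent Gillespie realisations from [initial_state()] until
#' absorption at `j = N` and returns the passage times.  Used to
#' cross-validate [mean_first_passage()].
#'
#' @param config A [walk_config()] with `absorb_at_end = TRUE`.
#' @param n_runs Number of independent runs.
#' @param seed Integer seed.
#' @param max_steps Per-run safety cap on transitions.
#' @return Numeric vector of `n_runs` first-passage times (s).
#' @export
sample_first_passage <- function(config, n_runs, seed = 1L, max_steps = 1e7) {
  if (!isTRUE(config$absorb_at_end))
    .fw_stop("first-passage sampling requires absorb_at_end = TRUE")
  state0 <- initial_state(config)
  chain <- .fw_build_chain(config, state0)
  n_states <- length(chain$states)
  totals <- vapply(chain$trans, function(tr) tr$total, numeric(1L))
  set.seed(seed)
  out <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    s <- 1L; t <- 0; steps <- 0L
    while (totals[s] > 0) {
      tr <- chain$trans[[s]]
      t <- t + rexp(1L, tr$total)
      s <- tr$targets[findInterval(runif(1L) * tr$total, tr$cum) + 1L]
      steps <- steps + 1L
      if (steps > max_steps)
        .fw_stop("run %d exceeded %g steps without absorbing", r, max_steps)
    }
    st <- chain$states[[s]]
    if (st$junction != config$domain_length)
      .fw_stop("run %d stalled in a non-absorbing state (junction %d)",
               r, st$junction)
    out[r] <- t
  }
  out
}

.fw_occupancy <- function(positions, probability) {
  if (abs(sum(probability) - 1) > 1e-9)
    .fw_stop("occupancy probabilities must sum to 1 (got %.12g)", sum(probability))
  ref <- probability[positions == 1L]
  fe <- if (length(ref) == 1L && ref > 0) -log(probability / ref)
        else rep(Inf, length(positions))
  fe[positions == 1L] <- 0
  structure(data.frame(position = positions, probability = probability,
                       free_energy_kT = fe),
            class = c("fw_occupancy", "data.frame"))
}

## Enumerate frozen-junction bulge configurations.
.fw_bulge_states <- function(config) {
  M <- config$bulge_domain_length
  if (config$n_bulges == 1L) {
    lapply(0:M, function(x) walk_state(0L, x, FALSE))
  } else if (config$n_bulges == 2L) {
    out <- list()
    for (x1 in 0:(M - 1L)) for (x2 in (x1 + 1L):M)
      out[[length(out) + 1L]] <- walk_state(0L, c(x1, x2), FALSE)
    out
  } else {
    .fw_stop("occupancy requires at least one bulge")
  }
}

#' Exact stationary occupancy of the frozen-junction chain
#'
#' Solves the global-balance linear system of the bulge-diffusion chain
#' with the junction frozen, and returns the per-position occupancy
#' probability with its free-energy transform
#' `F(x)/kT = -ln(P(x)/P(1))` (so the profile is pinned to 0 at
#' position 1).  For two bulges the position profile is the marginal
#' occupancy (each state contributes half its probability to each of its
#' two bulge positions).
#'
#' @param config A [walk_config()] with `freeze_junction = TRUE`.
#' @return An `fw_occupancy` data frame with columns `position`,
#'   `probability`, `free_energy_kT`.  The full stationary vector over
#'   states is attached as attribute `"stationary"`.
#' @export
stationary_exact <- function(config) {
  if (!inherits(config, "fw_walk_config")) .fw_stop("'config' must be an fw_walk_config")
  if (!isTRUE(config$freeze_junction))
    .fw_stop("stationary_exact requires freeze_junction = TRUE")
  states <- .fw_bulge_states(config)
  S <- length(states)
  keys <- vapply(states, .fw_state_key, character(1L))
  idx <- setNames(seq_len(S), keys)
  Q <- matrix(0, S, S)
  for (i in seq_len(S)) {
    for (mv in enumerate_moves(states[[i]], config)) {
      j <- idx[[.fw_state_key(mv$state)]]
      Q[i, j] <- Q[i, j] + mv$rate
    }
  }
  ## irreducibility: BFS over the undirected support
  reach <- rep(FALSE, S); reach[1L] <- TRUE; frontier <- 1L
  supp <- (Q > 0) | t(Q > 0)
  while (length(frontier) > 0L) {
    nxt <- which(colSums(supp[frontier, , drop = FALSE]) > 0 & !reach)
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  if (!all(reach))
    .fw_stop("chain is reducible; unreachable states: %s",
             paste(keys[!reach], collapse = "; "))
  diag(Q) <- -rowSums(Q)
  A <- rbind(t(Q), rep(1, S))
  pi_hat <- qr.solve(A, c(rep(0, S), 1))
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat <- pi_hat / sum(pi_hat)

  M <- config$bulge_domain_length
  prob <- numeric(M + 1L)
  for (i in seq_len(S)) {
    for (x in states[[i]]$bulges)
      prob[x + 1L] <- prob[x + 1L] + pi_hat[i] / config$n_bulges
  }
  out <- .fw_occupancy(0:M, prob)
  attr(out, "stationary") <- pi_hat
  out
}

#' Occupancy profile of bulge positions from a trajectory
#'
#' Dwell-time-weighted histogram of the bulge position(s) along a
#' trajectory, normalized to a probability distribution over positions
#' `0..M`, with the free-energy transform `F(x)/kT = -ln(P(x)/P(1))`.
#' Positions never occupied get infinite free energy (a flag, not an
#' error).
#'
#' @param trajectory An [gillespie_run()] result from a configuration
#'   with at least one bulge.
#' @return An `fw_occupancy` data frame.
#' @export
occupancy_profile <- function(trajectory) {
  if (!inherits(trajectory, "fw_trajectory")) .fw_stop("'trajectory' must be an fw_trajectory")
  config <- trajectory$config
  if (config$n_bulges < 1L) .fw_stop("occupancy requires at least one bulge")
  if (length(trajectory$visited) == 0L || sum(trajectory$dwell) <= 0)
    .fw_stop("trajectory has no dwell time")
  M <- config$bulge_domain_length
  w <- numeric(M + 1L)
  for (k in seq_along(trajectory$visited)) {
    st <- trajectory$chain_states[[trajectory$visited[k]]]
    for (x in st$bulges)
      w[x + 1L] <- w[x + 1L] + trajectory$dwell[k] / config$n_bulges
  }
  .fw_occupancy(0:M, w / sum(w))
}

#' Mean first-passage time to complete displacement
#'
#' Computes the expected time for the junction to first reach `j = N`
#' from the given start, exactly, by solving the linear first-passage
#' system of the chain (not by sampling).  The effective displacement
#' rate `1/MFPT` is reported alongside.
#'
#' @param config A [walk_config()] with `absorb_at_end = TRUE`.
#' @param state0 Starting state; default [initial_state()].
#' @return Object of class `fw_mfpt`: list with `mfpt` (s), `rate`
#'   (s^-1), and `n_states` (size of the reachable state space).
#' @export
mean_first_passage <- function(config, state0 = NULL) {
  if (!inherits(config, "fw_walk_config")) .fw_stop("'config' must be an fw_walk_config")
  if (!isTRUE(config$absorb_at_end))
    .fw_stop("mean_first_passage requires absorb_at_end = TRUE")
  if (is.null(state0)) state0 <- initial_state(config)
  .fw_check_walk_state(state0, config)
  chain <- .fw_build_chain(config, state0)
  S <- length(chain$states)
  absorbing <- vapply(seq_len(S), function(i) {
    st <- chain$states[[i]]
    st$junction == config$domain_length && !st$half_step
  }, logical(1L))
  if (!any(absorbing))
    .fw_stop("absorbing state j = %d is unreachable from the start",
             config$domain_length)
  transient <- which(!absorbing)
  ## every transient state must reach absorption: reverse BFS from absorbing
  can_reach <- absorbing
  repeat {
    grew <- FALSE
    for (i in transient) {
      if (can_reach[i]) next
      if (any(can_reach[chain$trans[[i]]$targets])) {
        can_reach[i] <- TRUE; grew <- TRUE
      }
    }
    if (!grew) break
  }
  if (!all(can_reach))
    .fw_stop("absorbing state unreachable from %d state(s), e.g. %s",
             sum(!can_reach),
             .fw_state_key(chain$states[[which(!can_reach)[1L]]]))

  pos <- match(seq_len(S), transient)   # state index -> row in system
  nT <- length(transient)
  A <- matrix(0, nT, nT)
  for (r in seq_len(nT)) {
    i <- transient[r]
    tr <- chain$trans[[i]]
    A[r, r] <- tr$total
    for (m in seq_along(tr$targets)) {
      j <- tr$targets[m]
      if (!absorbing[j]) A[r, pos[j]] <- A[r, pos[j]] - tr$rates[m]
    }
  }
  tau <- solve(A, rep(1, nT))
  mfpt <- tau[pos[1L]]
  structure(list(mfpt = mfpt, rate = 1 / mfpt, n_states = S),
            class = "fw_mfpt")
}

#' @export
print.fw_mfpt <- function(x, ...) {
  cat(sprintf("<fw_mfpt> MFPT = %.6g s (effective rate %.6g s^-1, %d states)\n",
              x$mfpt, x$rate, x$n_states))
  invisible(x)
}

#' Check the sequence constraint imposed by bulged branch-migration domains
#'
#' A single bulge forces every base of the branch-migration domain to pair
#' with its neighbour's complement, restricting the domain to poly-A or
#' poly-T (poly-G cannot be synthesized).  A second bulge relaxes the
#' constraint to every second base, allowing dinucleotide repeats of
#' GT/TG or CA/AC.
#'
#' @param domain A DNA string over `A`, `C`, `G`, `T` (non-empty).
#' @param n_bulges 1 or 2.
#' @return A list with `valid` (flag), `position` (1-based index of the
#'   first violating base, or `NA`), and `reason`.
#' @examples
#' check_sequence_constraint("AAAAAA", 1)  # valid
#' check_sequence_constraint("GTGAGT", 2)  # invalid at position 4
#' @export
check_sequence_constraint <- function(domain, n_bulges) {
  if (!is.character(domain) || length(domain) != 1L || nchar(domain) == 0L)
    .fw_stop("'domain' must be a non-empty DNA string")
  s <- strsplit(toupper(domain), "")[[1L]]
  bad <- which(!(s %in% c("A", "C", "G", "T")))
  if (length(bad) > 0L)
    .fw_stop("invalid character '%s' at position %d (alphabet is ACGT)",
             s[bad[1L]], bad[1L])
  n_bulges <- as.integer(n_bulges)
  if (!(n_bulges %in% 1:2)) .fw_stop("'n_bulges' must be 1 or 2")

  invalid <- function(pos, reason)
    list(valid = FALSE, position = pos, reason = reason)

  if (n_bulges == 1L) {
    if (!(s[1L] %in% c("A", "T")))
      return(invalid(1L, "single-bulge domain must be poly-A or poly-T"))
    mism <- which(s != s[1L])
    if (length(mism) > 0L)
      return(invalid(mism[1L],
                     sprintf("expected homopolymer of '%s'", s[1L])))
    list(valid = TRUE, position = NA_integer_,
         reason = sprintf("poly-%s domain", s[1L]))
  } else {
    set <- if (s[1L] %in% c("G", "T")) c("G", "T") else c("C", "A")
    for (i in seq_along(s)) {
      if (!(s[i] %in% set))
        return(invalid(i, sprintf("base outside the %s repeat alphabet",
                                  paste(set, collapse = "/"))))
      if (i > 1L && s[i] == s[i - 1L])
        return(invalid(i, sprintf("repeat must alternate %s",
                                  paste(set, collapse = "/"))))
    }
    list(valid = TRUE, position = NA_integer_,
         reason = sprintf("alternating %s repeat", paste(set, collapse = "/")))
  }
}
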