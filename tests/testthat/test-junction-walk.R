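move_key <- function(mv) {
  st <- mv$state
  sprintf("j%d h%d b%s @%g", st$junction, as.integer(st$half_step),
          paste(st$bulges, collapse = ","), mv$rate)
}

test_that("move enumeration matches hand-built transition tables", {
  cfg <- walk_config(4, n_bulges = 1, bulge_domain_length = 2,
                     rate_migration_nobulge = 0.3, rate_half_step = 2,
                     rate_bulge_hop = 0.7)

  # plain random walk when no bulge occupies the core
  mv <- enumerate_moves(walk_state(2, 1), cfg)
  expect_setequal(vapply(mv, move_key, character(1)),
                  c("j3 h0 b1 @0.3", "j1 h0 b1 @0.3",
                    "j2 h0 b0 @0.7", "j2 h0 b2 @0.7"))

  # bulge at the core: only half-step entries plus the outward hop
  mv <- enumerate_moves(walk_state(0, 0), cfg)
  expect_setequal(vapply(mv, move_key, character(1)),
                  c("j0 h1 b0 @2", "j0 h0 b1 @0.7"))

  # interior assisted state: forward and backward half-step entries
  mv <- enumerate_moves(walk_state(3, 0), cfg)
  expect_setequal(vapply(mv, move_key, character(1)),
                  c("j3 h1 b0 @2", "j2 h1 b0 @2", "j3 h0 b1 @0.7"))

  # mid-half-step: resolve either way, hops suspended
  mv <- enumerate_moves(walk_state(2, 0, half_step = TRUE), cfg)
  expect_setequal(vapply(mv, move_key, character(1)),
                  c("j2 h0 b0 @2", "j3 h0 b0 @2"))

  # complete displacement is absorbing
  expect_length(enumerate_moves(walk_state(4, 1), cfg), 0)

  # hand-summed total exit rates (no hidden leakage)
  totals <- list(list(walk_state(2, 1), 2 * 0.3 + 2 * 0.7),  # walk + 2 hops
                 list(walk_state(0, 0), 2 + 0.7),            # half entry + hop
                 list(walk_state(1, 2), 2 * 0.3 + 0.7))      # walk + 1 hop (x at M)
  for (case in totals) {
    mv <- enumerate_moves(case[[1]], cfg)
    expect_equal(sum(vapply(mv, `[[`, numeric(1), "rate")), case[[2]])
  }
})

test_that("frozen-junction chains reflect at the ends and respect exclusion", {
  cfg <- walk_config(5, n_bulges = 1, bulge_domain_length = 6,
                     freeze_junction = TRUE, absorb_at_end = FALSE)
  expect_length(enumerate_moves(walk_state(0, 0), cfg), 1)   # x = 0 -> 1 only
  expect_length(enumerate_moves(walk_state(0, 3), cfg), 2)   # interior
  expect_length(enumerate_moves(walk_state(0, 6), cfg), 1)   # far end

  cfg2 <- walk_config(5, n_bulges = 2, bulge_domain_length = 6,
                      freeze_junction = TRUE, absorb_at_end = FALSE)
  # adjacent bulges at 0,1: only the outer bulge can move, outward
  mv <- enumerate_moves(walk_state(0, c(0, 1)), cfg2)
  expect_length(mv, 1)
  expect_identical(mv[[1]]$state$bulges, c(0L, 2L))
})

test_that("energy-biased hops follow the symmetric detailed-balance rule", {
  E <- c(0, -log(2), 0.5)
  cfg <- walk_config(5, n_bulges = 1, bulge_domain_length = 2,
                     freeze_junction = TRUE, absorb_at_end = FALSE,
                     rate_bulge_hop = 1.5, energy = E)
  mv <- enumerate_moves(walk_state(0, 1), cfg)
  rates <- setNames(vapply(mv, `[[`, numeric(1), "rate"),
                    vapply(mv, function(m) m$state$bulges, integer(1)))
  expect_equal(rates[["0"]], 1.5 * exp(-(E[1] - E[2]) / 2))
  expect_equal(rates[["2"]], 1.5 * exp(-(E[3] - E[2]) / 2))
})

test_that("exact stationary occupancy matches hand-solvable chains", {
  # symmetric chain: uniform occupancy, flat free energy
  cfg <- walk_config(5, n_bulges = 1, bulge_domain_length = 6,
                     freeze_junction = TRUE, absorb_at_end = FALSE)
  prof <- stationary_exact(cfg)
  expect_equal(prof$probability, rep(1 / 7, 7), tolerance = 1e-12)
  expect_equal(prof$free_energy_kT, rep(0, 7), tolerance = 1e-9)
  expect_identical(prof$free_energy_kT[prof$position == 1], 0)

  # two-state chain with rates 2 and 1: occupancy (1/3, 2/3) by detailed balance
  cfg2 <- walk_config(5, n_bulges = 1, bulge_domain_length = 1,
                      freeze_junction = TRUE, absorb_at_end = FALSE,
                      rate_bulge_hop = sqrt(2), energy = c(0, -log(2)))
  prof2 <- stationary_exact(cfg2)
  expect_equal(prof2$probability, c(1 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(prof2$free_energy_kT[1], -log((1 / 3) / (2 / 3)), tolerance = 1e-9)

  # frozen chain with zero hop rate cannot mix
  cfg3 <- walk_config(5, n_bulges = 1, bulge_domain_length = 3,
                      freeze_junction = TRUE, absorb_at_end = FALSE,
                      rate_bulge_hop = 0)
  expect_error(stationary_exact(cfg3), "reducible")
})

test_that("Gillespie trajectories are seed-reproducible and account for all time", {
  cfg <- walk_config(4, n_bulges = 1, bulge_domain_length = 4,
                     freeze_junction = TRUE, absorb_at_end = FALSE, seed = 11)
  t1 <- gillespie_run(cfg, t_max = 50)
  t2 <- gillespie_run(cfg, t_max = 50)
  expect_identical(t1$visited, t2$visited)
  expect_identical(t1$dwell, t2$dwell)
  expect_equal(sum(t1$dwell), 50)
  expect_false(t1$absorbed)

  # all rates zero: the walk stalls in its initial state until t_max
  cfg0 <- walk_config(4, n_bulges = 1, rate_migration_nobulge = 0,
                      rate_half_step = 0, rate_bulge_hop = 0, seed = 1)
  tr0 <- gillespie_run(cfg0, t_max = 25)
  expect_true(tr0$stalled)
  expect_length(tr0$visited, 1)
  expect_equal(tr0$dwell, 25)
})

test_that("sampled occupancy converges to the exact stationary profile", {
  cfg <- walk_config(5, n_bulges = 1, bulge_domain_length = 5,
                     freeze_junction = TRUE, absorb_at_end = FALSE,
                     energy = 0.4 * (0:5), seed = 23)
  exact <- stationary_exact(cfg)
  emp <- occupancy_profile(gillespie_run(cfg, t_max = 3000))
  expect_lt(max(abs(emp$probability - exact$probability)), 0.02)
  expect_identical(emp$free_energy_kT[emp$position == 1], 0)

  # pinned trajectory: point mass, unvisited positions flagged +Inf
  cfg0 <- walk_config(4, n_bulges = 1, bulge_domain_length = 3,
                      rate_bulge_hop = 0, freeze_junction = TRUE,
                      absorb_at_end = FALSE, seed = 2)
  pp <- occupancy_profile(gillespie_run(cfg0, t_max = 10))
  expect_equal(pp$probability, c(1, 0, 0, 0))
  expect_true(all(is.infinite(pp$free_energy_kT[pp$probability == 0]) |
                    pp$position[pp$probability == 0] == 1))
})

test_that("mean first-passage time matches classical birth-death formulas", {
  # no bulge: reflecting start, absorbing end; MFPT = sum_{k<N} (k+1)/r
  bd_oracle <- function(N, r) sum((seq_len(N) - 1 + 1) / r)
  for (N in c(4, 6, 9)) {
    cfg <- walk_config(N, n_bulges = 0, rate_migration_nobulge = 2)
    expect_equal(mean_first_passage(cfg)$mfpt, bd_oracle(N, 2),
                 tolerance = 1e-10)
  }

  # bulge pinned at the core: the subdivided walk on 2N half-steps
  cfg <- walk_config(4, n_bulges = 1, bulge_domain_length = 3,
                     rate_bulge_hop = 0, rate_half_step = 3)
  m <- mean_first_passage(cfg)
  expect_equal(m$mfpt, bd_oracle(8, 3), tolerance = 1e-10)
  expect_equal(m$rate, 1 / m$mfpt)
})

test_that("bulge diffusion away from the core slows displacement", {
  mfpts <- vapply(c(0, 0.5, 2, 8), function(hop) {
    cfg <- walk_config(5, n_bulges = 1, bulge_domain_length = 4,
                       rate_bulge_hop = hop, rate_half_step = 5,
                       rate_migration_nobulge = 0.1)
    mean_first_passage(cfg)$mfpt
  }, numeric(1))
  expect_true(all(diff(mfpts) > 0))
})

test_that("unreachable absorption is an error", {
  cfg <- walk_config(4, n_bulges = 0, rate_migration_nobulge = 0)
  expect_error(mean_first_passage(cfg), "unreachable")
})

test_that("sequence constraints encode the bulged-domain design rules", {
  expect_true(check_sequence_constraint("AAAAAA", 1)$valid)
  expect_true(check_sequence_constraint("TTTTT", 1)$valid)
  r <- check_sequence_constraint("AATAAA", 1)
  expect_false(r$valid); expect_identical(r$position, 3L)
  expect_false(check_sequence_constraint("GGGG", 1)$valid)

  expect_true(check_sequence_constraint("GTGTGT", 2)$valid)
  expect_true(check_sequence_constraint("TGTG", 2)$valid)
  expect_true(check_sequence_constraint("CACAC", 2)$valid)
  expect_true(check_sequence_constraint("ACAC", 2)$valid)
  r2 <- check_sequence_constraint("GTGAGT", 2)
  expect_false(r2$valid); expect_identical(r2$position, 4L)
  expect_false(check_sequence_constraint("GGTG", 2)$valid)

  expect_error(check_sequence_constraint("AXTA", 1), "invalid character")
})
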