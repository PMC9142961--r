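# Bateman solver, equilibrium algebra, chain construction.

test_that("nuclide and chain constructors enforce their invariants", {
  bi <- nuclide("Bi-213", 45.6, "min")
  expect_equal(bi$decay_constant * bi$half_life, log(2), tolerance = 1e-13)
  expect_error(nuclide("X", -1), "positive")
  expect_error(nuclide("X", 0), "positive")

  ac <- nuclide("Ac-225", 9.9, "day")
  expect_equal(ac$half_life, 9.9 * 1440)
  expect_error(decay_chain(list(ac, ac)), "unique")
  expect_error(decay_chain(list(ac, bi), branching = 1.5), "branching")
  expect_error(decay_chain(list(ac, bi), branching = 0), "branching")
  expect_error(decay_chain(list(nuclide("S", Inf), bi)), "terminal")
})

test_that("the packaged chain matches its YAML definition and collapses At-217", {
  ch <- ac225_chain()
  expect_equal(ch$names, c("Ac-225", "Fr-221", "Bi-213", "Bi-209"))
  ch4 <- ac225_chain(collapse_at217 = FALSE)
  expect_equal(ch4$n, 5L)
  expect_equal(ch4$half_life[3], 32.3 / 60000)
  expect_equal(ch4$half_life[1], 9.9 * 1440)
  expect_equal(ch4$half_life[2], 5)
})

test_that("elapsed = 0 returns the initial state and one half-life halves the parent", {
  ch <- ac225_chain()
  init <- c("Ac-225" = 50)
  s0 <- bateman_activities(ch, init, 0)
  expect_equal(s0$activities[["Ac-225"]], 50)
  expect_equal(s0$activities[["Bi-213"]], 0)
  s1 <- bateman_activities(ch, init, 9.9, unit = "day")
  expect_equal(s1$activities[["Ac-225"]], 25, tolerance = 1e-12)
  expect_error(bateman_activities(ch, init, -1), "non-negative")
  expect_error(bateman_activities(ch, c(Unknown = 1), 1), "not in the chain")
})

test_that("analytic activities match the stiff ODE oracle on the full chain", {
  ch <- ac225_chain(collapse_at217 = FALSE)
  times <- c(15, 60, 360, 1440, 4320, 10080, 20160) # minutes, up to 14 d
  ana <- bateman_activities(ch, c("Ac-225" = 50), times)
  ode <- ode_activities(ch, c(50, 0, 0, 0, 0), c(0, times))[-1, ]
  rel <- abs(ana[, 1:4] - ode[, 1:4]) / ode[, 1:4]
  expect_lt(max(rel), 1e-6)
  # spec'd spot value: Bi-213 ingrowth from pure parent at 24 h
  bi24 <- bateman_activities(ch, c("Ac-225" = 50), 1440)$activities[["Bi-213"]]
  expect_equal(bi24, ode_activities(ch, c(50, 0, 0, 0, 0), c(0, 1440))[2, 4],
               tolerance = 1e-6)
})

test_that("atom numbers are conserved through the chain for random configurations", {
  set.seed(101)
  for (rep in 1:10) {
    n <- sample(3:5, 1)
    nucs <- c(lapply(seq_len(n - 1), function(i)
      nuclide(paste0("N", i), exp(runif(1, 0, 6)))), list(nuclide("stable", Inf)))
    ch <- decay_chain(nucs)
    a0 <- setNames(c(runif(n - 1, 1, 100), 0), ch$names)
    n0 <- ifelse(ch$lambda > 0, a0 / ch$lambda, 0)
    atoms <- alphachain:::bateman_atoms(ch, n0, exp(runif(1, 0, 8)))
    expect_equal(sum(atoms), sum(n0), tolerance = 1e-9)
  }
})

test_that("near-equal decay constants switch to the exact limit evaluation", {
  # two members with identical half-lives: the distinct-lambda formula would
  # divide by ~0; the matrix-exponential path must agree with a slightly
  # perturbed closed form
  mk <- function(hl2) decay_chain(list(nuclide("A", 10), nuclide("B", hl2),
                                       nuclide("stable", Inf)))
  exact <- bateman_activities(mk(10), c(A = 100), c(5, 20, 50))
  nearby <- bateman_activities(mk(10 * (1 + 1e-7)), c(A = 100), c(5, 20, 50))
  expect_equal(exact, nearby, tolerance = 1e-5)
  expect_true(all(is.finite(exact)))
})

test_that("supported daughter activity starts at zero, grows monotonically and hits equilibrium", {
  ch <- ac225_chain()
  expect_equal(supported_daughter_activity(ch, "Ac-225", "Bi-213", 100, 0), 0)
  tgrid <- seq(0, 200, by = 10)
  ing <- supported_daughter_activity(ch, "Ac-225", "Bi-213", 100, tgrid)
  expect_true(all(diff(ing) > 0))
  # ten daughter half-lives: the ingrowth residual is 2^-10 times the chain
  # prefactor lambda_Fr/(lambda_Fr - lambda_Bi) * lambda_Bi/(lambda_Bi -
  # lambda_Ac) ~ 1.13, so the approach to the asymptote is complete to ~1.1e-3
  eq <- 100 * equilibrium_ratio(ch, "Ac-225", "Bi-213")
  lam <- setNames(ch$lambda, ch$names)
  pref <- lam[["Fr-221"]] / (lam[["Fr-221"]] - lam[["Bi-213"]]) *
    lam[["Bi-213"]] / (lam[["Bi-213"]] - lam[["Ac-225"]])
  at10 <- supported_daughter_activity(ch, "Ac-225", "Bi-213", 100, 10 * 45.6)
  resid <- abs(at10 - eq * exp(-ch$lambda[1] * 456)) / eq
  expect_lt(resid, 2^-10 * pref * 1.05)
  expect_error(supported_daughter_activity(ch, "Bi-213", "Ac-225", 1, 10),
               "downstream")
})

test_that("equilibrium ratios evaluate the closed form and reject degenerate pairs", {
  ch <- ac225_chain()
  lam_ac <- log(2) / (9.9 * 1440)
  lam_fr <- log(2) / 5
  expect_equal(equilibrium_ratio(ch, "Ac-225", "Fr-221"),
               lam_fr / (lam_fr - lam_ac), tolerance = 1e-12)
  # secular limit: an extremely short-lived daughter sits at the parent's level
  fast <- decay_chain(list(nuclide("P", 1e6), nuclide("D", 1e-6)))
  expect_equal(equilibrium_ratio(fast, "P", "D"), 1, tolerance = 1e-9)
  same <- decay_chain(list(nuclide("P", 10), nuclide("D", 10)))
  expect_error(equilibrium_ratio(same, "P", "D"), "equilibrium")
  slow <- decay_chain(list(nuclide("P", 1), nuclide("D", 100)))
  expect_error(equilibrium_ratio(slow, "P", "D"), "equilibrium")
  # long-time ODE cross-check of the Ac -> Fr ratio
  ch4 <- ac225_chain(collapse_at217 = FALSE)
  late <- ode_activities(ch4, c(100, 0, 0, 0, 0), c(0, 2880))[2, ]
  expect_equal(late[2] / late[1], equilibrium_ratio(ch4, "Ac-225", "Fr-221"),
               tolerance = 1e-6)
})
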