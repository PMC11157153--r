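test_that("PTM tables build from masses or compositions", {
  tab <- default_ptm_table()
  expect_equal(nrow(tab), 9)
  expect_equal(tab$mass[tab$name == "Ox"], 15.9994, tolerance = 1e-4)
  expect_equal(tab$mass[tab$name == "Ph"], 79.98, tolerance = 1e-2)
  # sodium adduct replaces a proton: Na - H
  expect_equal(tab$mass[tab$name == "Na"], 22.98977 - 1.00794,
               tolerance = 1e-3)
  # acetylation and tri-methylation are near-degenerate (~0.04 Da)
  dm <- abs(tab$mass[tab$name == "Ac"] - tab$mass[tab$name == "Me3"])
  expect_lt(dm, 0.05)
  expect_error(ptm_table(c("A", "A"), mass = c(1, 2)), "unique")
  expect_error(ptm_table("A", mass = -1), "positive mass")
})

test_that("PTM tables round-trip through CSV with formula parsing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,composition,upper_bound",
               "Ph,HPO3,3", "Na,Na1H-1,2"), f)
  tab <- read_ptm_table(f)
  expect_equal(tab$mass[1], 79.98, tolerance = 0.01)
  expect_equal(tab$mass[2], 21.98, tolerance = 0.01)
  expect_equal(tab$upper_bound, c(3L, 2L))
  expect_equal(parse_formula("C2H3NO"), c(C = 2, H = 3, N = 1, O = 1),
               ignore_attr = TRUE)
})

test_that("feasible-pattern enumeration matches hand-checked cases", {
  tab <- toy_ptm_table()
  # the zero pattern is always feasible for obs = 0
  pats <- enumerate_feasible_patterns(0, tab, 0.1)
  expect_true(any(vapply(pats, function(p) p$total_ptms == 0L, TRUE)))

  ox <- ptm_table("Ox", mass = 15.9949, upper_bound = 2L)
  pats <- enumerate_feasible_patterns(16.0, ox, 0.1)
  expect_length(pats, 1)
  expect_equal(unname(pats[[1]]$counts["Ox"]), 1L)

  # 2 x Ph is the unique bounded explanation of 159.93 at 0.05 Da
  pats <- enumerate_feasible_patterns(159.93, tab, 0.05)
  expect_length(pats, 1)
  expect_equal(unname(pats[[1]]$counts), c(2L, 0L))
  expect_error(
    enumerate_feasible_patterns(500, ptm_table(letters[1:10], mass = 5 + 1:10),
                                eps_max = 400, guard = 100),
    "guard")
})

test_that("each solver agrees with the brute-force oracle on random instances", {
  set.seed(1234)
  n_checked <- 0
  for (i in 1:200) {
    tab <- random_instance()
    # half the instances target a reachable combination, half are arbitrary
    obs <- if (i %% 2 == 0) {
      ub <- ifelse(is.na(tab$upper_bound), 3L, tab$upper_bound)
      p <- vapply(ub, function(u) sample(0:u, 1), 0L)
      round(sum(p * tab$mass) + stats::runif(1, -0.5, 0.5), 2)
    } else {
      round(stats::runif(1, 0, 250), 2)
    }
    cfg <- inference_config(eps_max = stats::runif(1, 0.05, 2), laps = 1)
    for (objective in c("min_ptm", "min_error", "min_both")) {
      cfg$objective <- objective
      solver <- switch(objective, min_ptm = solve_min_ptm,
                       min_error = solve_min_error, min_both = solve_min_both)
      got <- solver(obs, tab, cfg)
      want <- oracle_best(obs, tab, cfg, objective)
      if (is.null(want)) {
        expect_null(got)
      } else {
        n_checked <- n_checked + 1
        expect_false(is.null(got))
        if (objective == "min_ptm") {
          expect_identical(got$total_ptms, as.integer(want$value))
        } else {
          expect_equal(got$objective_value, want$value, tolerance = 1e-9)
        }
        # feasibility of the returned pattern
        expect_lte(got$error, cfg$eps_max + 1e-12)
        ub <- resolve_upper_bounds(tab, obs, cfg$eps_max, cfg$ub_cap)
        expect_true(all(got$counts >= 0 & got$counts <= ub))
      }
    }
  }
  expect_gt(n_checked, 100)
})

test_that("laps strictly improve and match the oracle ranking", {
  tab <- toy_ptm_table()
  cfg <- inference_config(eps_max = 1, laps = 3, objective = "min_error")
  obs <- 2 * 79.966
  # exact hit first
  sols <- enumerate_k_solutions(obs, tab, cfg)
  expect_equal(sols[[1]]$error, 0, tolerance = 1e-12)
  expect_equal(unname(sols[[1]]$counts), c(2L, 0L))
  # second-best error equals the oracle's second-smallest error
  oracle <- oracle_best(obs, tab, cfg, "min_error")
  second <- sort(oracle$all[oracle$all > cfg$epsilon_step / 2])[1]
  if (length(sols) > 1) {
    expect_equal(sols[[2]]$error, second, tolerance = 1e-9)
  }

  # strict monotonicity across laps for all objectives
  set.seed(99)
  for (i in 1:25) {
    tab <- random_instance()
    obs <- round(stats::runif(1, 0, 200), 2)
    for (objective in c("min_ptm", "min_error", "min_both")) {
      cfg <- inference_config(eps_max = 1.5, laps = 4, objective = objective)
      sols <- enumerate_k_solutions(obs, tab, cfg)
      vals <- vapply(sols, `[[`, 0, "objective_value")
      if (length(vals) > 1) expect_true(all(diff(vals) > 0))
    }
  }

  # k = 1 equals the single solve; early stop on exhausted solution space
  ox <- ptm_table("Ox", mass = 15.9949, upper_bound = 2L)
  cfg1 <- inference_config(eps_max = 0.1, laps = 1, objective = "min_ptm")
  expect_equal(enumerate_k_solutions(16, ox, cfg1)[[1]]$counts,
               solve_min_ptm(16, ox, cfg1)$counts)
  cfg10 <- inference_config(eps_max = 20, laps = 10, objective = "min_ptm")
  sols <- enumerate_k_solutions(16, ox, cfg10)
  expect_lte(length(sols), 3)  # only counts 0..2 exist at all
})

test_that("no-good-cut mode enumerates tied alternatives", {
  tab <- ptm_table(c("A", "B"), mass = c(10, 10.0001),
                   upper_bound = c(1L, 1L))
  cfg <- inference_config(eps_max = 0.01, laps = 2, objective = "min_ptm")
  strict <- enumerate_k_solutions(10, tab, cfg, tie_mode = "strict")
  nogood <- enumerate_k_solutions(10, tab, cfg, tie_mode = "nogood")
  expect_length(strict, 1)  # the tied alternative is skipped
  expect_length(nogood, 2)
  expect_equal(sort(vapply(nogood, `[[`, 0L, "total_ptms")), c(1L, 1L))
})

test_that("enlarging the tolerance never worsens the optima", {
  set.seed(7)
  n_feasible <- 0
  for (i in 1:30) {
    tab <- random_instance()
    ub <- ifelse(is.na(tab$upper_bound), 3L, tab$upper_bound)
    p <- vapply(ub, function(u) sample(0:u, 1), 0L)
    obs <- round(sum(p * tab$mass) + stats::runif(1, -0.4, 0.4), 2)
    small <- inference_config(eps_max = 0.3)
    large <- inference_config(eps_max = 1.2)
    p_small <- solve_min_ptm(obs, tab, small)
    p_large <- solve_min_ptm(obs, tab, large)
    if (!is.null(p_small)) {
      n_feasible <- n_feasible + 1
      expect_false(is.null(p_large))
      expect_lte(p_large$total_ptms, p_small$total_ptms)
    }
    e_small <- solve_min_error(obs, tab, small)
    e_large <- solve_min_error(obs, tab, large)
    if (!is.null(e_small)) {
      expect_lte(e_large$error, e_small$error + 1e-12)
    }
  }
  expect_gt(n_feasible, 10)
})

test_that("infer_patterns produces the long report with ppm errors", {
  tab <- default_ptm_table()
  cfg <- inference_config(mass_tolerance_ppm = 36, reference_mass = 43652,
                          laps = 2)
  out <- infer_patterns(c(16, 1e6), tab, cfg,
                        objectives = c("min_ptm", "min_both"))
  expect_true(all(c("shift", "objective", "lap", "pattern", "error_ppm")
                  %in% names(out)))
  expect_equal(out$pattern[out$shift == 16 & out$lap == 1],
               c("1[Ox]", "1[Ox]"))
  expect_true(all(out$pattern[out$shift == 1e6] ==
                    "no pattern within tolerance"))
})
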