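test_that("whole-organ conversion multiplies by the organ mass", {
  ph <- phantom(c(liver = 2.5), body_mass_g = 25)
  tac <- tac_table(c("liver", "liver"), c(4, 24), c(4.0, 0))
  cur <- to_whole_organ(tac, ph)
  expect_equal(cur$pct_ia, c(10, 0))
  # tumor mass comes from user config; peak concentration 12.9 %IA/g
  tac2 <- tac_table("tumor", 24, 12.9)
  cur2 <- to_whole_organ(tac2, ph, extra_masses_g = c(tumor = 0.4))
  expect_equal(cur2$pct_ia, 5.16)
  expect_error(to_whole_organ(tac2, ph), "no mass")
  # whole_body converts with the body mass
  wb <- to_whole_organ(tac_table("whole_body", 4, 3.2), ph)
  expect_equal(wb$pct_ia, 3.2 * 25)
  # non-decay-corrected input is refused
  raw <- tac_table("liver", 4, 2, decay_corrected_to = "none")
  expect_error(to_whole_organ(raw, ph), "decay-corrected")
})

test_that("strict mass-fraction allocation follows the literal rule", {
  # one organ holding 10% of the body mass receives WB * 0.1
  ph <- phantom(c(liver = 1), body_mass_g = 10)
  cur <- make_curves("whole_body", c(4, 24), c(40, 40))
  out <- allocate_residual(cur, ph, mode = "strict_paper")
  expect_equal(out$pct_ia[out$organ == "liver"], c(4, 4))
  # the leftover carcass takes the remaining mass fraction
  expect_equal(out$pct_ia[out$organ == "remainder"], c(36, 36))
})

test_that("conserving allocation distributes the deficit by mass", {
  # delineated liver holds 30 of WB 40; kidneys and spleen (equal masses)
  # exhaust the remainder -> 5 %IA each
  ph <- tiny_phantom()
  cur <- make_curves(rep(c("whole_body", "liver"), each = 2),
                     rep(c(4, 24), 2), c(40, 40, 30, 30))
  out <- allocate_residual(cur, ph, mode = "conserve")
  expect_equal(out$pct_ia[out$organ == "kidneys"], c(5, 5))
  expect_equal(out$pct_ia[out$organ == "spleen"], c(5, 5))
  expect_setequal(unique(out$provenance[out$organ != "liver"]), "residual")
  # proportionality limit: no delineated organs, one organ = whole body
  ph1 <- phantom(c(muscle = 10), body_mass_g = 10)
  out1 <- allocate_residual(make_curves("whole_body", c(0, 10), c(80, 50)),
                            ph1, mode = "conserve")
  expect_equal(out1$pct_ia[out1$organ == "muscle"], c(80, 50))
})

test_that("conserving allocation conserves activity exactly at every time", {
  set.seed(21)
  for (i in 1:10) {
    masses <- stats::setNames(runif(5, 0.2, 4), paste0("o", 1:5))
    ph <- phantom(masses, body_mass_g = sum(masses) + runif(1, 1, 10))
    times <- sort(runif(4, 1, 80))
    wb <- runif(4, 30, 60)
    delin <- wb * runif(1, 0.2, 0.6)     # delineated organ o1
    cur <- make_curves(rep(c("whole_body", "o1"), each = 4), rep(times, 2),
                       c(wb, delin))
    out <- allocate_residual(cur, ph, mode = "conserve")
    total <- tapply(out$pct_ia, out$time_h, sum)
    expect_equal(as.numeric(total), wb, tolerance = 1e-12)
  }
})

test_that("conservation violations error by default, clamp on request", {
  ph <- tiny_phantom()
  cur <- make_curves(rep(c("whole_body", "liver"), each = 2),
                     rep(c(4, 24), 2), c(20, 20, 30, 30))
  expect_error(allocate_residual(cur, ph), "conservation")
  expect_warning(out <- allocate_residual(cur, ph, clamp = TRUE), "clamped")
  expect_true(all(out$pct_ia[out$organ == "kidneys"] == 0))
})

test_that("curves on different grids are resampled before allocation", {
  ph <- tiny_phantom()
  cur <- make_curves(c("whole_body", "whole_body", "liver"),
                     c(4, 24, 14), c(40, 20, 9))
  out <- allocate_residual(cur, ph, mode = "conserve")
  # liver is held constant outside its single sample; WB interpolated at 14 h
  liver <- out$pct_ia[out$organ == "liver"]
  expect_equal(liver, c(9, 9, 9))
  wb14 <- approx(c(4, 24), c(40, 20), xout = 14)$y
  expect_equal(sum(out$pct_ia[out$time_h == 14]), wb14, tolerance = 1e-12)
})

test_that("isotope transposition imposes and removes physical decay", {
  # constant biological curve halves after one physical half-life
  cur <- make_curves(rep("tumor", 2), c(0, 159.5), c(10, 10))
  dec <- transpose_isotope(cur, lu177())
  expect_equal(dec$pct_ia, c(10, 5), tolerance = 1e-12)
  # reverse-then-forward is the identity to machine precision
  back <- transpose_isotope(dec, lu177(), reverse = TRUE)
  expect_equal(back$pct_ia, cur$pct_ia, tolerance = 1e-15)
  expect_true(is.na(attr(back, "physical_decay")))
  # decayed curves refuse a second transposition; biological refuse reverse
  expect_error(transpose_isotope(dec, lu177()), "already carry")
  expect_error(transpose_isotope(cur, lu177(), reverse = TRUE),
               "do not carry")
})

test_that("biological and physical rates combine harmonically", {
  # biological half-life 100 h under a 159.5 h physical half-life gives an
  # effective half-life 1/(1/100 + 1/159.5) = 61.46 h
  t <- seq(0, 96, by = 4)
  cur <- make_curves(rep("blood", length(t)), t, 12 * exp(-log(2) / 100 * t))
  dec <- transpose_isotope(cur, lu177())
  fit <- fit_exponential(dec$time_h, dec$pct_ia)
  expect_equal(fit$half_life_h, 1 / (1 / 100 + 1 / 159.5), tolerance = 1e-6)
})

test_that("transposition commutes with mass scaling", {
  t <- c(4, 24, 48)
  cur <- make_curves(rep("liver", 3), t, c(9, 7, 5))
  mass <- 1.37
  a <- transpose_isotope(cur, lu177())$pct_ia * mass
  cur2 <- make_curves(rep("liver", 3), t, c(9, 7, 5) * mass)
  b <- transpose_isotope(cur2, lu177())$pct_ia
  expect_equal(a, b, tolerance = 1e-14)
})

test_that("exponential fitting recovers exact generating parameters", {
  t <- c(4, 24, 48, 72)
  y <- 17.3 * exp(-0.031 * t)
  fit <- fit_exponential(t, y)
  expect_equal(fit$amplitudes, 17.3, tolerance = 1e-7)
  expect_equal(fit$rates, 0.031, tolerance = 1e-7)
  expect_lt(fit$rss / sum(y^2), 1e-18)
  # two exact points pin down the printed clearance half-life
  fit2 <- fit_exponential(c(0, 20.4), c(20, 10))
  expect_equal(fit2$half_life_h, 20.4, tolerance = 1e-6)
})

test_that("biexponential fitting resolves two noiseless components", {
  t <- c(1, 2, 4, 8, 16, 24, 48, 72, 96)
  y <- 12 * exp(-log(2) / 30 * t) + 25 * exp(-log(2) / 3 * t)
  fit <- fit_exponential(t, y, terms = 2)
  expect_equal(fit$half_life_h, 30, tolerance = 1e-4)
  expect_equal(sort(fit$amplitudes), c(12, 25), tolerance = 1e-3)
  expect_lt(fit$rss / sum(y^2), 1e-12)
})

test_that("fitting rejects underdetermined or nonpositive input", {
  expect_error(fit_exponential(c(1, 2), c(3, 2), terms = 2), "at least 4")
  expect_error(fit_exponential(1, 3), "at least 2")
  expect_error(fit_exponential(c(1, 2, 3), c(1, 0, 1)), "positive")
})
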