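test_that("piecewise integration: rectangle, closed form, single point", {
  # constant 10 %IA over [0, 10 h], no tail -> 10% * 10 h / 100 = 1 MBq h
  cur <- make_curves(rep("liver", 2), c(0, 10), c(10, 10),
                     physical_decay = "Lu-177")
  expect_equal(integrate_tac(cur, tail = "none")$a_tilde_mbq_h, 1,
               tolerance = 1e-12)

  # dense monoexponential with effective half-life 50 h: closed form
  # A0/lambda/100 = 10 / (ln2/50) / 100 = 7.213 MBq h per MBq
  cur <- mono_curve(A0 = 10, hl_h = 50, dt_h = 0.1, t_max = 400)
  got <- integrate_tac(cur, tail = "fitted_terminal")$a_tilde_mbq_h
  expect_equal(got, 10 / (log(2) / 50) / 100, tolerance = 1e-3)

  # single sample at t = 0 with a physical tail: A0/lambda
  cur1 <- make_curves("liver", 0, 10, physical_decay = "Lu-177")
  got1 <- integrate_tac(cur1, tail = "physical_decay")$a_tilde_mbq_h
  expect_equal(got1, 0.1 / (log(2) / 159.5), tolerance = 1e-4)
  expect_equal(got1, 23.01, tolerance = 1e-3)

  # purely biological curves are refused (divergent physical tail)
  bio <- make_curves("liver", c(0, 10), c(10, 10))
  expect_error(integrate_tac(bio), "no physical decay")
})

test_that("head model choice controls the [0, t1] segment", {
  cur <- make_curves(rep("blood", 2), c(4, 8), c(10, 10),
                     physical_decay = "Lu-177")
  const <- integrate_tac(cur, tail = "none", head_model = "constant")
  ramp <- integrate_tac(cur, tail = "none", head_model = "linear_zero")
  expect_equal(const$a_tilde_mbq_h, (4 * 10 + 4 * 10) / 100)
  expect_equal(ramp$a_tilde_mbq_h, (4 * 10 / 2 + 4 * 10) / 100)
})

test_that("trapezoid integration converges to the closed form as the grid densifies", {
  hl <- 30; lam <- log(2) / hl; A0 <- 10
  exact <- A0 / lam / 100
  errs <- vapply(c(8, 4, 2, 1), function(step) {
    t <- seq(0, 600, by = step)
    cur <- make_curves(rep("t", length(t)), t, A0 * exp(-lam * t),
                       physical_decay = "Lu-177")
    got <- integrate_tac(cur, tail = "fitted_terminal")$a_tilde_mbq_h
    abs(got - exact) / exact
  }, numeric(1))
  expect_true(all(diff(errs) < 0))        # strictly decreasing error
  expect_lt(errs[length(errs)], 1e-4)
})

test_that("dose convolution sums source contributions", {
  mk_cum <- function(organs, a) {
    cur <- make_curves(organs, rep(0, length(organs)), rep(1, length(organs)),
                       physical_decay = "Lu-177")
    cum <- integrate_tac(cur, tail = "none")
    cum$a_tilde_mbq_h <- a
    cum
  }
  # all-zero kernel -> all doses zero
  s0 <- svalue_matrix(matrix(0, 2, 2, dimnames = list(c("liver", "tumor"),
                                                      c("liver", "tumor"))))
  expect_true(all(absorbed_dose(mk_cum(c("liver", "tumor"), c(5, 3)),
                                s0)$gy_per_mbq == 0))
  # single-organ self dose
  s1 <- svalue_matrix(matrix(0.2, 1, 1, dimnames = list("liver", "liver")))
  expect_equal(absorbed_dose(mk_cum("liver", 10), s1)$gy_per_mbq, 2.0)
  # two sources, one target row: dot product
  s2 <- svalue_matrix(matrix(c(0.1, 0.05), 1, 2,
                             dimnames = list("tumor", c("a1", "a2"))))
  expect_equal(absorbed_dose(mk_cum(c("a1", "a2"), c(5, 10)), s2)$gy_per_mbq,
               1.0)
  # sources absent from the S-matrix are a hard error
  expect_error(absorbed_dose(mk_cum(c("liver", "brain"), c(1, 1)), s1),
               "missing from S-matrix")
  # S-matrix sources without cumulated activity contribute zero, with warning
  s3 <- svalue_matrix(matrix(c(0.2, 0, 0, 0.2), 2, 2,
                             dimnames = list(c("liver", "tumor"),
                                             c("liver", "tumor"))))
  expect_warning(r <- absorbed_dose(mk_cum("liver", 10), s3),
                 "contributing zero")
  expect_equal(dose_coefficient(r, "tumor"), 0)
  # unit label must match
  sbad <- svalue_matrix(matrix(1, 1, 1, dimnames = list("liver", "liver")),
                        units_label = "mGy_per_kBq_s")
  expect_error(absorbed_dose(mk_cum("liver", 1), sbad), "units")
})

test_that("convolution equals a brute-force double loop on random instances", {
  for (seed in 1:8) {
    inst <- random_dose_instance(sample(2:6, 1), seed = 100 + seed)
    cur <- make_curves(inst$organs, rep(0, length(inst$organs)),
                       rep(1, length(inst$organs)), physical_decay = "Lu-177")
    cum <- integrate_tac(cur, tail = "none")
    cum$a_tilde_mbq_h <- inst$a[cum$organ]
    got <- absorbed_dose(cum, svalue_matrix(inst$S))
    brute <- vapply(inst$organs, function(tg) {
      acc <- 0
      for (src in inst$organs) acc <- acc + inst$a[[src]] * inst$S[tg, src]
      acc
    }, numeric(1))
    expect_equal(stats::setNames(got$gy_per_mbq, got$target),
                 brute[got$target], tolerance = 1e-12)
  }
})

test_that("pointwise-increasing a source curve never decreases any dose", {
  set.seed(5)
  organs <- c("liver", "tumor", "kidneys")
  S <- matrix(runif(9, 0, 0.3), 3, 3, dimnames = list(organs, organs))
  sv <- svalue_matrix(S)
  t <- c(4, 24, 48, 72)
  base <- c(9, 7, 5, 4)
  mk <- function(liver_curve) {
    cur <- make_curves(rep(organs, each = 4), rep(t, 3),
                       c(liver_curve, 12, 12.5, 12.9, 12, 4, 3, 2, 1.5),
                       physical_decay = "Lu-177")
    absorbed_dose(integrate_tac(cur), sv)$gy_per_mbq
  }
  d0 <- mk(base)
  d1 <- mk(base + c(0, 1, 0.5, 2))
  expect_true(all(d1 >= d0 - 1e-12))
})

test_that("schedule totals are linear sums of fraction doses", {
  # printed tumor coefficients: fraction doses match the treatment table
  s_single <- schedule_dose(2.04, schedule(9.25))
  expect_equal(s_single$total_gy, 18.9, tolerance = 0.05)
  s_frac <- schedule_dose(1.68, schedule(c(9.25, 9.25), c(0, 240)))
  expect_equal(s_frac$fraction_gy, c(15.54, 15.54), tolerance = 1e-10)
  expect_equal(s_frac$total_gy, 31.0, tolerance = 0.1)
  expect_equal(schedule_dose(1.68, schedule(numeric(0), numeric(0)))$total_gy,
               0)
  expect_error(schedule(c(-1, 2)), "positive")
  expect_error(schedule(c(1, 2), c(10, 0)), "non-decreasing")
})

test_that("dose linearity and fraction additivity hold exactly", {
  set.seed(3)
  for (i in 1:6) {
    coef <- runif(1, 0.1, 3)
    act <- runif(sample(1:4, 1), 1, 20)
    tms <- sort(runif(length(act), 0, 500))
    sch <- schedule(act, tms)
    total <- schedule_dose(coef, sch)$total_gy
    # scaling all injected activities by k scales the total by k
    k <- runif(1, 0.1, 5)
    expect_equal(schedule_dose(coef, schedule(act * k, tms))$total_gy,
                 k * total, tolerance = 1e-12)
    # sum of single-fraction decompositions equals the schedule total
    parts <- vapply(seq_along(act), function(j)
      schedule_dose(coef, schedule(act[j], tms[j]))$total_gy, numeric(1))
    expect_equal(sum(parts), total, tolerance = 1e-12)
  }
})

test_that("dose ratios reproduce the published tumor:liver contrast", {
  expect_equal(round(dose_ratio(c(tumor = 2.04, liver = 1.12),
                                "tumor", "liver"), 1), 1.8)
  expect_equal(round(dose_ratio(c(tumor = 1.68, liver = 1.28),
                                "tumor", "liver"), 1), 1.3)
  expect_equal(dose_ratio(c(tumor = 1.5, liver = 1.5), "tumor", "liver"), 1)
  expect_error(dose_ratio(c(tumor = 1, liver = 0), "tumor", "liver"),
               "undefined")
})
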