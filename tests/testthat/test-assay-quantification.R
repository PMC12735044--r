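test_that("scavenging percentage follows the inhibition formula", {
  # As = Ab: no signal left, full scavenging
  expect_equal(scavengingPercent(0.3, 0.3, 0.7), 100)
  # As - Ab = Ac: full signal, no scavenging
  expect_equal(scavengingPercent(0.9, 0.1, 0.8), 0)
  # hand arithmetic: (1 - 0.4/0.8) * 100
  expect_equal(scavengingPercent(0.5, 0.1, 0.8), 50)
  # pro-oxidant readings are reported as-is, not clamped
  expect_lt(scavengingPercent(1.5, 0.1, 0.8), 0)
  expect_gt(scavengingPercent(0.05, 0.2, 0.8), 100)
})

test_that("scavenging percentage rejects impossible absorbances", {
  expect_error(scavengingPercent(0.5, 0.1, 0, assay = "DPPH"),
               class = "strainscreen_degenerate_error")
  expect_error(scavengingPercent(0.5, 0.1, 0, assay = "DPPH"), "DPPH")
  expect_error(scavengingPercent(-0.1, 0.1, 0.8),
               class = "strainscreen_validation_error")
  expect_error(scavengingPercent(NA, 0.1, 0.8),
               class = "strainscreen_validation_error")
})

test_that("scavenging percentage is invariant to common positive rescaling", {
  set.seed(11)
  for (k in 1:25) {
    ab <- runif(1, 0.2, 0.4)
    as_ <- ab + runif(1, -0.05, 0.6)
    ac <- runif(1, 0.2, 1.5)
    lambda <- runif(1, 0.1, 3)
    base <- scavengingPercent(as_, ab, ac)
    # scale the net signal (As - Ab) and the control together
    scaled <- scavengingPercent(ab + lambda * (as_ - ab), ab, lambda * ac)
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("standard-curve fitting recovers known lines exactly", {
  x <- c(0, 20, 50, 80, 120)
  curve <- fitStandardCurve(x, 0.0039 * x + 0.0033, unit = "mg/L")
  expect_equal(curve@slope, 0.0039, tolerance = 1e-10)
  expect_equal(curve@intercept, 0.0033, tolerance = 1e-10)
  expect_equal(curve@rSquared, 1.0, tolerance = 1e-10)

  # two points always define the line
  c2 <- fitStandardCurve(c(1, 3), c(0.2, 0.8))
  expect_equal(c2@rSquared, 1.0, tolerance = 1e-12)
  expect_equal(c2@slope, 0.3, tolerance = 1e-12)

  # symmetric noise around a known line leaves the OLS slope untouched
  xs <- c(10, 20, 30, 40)
  delta <- 0.05
  ys <- 2 * xs + 1 + c(delta, -delta, -delta, delta)
  expect_equal(fitStandardCurve(xs, ys)@slope, 2, tolerance = 1e-10)

  expect_error(fitStandardCurve(c(5, 5, 5), c(0.1, 0.2, 0.3)),
               class = "strainscreen_degenerate_error")
  expect_error(fitStandardCurve(1, 0.1),
               class = "strainscreen_validation_error")
})

test_that("curve inversion is the exact inverse of forward evaluation", {
  eps <- epsGlucoseCurve()
  expect_equal(invertStandardCurve(eps, 0.0033), 0)
  expect_equal(invertStandardCurve(eps, 0.3933), 100, tolerance = 1e-10)
  expect_equal(invertStandardCurve(linearStandardCurve(2, 0), 1), 0.5)

  set.seed(21)
  conc <- runif(40, 0, 500)
  abs_fwd <- eps@slope * conc + eps@intercept
  expect_equal(invertStandardCurve(eps, abs_fwd), conc, tolerance = 1e-12)

  # readings below the intercept flag, but do not clamp, the result
  expect_warning(neg <- invertStandardCurve(eps, 0.001),
                 class = "strainscreen_negative_concentration")
  expect_lt(neg, 0)
})

test_that("FRAP equivalent shares the inversion contract on a FeSO4 curve", {
  crv <- frapSyntheticCurve()
  expect_equal(frapEquivalent(0.596, crv), 273, tolerance = 1e-10)
  expect_equal(frapEquivalent(0.05, crv), 0)
})

test_that("titratable acidity follows the titrimetric conversion", {
  expect_equal(titratableAcidity(0), 0)
  # 0.1 mol/L x 10 mL = 1 mmol NaOH -> 90.08 mg lactic acid in 10 mL
  expect_equal(titratableAcidity(10, 0.1, 10), 9.008, tolerance = 1e-12)
  # linear in titrant volume, inverse-linear in sample volume
  v <- runif(10, 0.5, 20)
  expect_equal(titratableAcidity(2 * v, 0.1, 10),
               2 * titratableAcidity(v, 0.1, 10), tolerance = 1e-12)
  expect_equal(titratableAcidity(v, 0.1, 20),
               titratableAcidity(v, 0.1, 10) / 2, tolerance = 1e-12)
  expect_error(titratableAcidity(5, 0.1, 0),
               class = "strainscreen_degenerate_error")
})

test_that("inhibition zones honour the 9 mm well convention", {
  expect_equal(zoneDiameter(c(0, 12, 30)), c(0, 12, 30))
  expect_equal(zoneDiameter(c(0, 12, 30), net = TRUE), c(0, 3, 21))
  expect_error(zoneDiameter(5), class = "strainscreen_validation_error")
})

test_that("long-format replicate records reduce to mean +/- SD of percentages", {
  rec <- expand.grid(strain = c("A", "B"), assay = c("DPPH", "ABTS"),
                     replicate = 1:3, role = c("sample", "blank", "control"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec$value <- ifelse(rec$role == "control", 0.8,
               ifelse(rec$role == "blank", 0.1,
                      0.1 + 0.008 * (rec$replicate - 2) +
                        ifelse(rec$strain == "A", 0.4, 0.2)))
  out <- quantifyAssays(rec)
  expect_equal(nrow(out), 4L)
  a_dpph <- out[out$strain == "A" & out$indicator == "DPPH", ]
  expect_equal(a_dpph$mean, 50, tolerance = 1e-12)  # mean of 49, 50, 51
  expect_equal(a_dpph$sd, sd(c(49, 50, 51)), tolerance = 1e-12)
  expect_equal(a_dpph$n, 3L)
  b_abts <- out[out$strain == "B" & out$indicator == "ABTS", ]
  expect_equal(b_abts$mean, 75, tolerance = 1e-12)

  # a missing role is a hard validation error
  expect_error(quantifyAssays(rec[rec$role != "blank", ]),
               class = "strainscreen_validation_error")
})
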