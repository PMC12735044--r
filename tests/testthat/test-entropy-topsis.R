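test_that("entropy weights follow the Shannon definition", {
  # hand-evaluated two-strain column: p = {0.25, 0.75}
  x <- cbind(a = c(1, 3), b = c(2, 2.5))
  w <- entropyWeights(x)
  e_hand <- -(0.25 * log(0.25) + 0.75 * log(0.75)) / log(2)
  expect_equal(unname(w@entropy["a"]), e_hand, tolerance = 1e-12)
  expect_equal(e_hand, 0.81128, tolerance = 1e-5)
  # Dj = 1 - Ej exactly, weights sum to one
  expect_equal(w@utility, 1 - w@entropy, tolerance = 1e-15)
  expect_equal(sum(w@weight), 1, tolerance = 1e-12)

  # a constant column carries no information
  wc <- entropyWeights(cbind(flat = c(4, 4, 4), var = c(1, 2, 3)))
  expect_equal(unname(wc@entropy["flat"]), 1)
  expect_equal(unname(wc@weight["flat"]), 0)

  # all-constant matrix has no usable information at all
  expect_error(entropyWeights(cbind(a = c(1, 1), b = c(2, 2))),
               class = "strainscreen_degenerate_error")
  expect_error(entropyWeights(cbind(a = c(-1, 2))),
               class = "strainscreen_validation_error")
})

test_that("closeness reproduces the printed reference scores", {
  t3 <- table3Fixture()
  ci <- closeness(t3$d_plus, t3$d_minus)
  # every printed Ci is recovered to within one unit in its printed last
  # place (the distances feeding the division are themselves rounded)
  for (i in seq_len(nrow(t3))) {
    digits <- nchar(sub("^[^.]*\\.", "", format(t3$ci[i])))
    expect_lte(abs(round(ci[i], digits) - t3$ci[i]), 10^-digits + 1e-12)
  }
  expect_equal(closeness(0, 0.4), 1)
  expect_equal(closeness(0.4, 0), 0)
  expect_error(closeness(0, 0), class = "strainscreen_degenerate_error")
  expect_error(closeness(-0.1, 0.5), class = "strainscreen_validation_error")
})

test_that("ranking is competition-style with lexicographic tie order", {
  t3 <- table3Fixture()
  ci <- setNames(closeness(t3$d_plus, t3$d_minus), t3$strain)
  rk <- rankStrains(ci)
  expect_equal(rk$strain[1], "Leu. lactis W3J")
  expect_equal(rk$strain[7], "Leu. mesenteroides W3E")
  expect_equal(rk$rank, t3$rank[match(rk$strain, t3$strain)])

  tied <- rankStrains(c(b = 0.4, a = 0.4, c = 0.2))
  expect_equal(tied$rank, c(1L, 1L, 3L))
  expect_equal(tied$strain, c("a", "b", "c"))  # lexicographic among ties
  expect_equal(rankStrains(c(a = 1, b = 1, c = 1))$rank, rep(1L, 3))
  # reversing all scores reverses the ranking
  fwd <- rankStrains(c(a = 0.1, b = 0.5, c = 0.9))
  rev_ <- rankStrains(c(a = 0.9, b = 0.5, c = 0.1))
  expect_equal(rev_$strain, rev(fwd$strain))
})

test_that("TOPSIS honours its boundary identities", {
  # a strain strictly best everywhere sits at the ideal point
  x <- rbind(best = c(9, 8, 7), mid = c(5, 5, 5), low = c(1, 2, 3))
  colnames(x) <- c("i1", "i2", "i3")
  s <- topsisScores(x, entropyWeights(x))
  expect_equal(unname(s@dPlus["best"]), 0, tolerance = 1e-15)
  expect_equal(unname(s@closeness["best"]), 1, tolerance = 1e-15)
  expect_equal(unname(s@rank["best"]), 1L)

  # identical strains are fully symmetric: tied ranks, Ci = 0.5
  y <- rbind(a = c(2, 3), b = c(2, 3))
  sy <- topsisScores(y, c(0.5, 0.5))
  expect_equal(unname(sy@closeness), c(0.5, 0.5))
  expect_equal(unname(sy@rank), c(1L, 1L))
})

test_that("pipeline agrees with the independent naive oracle", {
  set.seed(42)
  for (k in 1:200) {
    n <- sample(3:6, 1)
    p <- sample(2:5, 1)
    x <- random_matrix(n, p)
    ref <- oracle_entropy_topsis(x)
    w <- entropyWeights(x)
    s <- topsisScores(x, w)
    expect_equal(unname(w@entropy), ref$entropy, tolerance = 1e-12)
    expect_equal(unname(w@weight), ref$weight, tolerance = 1e-12)
    expect_equal(unname(s@dPlus), ref$dplus, tolerance = 1e-12)
    expect_equal(unname(s@dMinus), ref$dminus, tolerance = 1e-12)
    expect_equal(unname(s@closeness), ref$ci, tolerance = 1e-12)
  }
})

test_that("scores are invariant to positive rescaling of any column", {
  set.seed(7)
  for (k in 1:20) {
    x <- random_matrix(5, 4)
    j <- sample(4, 1)
    y <- x
    y[, j] <- y[, j] * runif(1, 0.01, 50)
    wx <- entropyWeights(x); wy <- entropyWeights(y)
    expect_equal(wx@entropy, wy@entropy, tolerance = 1e-10)
    expect_equal(wx@weight, wy@weight, tolerance = 1e-10)
    sx <- topsisScores(x, wx); sy <- topsisScores(y, wy)
    expect_equal(sx@closeness, sy@closeness, tolerance = 1e-10)
  }
})

test_that("flipping every orientation maps Ci to 1 - Ci", {
  set.seed(13)
  for (k in 1:20) {
    x <- random_matrix(5, 4)
    w <- entropyWeights(x)
    s_benefit <- topsisScores(x, w, orientation = "benefit")
    s_cost <- topsisScores(x, w, orientation = "cost")
    expect_equal(s_cost@dPlus, s_benefit@dMinus, tolerance = 1e-12)
    expect_equal(s_cost@dMinus, s_benefit@dPlus, tolerance = 1e-12)
    expect_equal(s_cost@closeness, 1 - s_benefit@closeness, tolerance = 1e-12)
  }
})

test_that("with fixed weights, improving a strain never lowers its score", {
  set.seed(29)
  for (k in 1:40) {
    x <- random_matrix(4, 3)
    w <- rep(1 / 3, 3)
    i <- sample(4, 1); j <- sample(3, 1)
    before <- topsisScores(x, w)@closeness[i]
    x2 <- x
    x2[i, j] <- x2[i, j] * runif(1, 1.01, 1.5)
    after <- topsisScores(x2, w)@closeness[i]
    expect_gte(after, before - 1e-12)
  }
})
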