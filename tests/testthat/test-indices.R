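test_that("TAWSS matches closed forms on analytic patterns", {
  expect_equal(tawss(synthetic_wall_traction("constant", amplitude = 3)),
               rep(3, 8))
  # mean of |A sin| over a cycle is 2A/pi
  s <- synthetic_wall_traction("reversing", amplitude = 2, n_time = 100)
  expect_equal(tawss(s), rep(4 / pi, 8), tolerance = 5e-3)
  z <- synthetic_wall_traction("constant", amplitude = 0)
  expect_equal(tawss(z), rep(0, 8))
  expect_error(wall_traction_series(1:3 * 1e-3, (0:2) / 3,
                                    array(1, c(3, 3, 2)), 1))
})

test_that("OSI respects its range and degenerate conventions", {
  s <- synthetic_wall_traction("offset_sine", amplitude = 2, offset = 1)
  o <- osi(s)
  expect_true(all(o >= 0 & o <= 0.5))
  # zero traction everywhere -> OSI 0 by convention
  z <- synthetic_wall_traction("constant", amplitude = 0)
  expect_equal(osi(z), rep(0, 8))
})

test_that("RRT singularity handling follows the capped-flag design", {
  r <- rrt(osi_values = 0, tawss_values = 2)
  expect_equal(r$rrt, 0.5)
  expect_false(r$flag)
  expect_equal(rrt(0.25, 1)$rrt, 2)
  r5 <- rrt(0.5, 3, epsilon = 1e-3)
  expect_true(r5$flag)
  expect_equal(r5$rrt, 1 / (1e-3 * 3))
  rz <- rrt(0, 0)
  expect_true(rz$flag)
  expect_equal(rz$rrt, Inf)
  expect_error(rrt(0.1, 1, epsilon = 0), "positive")
})

test_that("index profile composes the chain with positional independence", {
  con <- synthetic_wall_traction("constant", amplitude = 2, n_points = 4)
  prof <- index_profile(con)
  expect_equal(prof$tawss, rep(2, 4))
  expect_equal(prof$osi, rep(0, 4))
  expect_equal(prof$rrt, rep(0.5, 4))
  expect_false(any(prof$rrt_flag))
  rev <- synthetic_wall_traction("reversing", amplitude = 2, n_points = 4)
  expect_true(all(index_profile(rev)$rrt_flag))
  # mixed fixture: constant on half the positions, reversing on the rest
  mix <- con
  mix$tau[3:4, , ] <- rev$tau[3:4, , ]
  pm <- index_profile(mix)
  expect_equal(pm$rrt_flag, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("indices are quadrature-stable under time refinement", {
  for (pat in c("offset_sine", "reversing", "rotating")) {
    a <- synthetic_wall_traction(pat, amplitude = 1.3, n_time = 100)
    b <- synthetic_wall_traction(pat, amplitude = 1.3, n_time = 200)
    expect_equal(tawss(a), tawss(b), tolerance = 5e-3)
    expect_equal(osi(a), osi(b), tolerance = 5e-3)
  }
})

test_that("index chain obeys scale equivariance and rotation invariance", {
  s <- synthetic_wall_traction("offset_sine", amplitude = 1, offset = 1.4)
  k <- 3.7
  sk <- s; sk$tau <- s$tau * k
  expect_equal(tawss(sk), k * tawss(s))
  expect_equal(osi(sk), osi(s))
  p1 <- index_profile(s); pk <- index_profile(sk)
  ok <- !p1$rrt_flag
  expect_equal(pk$rrt[ok], p1$rrt[ok] / k)
  # global rotation of all traction vectors leaves OSI unchanged
  th <- 0.83
  rot <- s
  rot$tau[, , 1] <- cos(th) * s$tau[, , 1] - sin(th) * s$tau[, , 2]
  rot$tau[, , 2] <- sin(th) * s$tau[, , 1] + cos(th) * s$tau[, , 2]
  expect_equal(osi(rot), osi(s), tolerance = 1e-12)
})

test_that("index CSV export carries the documented columns", {
  prof <- index_profile(synthetic_wall_traction("constant", amplitude = 1))
  f <- tempfile(fileext = ".csv")
  indices_to_csv(prof, f)
  df <- read.csv(f)
  expect_named(df, c("position_m", "tawss_Pa", "osi", "rrt_inv_Pa",
                     "rrt_flag"))
  expect_equal(df$tawss_Pa, prof$tawss)
})
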