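test_that("identical, disjoint, and hand-computed configurations", {
  sq <- square_region
  expect_equal(overlap_proportion(list(sq(0, 0, 2), sq(0, 0, 2),
                                       sq(0, 0, 2)))$proportion, 1,
               tolerance = 1e-6)
  expect_equal(overlap_proportion(list(sq(0, 0, 2), sq(5, 0, 2),
                                       sq(10, 0, 2)))$proportion, 0)
  # [0,2]^2 and [1,3]^2 overlap in 1; disjoint third square adds 4:
  # overlap 1, total 11
  r <- overlap_proportion(list(sq(0, 0, 2), sq(1, 1, 2), sq(10, 10, 2)))
  expect_equal(r$overlap_area, 1, tolerance = 1e-6)
  expect_equal(r$total_area, 11, tolerance = 1e-6)
  expect_equal(r$proportion, 1 / 11, tolerance = 1e-6)
  expect_equal(r$per_player_areas, c(4, 4, 4), tolerance = 1e-6)
})

test_that("triply covered ground counts once", {
  sq <- square_region
  # three unit squares all containing [0.5, 1] x [0, 1]:
  # pairwise intersections union to [0.25, 1.25] x [0, 1] roughly
  r <- overlap_proportion(list(sq(0, 0, 1), sq(0.25, 0, 1), sq(0.5, 0, 1)))
  # union [0, 1.5] x [0, 1] = 1.5; covered >= twice: [0.25, 1.25] = 1.0
  expect_equal(r$total_area, 1.5, tolerance = 1e-6)
  expect_equal(r$overlap_area, 1.0, tolerance = 1e-6)
})

test_that("degenerate total area yields a flagged missing proportion", {
  pt <- list(list(x = c(0, 0, 0), y = c(0, 0, 0)))
  r <- overlap_proportion(list(pt, pt, pt))
  expect_true(r$degenerate)
  expect_true(is.na(r$proportion))
  expect_error(overlap_proportion(list(pt)), "at least two")
})

test_that("proportion is invariant under rigid motions and rescaling", {
  set.seed(41)
  polys <- lapply(1:3, function(i) {
    alpha_shape(cbind(rnorm(120, i * 2), rnorm(120, i)))
  })
  p0 <- overlap_proportion(polys)$proportion
  th <- 0.83
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- lapply(polys, function(p) {
    alpha_shape(t(Rm %*% t(p$points)) + 7)
  })
  expect_equal(overlap_proportion(moved)$proportion, p0, tolerance = 0.02)
  scaled <- lapply(polys, function(p) alpha_shape(p$points * 3.5))
  expect_equal(overlap_proportion(scaled)$proportion, p0, tolerance = 1e-6)
})

test_that("proportions agree with the Monte-Carlo area oracle", {
  set.seed(55)
  for (rep in 1:3) {
    regions <- lapply(1:3, function(i) {
      alpha_shape(cbind(runif(200, 0, 60) + 15 * i,
                        runif(200, 0, 60)))$rings
    })
    mine <- overlap_proportion(regions)$proportion
    mc <- oracle_overlap_mc(regions, n_pts = 1e5, seed = 500 + rep)
    expect_equal(mine, mc, tolerance = 0.02)
  }
})

test_that("trial overlap lies in [0, 1] and responds to strategy", {
  tr <- small_trial()
  r <- trial_overlap(tr)
  expect_gte(r$proportion, 0)
  expect_lte(r$proportion, 1)
  expect_equal(r$proportion, r$overlap_area / r$total_area)
})
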