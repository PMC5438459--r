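test_that("nearest assignment matches the exhaustive oracle row-for-row", {
  set.seed(31)
  ctr <- random_centers(50)
  pts <- random_points(500)
  ind <- data.frame(individual_id = sprintf("I%03d", 1:500),
                    lat = pts$lat, lon = pts$lon, region_id = "", diagnosed = FALSE)
  got <- assign_nearest(ind, ctr)
  want <- oracle_nearest(pts, ctr)
  expect_identical(got$center_id, want$center_id)
  expect_equal(got$distance_km, want$distance_km, tolerance = 1e-9)
  expect_true(all(is.na(got$tier_km)))
  expect_false(any(got$fallback))
  expect_identical(got$individual_id, ind$individual_id)
})

test_that("individuals at center locations get distance zero; one center takes all", {
  ctr <- tiny_centers()
  ind <- data.frame(individual_id = c("I1", "I2"),
                    lat = ctr$lat, lon = ctr$lon, region_id = "", diagnosed = FALSE)
  got <- assign_nearest(ind, ctr)
  expect_equal(got$distance_km, c(0, 0))
  expect_identical(got$center_id, c("C1", "C2"))
  one <- assign_nearest(ind, ctr[1, ])
  expect_true(all(one$center_id == "C1"))
})

test_that("tiered assignment picks the smallest viable tier", {
  # one center 10 km away: deterministic assignment at tier 25
  ctr <- data.frame(center_id = "C1", name = "c", lat = 40, lon = -100, s = 5, o = 200)
  loc <- geo_destination(40, -100, 90, 10)
  ind <- data.frame(individual_id = "I1", lat = loc$lat, lon = loc$lon,
                    region_id = "", diagnosed = FALSE)
  got <- assign_tiered_random(ind, ctr, seed = 1)
  expect_identical(got$center_id, "C1")
  expect_equal(got$tier_km, 25)
  expect_false(got$fallback)
  expect_equal(got$distance_km, 10, tolerance = 1e-9)
})

test_that("tier minimality holds on random instances", {
  set.seed(77)
  ctr <- random_centers(30)
  pts <- random_points(300)
  ind <- data.frame(individual_id = sprintf("I%03d", 1:300),
                    lat = pts$lat, lon = pts$lon, region_id = "", diagnosed = FALSE)
  tiers <- c(25, 100, 500, 3000)
  got <- assign_tiered_random(ind, ctr, tiers, seed = 5)
  for (i in seq_len(nrow(got))) {
    d <- oracle_dist_km(pts$lat[i], pts$lon[i], ctr$lat, ctr$lon)
    if (!got$fallback[i]) {
      expect_lte(got$distance_km[i], got$tier_km[i])
      smaller <- tiers[tiers < got$tier_km[i]]
      for (t in smaller) expect_equal(sum(d <= t), 0)
      # the recorded tier really contains the assigned center
      expect_true(got$center_id[i] %in% ctr$center_id[d <= got$tier_km[i]])
    }
  }
})

test_that("in-tier choice is uniform between two reachable centers", {
  base <- c(40, -100)
  c1 <- geo_destination(base[1], base[2], 0, 10)
  c2 <- geo_destination(base[1], base[2], 180, 20)
  ctr <- data.frame(center_id = c("C1", "C2"), name = c("a", "b"),
                    lat = c(c1$lat, c2$lat), lon = c(c1$lon, c2$lon), s = 5, o = 200)
  n <- 10000
  ind <- data.frame(individual_id = sprintf("I%05d", 1:n),
                    lat = rep(base[1], n), lon = rep(base[2], n),
                    region_id = "", diagnosed = FALSE)
  got <- assign_tiered_random(ind, ctr, seed = 8)
  frac <- mean(got$center_id == "C1")
  expect_gte(frac, 0.48)
  expect_lte(frac, 0.52)
  expect_true(all(got$tier_km == 25))
})

test_that("individuals beyond the largest tier fall back to nearest, flagged", {
  ctr <- data.frame(center_id = "C1", name = "c", lat = 0, lon = 100, s = 5, o = 200)
  ind <- data.frame(individual_id = "I1", lat = 0, lon = -100,
                    region_id = "", diagnosed = FALSE)
  got <- assign_tiered_random(ind, ctr, c(25, 100, 500, 3000), seed = 2)
  expect_true(got$fallback)
  expect_true(is.na(got$tier_km))
  expect_identical(got$center_id, "C1")
  expect_gt(got$distance_km, 3000)
})

test_that("a single huge tier with one center reduces to nearest assignment", {
  set.seed(13)
  ctr <- random_centers(1)
  pts <- random_points(100)
  ind <- data.frame(individual_id = sprintf("I%03d", 1:100),
                    lat = pts$lat, lon = pts$lon, region_id = "", diagnosed = FALSE)
  tr <- assign_tiered_random(ind, ctr, tiers_km = 1e6, seed = 4)
  nn <- assign_nearest(ind, ctr)
  expect_identical(tr$center_id, nn$center_id)
  expect_equal(tr$distance_km, nn$distance_km)
  expect_false(any(tr$fallback))
})

test_that("assignment is deterministic under a seed and validates tiers", {
  set.seed(55)
  ctr <- random_centers(10)
  pts <- random_points(200)
  ind <- data.frame(individual_id = sprintf("I%03d", 1:200),
                    lat = pts$lat, lon = pts$lon, region_id = "", diagnosed = FALSE)
  a1 <- assign_tiered_random(ind, ctr, seed = 6)
  a2 <- assign_tiered_random(ind, ctr, seed = 6)
  expect_identical(a1, a2)
  expect_error(assign_tiered_random(ind, ctr, c(100, 25)), "ascending")
  expect_error(assign_tiered_random(ind, ctr[0, ]), "non-empty")
})

test_that("per-center counts partition the individuals and include zeros", {
  set.seed(65)
  ctr <- random_centers(20)
  pts <- random_points(300)
  ind <- data.frame(individual_id = sprintf("I%03d", 1:300),
                    lat = pts$lat, lon = pts$lon, region_id = "", diagnosed = FALSE)
  for (a in list(assign_nearest(ind, ctr),
                 assign_tiered_random(ind, ctr, seed = 7))) {
    counts <- per_center_counts(a, ctr)
    expect_equal(sum(counts$n_assigned), 300)
    expect_setequal(counts$center_id, ctr$center_id)
    # brute-force tally oracle
    want <- as.integer(table(factor(a$center_id, levels = counts$center_id)))
    expect_identical(counts$n_assigned, want)
  }
  empty <- per_center_counts(assign_nearest(ind[0, ], ctr), ctr)
  expect_true(all(empty$n_assigned == 0))
})
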