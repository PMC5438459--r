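center_with_load <- function(rl, lat = 40, lon = -100, id = "C1") {
  list(
    centers = data.frame(center_id = id, name = id, lat = lat, lon = lon,
                         s = 5, o = 200, stringsAsFactors = FALSE),
    loads = data.frame(center_id = id, rl = rl, stringsAsFactors = FALSE)
  )
}

test_that("screening fraction is the product of its two components", {
  expect_equal(derive_screening_fraction(0.065, 0.03), 0.00195)
  expect_equal(derive_screening_fraction(0.5, 0.5), 0.25)
  expect_equal(derive_screening_fraction(0.999, 0.999), 0.998001)
  expect_error(derive_screening_fraction(0, 0.5), "fractions")
  expect_error(derive_screening_fraction(0.5, 1), "fractions")
})

test_that("resource load is demand over capacity and linear in demand", {
  ctr <- tiny_centers()[1, ]
  counts <- data.frame(center_id = "C1", n_assigned = 512821)
  rl <- resource_load(ctr, counts)$rl
  expect_equal(rl, 1.0, tolerance = 1e-3)
  counts$n_assigned <- 3076923
  expect_equal(resource_load(ctr, counts)$rl, 6.0, tolerance = 1e-3)
  counts$n_assigned <- 0
  expect_equal(resource_load(ctr, counts)$rl, 0)
  # linearity in n_assigned
  base <- resource_load(ctr, data.frame(center_id = "C1", n_assigned = 1000))$rl
  for (k in c(0, 1, 3, 10)) {
    expect_equal(
      resource_load(ctr, data.frame(center_id = "C1", n_assigned = 1000 * k))$rl,
      k * base
    )
  }
  expect_error(resource_load(ctr, data.frame(center_id = "C1", n_assigned = -1)),
               "n_assigned")
  bad <- ctr; bad$s <- 0
  expect_error(resource_load(bad, counts), "s and o")
})

test_that("availability satisfies the adequate-resource boundary property", {
  # one center 10 km away with RL = 1 and z = 30 gives RA exactly 1
  loc <- geo_destination(40, -100, 45, 10)
  cw <- center_with_load(1)
  expect_equal(resource_availability(loc$lat, loc$lon, cw$loads, cw$centers), 1)
  # spare capacity is clamped: RL = 0.2 still contributes exactly 1
  cw2 <- center_with_load(0.2)
  expect_equal(resource_availability(loc$lat, loc$lon, cw2$loads, cw2$centers), 1)
  # unclamped variant lets spare capacity exceed 1
  p_unc <- metric_params(clamp_load_floor = FALSE)
  expect_equal(
    resource_availability(loc$lat, loc$lon, cw2$loads, cw2$centers, p_unc), 5
  )
})

test_that("availability halves at double the travel distance or double the load", {
  d60 <- geo_destination(40, -100, 90, 60)
  cw <- center_with_load(1)
  expect_equal(
    resource_availability(d60$lat, d60$lon, cw$loads, cw$centers), 0.5,
    tolerance = 1e-9
  )
  d10 <- geo_destination(40, -100, 90, 10)
  cw2 <- center_with_load(2)
  expect_equal(
    resource_availability(d10$lat, d10$lon, cw2$loads, cw2$centers), 0.5,
    tolerance = 1e-9
  )
  # no centers -> zero availability
  expect_equal(resource_availability(40, -100, cw$loads[0, ], cw$centers[0, ]), 0)
  # a center without a load row is an error
  expect_error(resource_availability(40, -100, cw$loads[0, ], cw$centers),
               "missing resource load")
})

test_that("availability is monotone in centers, load, and distance", {
  set.seed(9)
  pts <- random_points(20)
  ctr <- random_centers(15)
  loads <- data.frame(center_id = ctr$center_id, rl = runif(15, 0.1, 30))
  ra_all <- resource_availability(pts$lat, pts$lon, loads, ctr)
  # dropping a center never increases RA
  ra_less <- resource_availability(pts$lat, pts$lon, loads[-3, ], ctr[-3, ])
  expect_true(all(ra_less <= ra_all + 1e-12))
  # increasing one center's load never increases RA
  loads_up <- loads; loads_up$rl[1] <- loads_up$rl[1] * 4 + 2
  ra_up <- resource_availability(pts$lat, pts$lon, loads_up, ctr)
  expect_true(all(ra_up <= ra_all + 1e-12))
  # decay weights are non-increasing in distance for every decay choice
  d <- sort(runif(50, 0, 500))
  for (dec in c("capped_inverse", "exponential", "hard_cutoff")) {
    w <- resourcegaps:::decay_weight(d, 30, dec)
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("gap classification is strict at the RA = 1 threshold", {
  expect_false(classify_gap(1.0))
  expect_true(classify_gap(0.999))
  expect_true(classify_gap(0))
  expect_identical(classify_gap(c(0, 1, 2, 0.5)), c(TRUE, FALSE, FALSE, TRUE))
  expect_error(classify_gap(-0.1), "non-negative")
})

test_that("distance summaries reproduce hand-computed values", {
  asn <- data.frame(individual_id = sprintf("I%d", 1:4),
                    center_id = "C1", distance_km = c(10, 20, 30, 40),
                    tier_km = NA_real_, fallback = FALSE)
  s <- summarize_distances(asn, z = 30)
  expect_equal(s$mean_km, 25)
  expect_equal(s$median_km, 25)
  expect_equal(s$max_km, 40)
  expect_equal(s$pct_within_z, 75)
  expect_equal(s$sd_km, sqrt(500 / 3))
  expect_equal(s$n, 4)
  zero <- summarize_distances(data.frame(individual_id = c("a", "b", "c"),
                                         distance_km = c(0, 0, 0)))
  expect_equal(unlist(zero[c("mean_km", "sd_km", "median_km", "max_km")]),
               c(mean_km = 0, sd_km = 0, median_km = 0, max_km = 0))
  expect_equal(zero$pct_within_z, 100)
  one <- summarize_distances(data.frame(individual_id = "a", distance_km = 7))
  expect_equal(one$mean_km, 7)
  expect_equal(one$sd_km, 0)
})

test_that("distance summary matches a streaming recomputation on 1e5 values", {
  set.seed(2024)
  d <- rexp(1e5, rate = 1 / 80)
  asn <- data.frame(individual_id = as.character(seq_along(d)), distance_km = d)
  s <- summarize_distances(asn, z = 30)
  # Welford one-pass mean/variance as the independent route
  m <- 0; m2 <- 0; k <- 0
  for (x in d) {
    k <- k + 1
    delta <- x - m
    m <- m + delta / k
    m2 <- m2 + delta * (x - m)
  }
  expect_equal(s$mean_km, m, tolerance = 1e-9)
  expect_equal(s$sd_km, sqrt(m2 / (k - 1)), tolerance = 1e-9)
  expect_equal(s$median_km, unname(quantile(d, 0.5, type = 7)), tolerance = 1e-9)
  expect_equal(s$max_km, max(d))
  expect_equal(s$pct_within_z, 100 * sum(d <= 30) / k, tolerance = 1e-12)
})

test_that("diagnosed-only filtering works and empty filters error", {
  ind <- data.frame(individual_id = c("I1", "I2", "I3"), lat = 0, lon = 0,
                    region_id = "", diagnosed = c(TRUE, FALSE, TRUE))
  asn <- data.frame(individual_id = c("I1", "I2", "I3"),
                    center_id = "C1", distance_km = c(10, 100, 20))
  s <- summarize_distances(asn, diagnosed_only = TRUE, individuals = ind)
  expect_equal(s$n, 2)
  expect_equal(s$mean_km, 15)
  none <- ind; none$diagnosed <- FALSE
  expect_error(summarize_distances(asn, diagnosed_only = TRUE, individuals = none),
               "no individuals")
  expect_error(summarize_distances(asn, diagnosed_only = TRUE), "requires")
})

test_that("availability grid matches point-wise evaluation and flags gaps", {
  cw <- center_with_load(1)
  bbox <- c(39, 41, -101, -99)
  grid <- availability_grid(bbox, 0.25, cw$loads, cw$centers)
  expect_equal(nrow(grid), (ceiling(2 / 0.25) + 1)^2)
  ra_pt <- resource_availability(grid$lat, grid$lon, cw$loads, cw$centers)
  expect_identical(grid$ra, ra_pt)
  expect_identical(grid$gap, classify_gap(grid$ra))
  # within z of an RL = 1 center: RA exactly 1, not a gap
  d <- haversine_km(grid$lat, grid$lon, 40, -100)
  expect_true(all(grid$ra[d <= 30] == 1))
  expect_true(all(!grid$gap[d <= 30]))
  expect_true(all(grid$gap[d > 30]))
  # no centers: all zero, all gap
  g0 <- availability_grid(bbox, 0.5, cw$loads[0, ], cw$centers[0, ])
  expect_true(all(g0$ra == 0))
  expect_true(all(g0$gap))
  expect_error(availability_grid(bbox, 0, cw$loads, cw$centers), "resolution")
  expect_error(availability_grid(c(41, 39, -101, -99), 0.5, cw$loads, cw$centers),
               "well-ordered")
})
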