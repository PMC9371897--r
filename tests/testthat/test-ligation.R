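test_that("seal_nicks honors p, seed and masks", {
  lat <- build_lattice(builtin_design("J4-I"))
  expect_true(all(seal_nicks(lat, 1, seed = 1)$sealed))
  expect_false(any(seal_nicks(lat, 0, seed = 1)$sealed))
  a <- seal_nicks(lat, 0.5, seed = 7)
  b <- seal_nicks(lat, 0.5, seed = 7)
  expect_identical(a$sealed, b$sealed)
  expect_error(seal_nicks(lat, 1.5), "domain")
  masked <- apply_phosphorylation_mask(lat, lat$nicks$nick[1:10])
  oc <- seal_nicks(masked, 1, seed = 1)
  expect_equal(sum(oc$sealed), 10L)
  expect_false(any(oc$sealed[!masked$nicks$ligatable]))
})

test_that("sealed sets are nondecreasing in p under a common seed", {
  lat <- build_lattice(builtin_design("J4-I"))
  prev <- seal_nicks(lat, 0, seed = 3)$sealed
  for (p in seq(0.1, 1, by = 0.1)) {
    cur <- seal_nicks(lat, p, seed = 3)$sealed
    expect_true(all(cur[prev]))
    prev <- cur
  }
})

test_that("enumerate_products agrees with a union-find oracle", {
  lat <- build_lattice(builtin_design("J4-I_3x3"))
  set.seed(42)
  for (i in 1:25) {
    sealed_ids <- lat$nicks$nick[runif(nrow(lat$nicks)) < 0.5]
    oc <- ligation_outcome(lat, sealed_ids)
    got <- enumerate_products(lat, oc)
    want <- oracle_products(lat, sealed_ids)
    got <- got[order(got$members), ]
    want <- want[order(want$members), ]
    expect_equal(got$members, want$members)
    expect_equal(got$length_nt, want$length_nt)
    expect_equal(got$n_strands, want$n_strands)
    expect_equal(got$circular, want$circular)
  }
})

test_that("a fully sealed lattice closes one ring per interior plaquette", {
  for (nm in c("J4-I_2x2", "J4-I_3x3", "J4-I")) {
    des <- builtin_design(nm)
    lat <- build_lattice(des)
    oc <- seal_nicks(lat, 1, seed = 1)
    prods <- enumerate_products(lat, oc)
    expect_equal(sum(prods$circular), expected_ring_count(des), label = nm)
  }
})

test_that("product mass is conserved", {
  lat <- build_lattice(builtin_design("J4-I_3x3"))
  total <- sum(lat$strands$length_nt)
  for (p in c(0, 0.37, 1)) {
    prods <- enumerate_products(lat, seal_nicks(lat, p, seed = 2))
    expect_equal(sum(prods$length_nt * prods$count), total)
  }
})

test_that("exact product distribution is a proper distribution", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))
  d <- product_distribution(lat, 0.6, mode = "exact")
  # frequency of the designed ring: exactly p^4
  ring <- d$species[d$species$circular, ]
  expect_equal(nrow(ring), 1L)
  expect_equal(ring$frequency, 0.6^4, tolerance = 1e-12)
  # mass fractions sum to 1
  expect_equal(sum(d$species$mass_fraction), 1, tolerance = 1e-12)
})

test_that("exact mode refuses lattices beyond its capacity", {
  lat <- build_lattice(builtin_design("J4-I"))
  expect_error(product_distribution(lat, 0.5, mode = "exact"), "capacity")
})

test_that("Monte-Carlo distribution converges to exact on the 2x2 lattice", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))
  ex <- product_distribution(lat, 0.7, mode = "exact")
  mc <- product_distribution(lat, 0.7, mode = "monte_carlo",
                             n_reps = 4000, seed = 5)
  key <- function(s) paste0(s$members, "|", s$circular)
  i <- match(key(mc$species), key(ex$species))
  expect_false(anyNA(i))
  se <- sqrt(pmax(ex$species$frequency[i] * (1 - ex$species$frequency[i]), 1e-4) / 4000)
  expect_true(all(abs(mc$species$frequency - ex$species$frequency[i]) < 4 * se))
})

test_that("estimate_efficiency inverts the circular fraction", {
  est <- estimate_efficiency(0.8^4, 4)
  expect_equal(est$p_hat, 0.8, tolerance = 1e-12)
  expect_error(estimate_efficiency(-0.1, 4), "domain")
  expect_error(estimate_efficiency(0.5, 0), "domain")
})

test_that("designed cycles of the 2x2 lattice form one 4-nick ring", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))
  dc <- designed_cycles(lat)
  expect_equal(length(dc), 1L)
  expect_equal(length(dc[[1]]$nicks), 4L)
  expect_equal(length(dc[[1]]$members), 4L)
})

test_that("predict_gel_pattern aggregates by length and floors faint bands", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))
  d <- product_distribution(lat, 0.9, mode = "exact")
  g <- predict_gel_pattern(d, floor = 0.005)
  expect_true(all(g$intensity >= 0.005))
  expect_false(any(duplicated(paste(g$length_nt, g$circular))))
  expect_true(sum(g$intensity) <= 1 + 1e-12)
})
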