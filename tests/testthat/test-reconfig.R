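fixture_path <- function(nm) {
  system.file("extdata", "designs", paste0(nm, ".json"),
              package = "nicklattice", mustWork = TRUE)
}

test_that("mask fixtures leave the designed ligatable counts", {
  want <- c(fig4a_mask = 96L, fig4b_mask = 96L, fig4c_mask = 108L)
  for (nm in names(want)) {
    sp <- read_reconfig_spec(fixture_path(nm))
    lat <- apply_phosphorylation_mask(build_lattice(sp$design), sp$mask)
    expect_equal(count_nicks(lat, ligatable_only = TRUE), unname(want[nm]),
                 label = nm)
  }
})

test_that("at p=1 each mask fixture carves exactly its target shape", {
  for (nm in c("fig4a_mask", "fig4b_mask", "fig4c_mask")) {
    sp <- read_reconfig_spec(fixture_path(nm))
    res <- reconfigure(sp, p = 1, seed = 1)
    expect_true(res$match, label = nm)
    # every surviving component is a full-width band of the carving
    sizes <- vapply(res$components, nrow, 0L)
    expect_equal(sum(sizes), 36L, label = nm)
  }
  # two seams -> three pieces; one seam -> two pieces
  a <- reconfigure(read_reconfig_spec(fixture_path("fig4a_mask")), p = 1, seed = 1)
  expect_length(a$components, 3L)
  c_ <- reconfigure(read_reconfig_spec(fixture_path("fig4c_mask")), p = 1, seed = 1)
  expect_length(c_$components, 2L)
})

test_that("match fraction over replicates is reproducible and sensible", {
  sp <- read_reconfig_spec(fixture_path("fig4c_mask"))
  r1 <- reconfigure(sp, p = 0.95, seed = 3, n_reps = 10)
  r2 <- reconfigure(sp, p = 0.95, seed = 3, n_reps = 10)
  expect_equal(r1$match_fraction, r2$match_fraction)
  r0 <- reconfigure(sp, p = 0, seed = 3, n_reps = 5)
  expect_equal(r0$match_fraction, 0)
})

test_that("tube classifier reproduces the four control outcomes", {
  verdict <- function(variant, p) {
    lat <- build_lattice(tube_design(variant))
    classify_topology(lat, seal_nicks(lat, p, seed = 1))$classification
  }
  expect_equal(verdict("comp3", 1), "tubular")
  expect_equal(verdict("comp3", 0), "planar")
  expect_equal(verdict("noncomp", 1), "planar")
  expect_equal(verdict("unlig", 1), "planar")
  expect_equal(verdict("sticky10", 1), "tubular")
  expect_equal(verdict("sticky10", 0), "tubular")
})

test_that("topology classification demands an overhang boundary", {
  lat <- build_lattice(builtin_design("J4-I"))
  expect_error(classify_topology(lat, seal_nicks(lat, 1, seed = 1)),
               "configuration error")
})

test_that("partial boundary closure respects row_fraction", {
  lat <- build_lattice(tube_design("comp3"))
  # seal everything except row 0's boundary nicks
  keep <- lat$nicks$nick[is.na(lat$nicks$edge) | lat$nicks$edge != "b_r0_EW"]
  oc <- ligation_outcome(lat, keep)
  expect_equal(classify_topology(lat, oc)$classification, "planar")
  expect_equal(classify_topology(lat, oc, row_fraction = 5 / 6)$classification,
               "tubular")
})

test_that("ring census counts designed rings and links them when sharing duplexes", {
  l2 <- build_lattice(builtin_design("J4-I_2x2"))
  rc2 <- ring_census(l2, seal_nicks(l2, 1, seed = 1))
  expect_equal(nrow(rc2$rings), 1L)
  expect_equal(nrow(rc2$catenation_edges), 0L)
  l6 <- build_lattice(builtin_design("J4-I"))
  rc6 <- ring_census(l6, seal_nicks(l6, 1, seed = 1))
  expect_equal(nrow(rc6$rings), 25L)  # 5x5 interior plaquettes
  expect_gt(nrow(rc6$catenation_edges), 0L)
  expect_true(rc6$spanning)
  rc0 <- ring_census(l6, seal_nicks(l6, 0, seed = 1))
  expect_equal(nrow(rc0$rings), 0L)
  expect_false(rc0$spanning)
})

test_that("percolation probability is 0 at p=0, 1 at p=1, monotone and seeded", {
  lat <- build_lattice(builtin_design("J4-I"))
  expect_equal(percolation_probability(lat, 0, n_reps = 5, seed = 2)$probability, 0)
  expect_equal(percolation_probability(lat, 1, n_reps = 5, seed = 2)$probability, 1)
  grid <- c(0.2, 0.5, 0.8, 0.95)
  probs <- vapply(grid, function(p)
    percolation_probability(lat, p, n_reps = 40, seed = 2)$probability, 0)
  expect_false(is.unsorted(probs))
  again <- vapply(grid, function(p)
    percolation_probability(lat, p, n_reps = 40, seed = 2)$probability, 0)
  expect_equal(probs, again)
})

test_that("exonuclease survival keeps exactly the circular species", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))
  oc <- seal_nicks(lat, 0.8, seed = 6)
  surv <- exonuclease_survival(lat, oc)
  prods <- enumerate_products(lat, oc)
  expect_equal(nrow(surv), sum(prods$circular))
  expect_true(all(surv$circular))
})
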