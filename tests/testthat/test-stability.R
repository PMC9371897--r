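test_that("strand lock status follows the X/Y nick classification", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))
  nk <- lat$nicks[1, ]
  oc <- ligation_outcome(lat, nk$nick)
  # sealing a terminal nick fully locks both flanking strands
  expect_equal(strand_lock_status(lat, oc, nk$upstream), "full")
  expect_equal(strand_lock_status(lat, oc, nk$downstream), "full")
  # the template strand is at most partially locked by this nick
  expect_true(strand_lock_status(lat, oc, nk$template) %in% c("partial", "none"))
  oc0 <- ligation_outcome(lat, character(0))
  expect_true(all(strand_status_all(lat, oc0$sealed, lockin_rule()) != "full"))
})

test_that("trivial regimes: p=1 keeps everything, p=0 keeps nothing", {
  lat <- build_lattice(builtin_design("J4-I"))
  s1 <- surviving_structure(lat, seal_nicks(lat, 1, seed = 1))
  expect_length(s1$removed_strands, 0L)
  expect_setequal(s1$present_duplexes, lat$duplexes$duplex)
  s0 <- surviving_structure(lat, seal_nicks(lat, 0, seed = 1))
  expect_length(s0$retained_strands, 0L)
  expect_equal(intact_proportion(lat, 1, n_reps = 5, seed = 1)$intact_fraction, 1)
  expect_equal(intact_proportion(lat, 0, n_reps = 5, seed = 1)$intact_fraction, 0)
})

test_that("low regime is the identity; high regime keeps only covalent species", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))
  oc <- seal_nicks(lat, 0.5, seed = 4)
  lo <- surviving_structure(lat, oc, regime = thermal_regime("low"))
  expect_setequal(lo$retained_strands, lat$strands$strand)
  hi <- surviving_structure(lat, oc, regime = thermal_regime("high"))
  expect_length(hi$retained_strands, 0L)
  expect_true(all(hi$dissolved_species$circular |
                    hi$dissolved_species$n_strands >= 2))
})

test_that("intact fraction is monotone nondecreasing in p under a shared seed", {
  lat <- build_lattice(builtin_design("J4-I"))
  sc <- efficiency_scan(lat, seq(0, 1, by = 0.1), n_reps = 200, seed = 11)
  expect_false(is.unsorted(sc$intact_fraction))
  sc2 <- efficiency_scan(lat, seq(0, 1, by = 0.1), n_reps = 200, seed = 11,
                         criterion = "single_connected_component")
  expect_false(is.unsorted(sc2$intact_fraction))
})

test_that("Monte-Carlo intact fraction matches exhaustive enumeration", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))  # 8 nicks, 2^8 states
  for (p in c(0.3, 0.7, 0.9)) {
    ex <- intact_proportion_exact(lat, p)
    mc <- intact_proportion(lat, p, n_reps = 4000, seed = 9)
    se <- max(mc$se, sqrt(ex * (1 - ex) / 4000))
    expect_lt(abs(ex - mc$intact_fraction), 4 * se)
  }
})

test_that("fast vectorized path equals the scalar surviving_structure path", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))
  pre <- intact_precompute(lat, lockin_rule())
  set.seed(13)
  for (i in 1:30) {
    ids <- lat$nicks$nick[runif(nrow(lat$nicks)) < 0.5]
    oc <- ligation_outcome(lat, ids)
    sealed <- lat$nicks$nick %in% ids
    names(sealed) <- lat$nicks$nick
    sv <- surviving_structure(lat, oc)
    fast <- nicklattice:::intact_one(lat, sealed, pre,
                                     thermal_regime("intermediate"),
                                     lockin_rule(), "all_strands_retained")
    expect_identical(fast, length(sv$removed_strands) == 0L)
  }
})

test_that("at p=0.7 a 6x6 lattice almost surely survives as one component", {
  # the all-strands criterion is conservative by design; the connected
  # component criterion reflects gross lattice survival
  lat <- build_lattice(builtin_design("J4-I"))
  r <- intact_proportion(lat, 0.7, n_reps = 400, seed = 21,
                         criterion = "single_connected_component")
  expect_gt(r$intact_fraction, 0.5)
})

test_that("partial lock-in policies bracket the default", {
  lat <- build_lattice(builtin_design("J4-I"))
  oc <- seal_nicks(lat, 0.6, seed = 8)
  keep <- function(pol) length(surviving_structure(
    lat, oc, rule = lockin_rule(pol))$retained_strands)
  expect_lte(keep("retain_never"), keep("retain_if_all_duplexes_templated"))
  expect_lte(keep("retain_if_all_duplexes_templated"), keep("retain_always"))
})

test_that("unligated intermotif stems dissolve but boundary controls persist", {
  # masked (never-sealed) edge: its duplex must be absent at p=1
  des <- builtin_design("J4-I")
  lat <- build_lattice(des)
  cut <- lat$edges$edge[lat$edges$class == "intermotif"][1]
  ml <- apply_phosphorylation_mask(lat, list(cut_edges = cut))
  sv <- surviving_structure(ml, seal_nicks(ml, 1, seed = 2))
  dcut <- lat$duplexes$duplex[!is.na(lat$duplexes$edge) & lat$duplexes$edge == cut]
  expect_false(dcut %in% sv$present_duplexes)
  # 10-bp sticky boundary duplexes persist without their nicks being sealed
  # (interior fully ligated, boundary nicks left unsealed)
  tube <- build_lattice(tube_design("sticky10"))
  interior <- tube$nicks$nick[is.na(tube$nicks$edge) |
                                !grepl("^b_", tube$nicks$edge)]
  oc <- ligation_outcome(tube, interior)
  svt <- surviving_structure(tube, oc)
  bd <- tube$duplexes$duplex[tube$duplexes$class == "boundary"]
  expect_true(all(bd %in% svt$present_duplexes))
  # whereas the 3-nt overhang variant's boundary duplexes dissolve unligated
  t3 <- build_lattice(tube_design("comp3"))
  oc3 <- ligation_outcome(t3, interior)
  sv3 <- surviving_structure(t3, oc3)
  bd3 <- t3$duplexes$duplex[t3$duplexes$class == "boundary"]
  expect_false(any(bd3 %in% sv3$present_duplexes))
})
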