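test_that("J4-I 6x6 build matches the reference structural accounting", {
  lat <- build_lattice(builtin_design("J4-I"))
  expect_equal(nrow(lat$motifs), 36L)
  expect_equal(sum(lat$edges$class == "intermotif"), 60L)
  expect_equal(count_nicks(lat), 120L)
  expect_equal(count_nicks(lat, ligatable_only = TRUE), 120L)
  expect_equal(unique(lat$nicks$fused_length), 21L)
})

test_that("all builtin designs build to their reference nick counts", {
  counts <- c("J4-I" = 120L, "J4-II" = 120L, "J4-III" = 120L,
              "J3" = 108L, "DX-I" = 146L, "DX-II" = 110L,
              "J4-I_2x2" = 8L, "J4-I_3x3" = 24L)
  for (nm in names(counts)) {
    lat <- build_lattice(builtin_design(nm))
    expect_equal(count_nicks(lat, ligatable_only = TRUE), unname(counts[nm]),
                 label = nm)
  }
})

test_that("ligated segment lengths equal the fused root+stem domains", {
  l1 <- build_lattice(builtin_design("J4-I"))
  expect_equal(ligated_segment_length(l1, l1$nicks$nick[1]), 21L)  # 11+10
  l2 <- build_lattice(builtin_design("J4-II"))
  expect_equal(ligated_segment_length(l2, l2$nicks$nick[1]), 19L)  # 13+6
  expect_error(ligated_segment_length(l1, "no_such_nick"), "unknown")
})

test_that("J3 brick wall has 36 horizontal + 18 vertical edges and 18 free arms", {
  des <- builtin_design("J3")
  lat <- build_lattice(des)
  horiz <- grepl("_E$", lat$edges$edge)
  expect_equal(sum(horiz), 36L)
  expect_equal(sum(!horiz), 18L)
  # every motif has 3 arms; arms not consumed by an edge are free
  n_arm_slots <- 3L * nrow(lat$motifs)
  expect_equal(n_arm_slots - 2L * nrow(lat$edges), 18L)
})

test_that("phosphorylation mask forms all work and errors on unknown ids", {
  lat <- build_lattice(builtin_design("J4-I"))
  m1 <- apply_phosphorylation_mask(lat, "all")
  expect_equal(count_nicks(m1, ligatable_only = TRUE), 120L)
  some <- lat$nicks$nick[1:5]
  m2 <- apply_phosphorylation_mask(lat, some)
  expect_equal(count_nicks(m2, ligatable_only = TRUE), 5L)
  m3 <- apply_phosphorylation_mask(lat, list(nicks = some))
  expect_equal(count_nicks(m3, ligatable_only = TRUE), 5L)
  # strand form: only nicks whose 5'-phosphate strand is listed stay ligatable
  st <- lat$strands$strand[1]
  m4 <- apply_phosphorylation_mask(lat, list(strands = st))
  expect_true(count_nicks(m4, ligatable_only = TRUE) < 120L)
  # cut_edges form: both nicks of each cut edge become unligatable
  m5 <- apply_phosphorylation_mask(lat, list(cut_edges = lat$edges$edge[1:3]))
  expect_equal(count_nicks(m5, ligatable_only = TRUE), 120L - 6L)
  expect_error(apply_phosphorylation_mask(lat, "bogus_nick"), "unknown")
  expect_error(apply_phosphorylation_mask(lat, list(cut_edges = "bogus_edge")),
               "unknown")
})

test_that("masking is idempotent", {
  lat <- build_lattice(builtin_design("J4-I"))
  some <- lat$nicks$nick[1:10]
  once <- apply_phosphorylation_mask(lat, some)
  twice <- apply_phosphorylation_mask(once, some)
  expect_identical(once$nicks$ligatable, twice$nicks$ligatable)
})

test_that("nick labels classify strand roles correctly", {
  lat <- build_lattice(builtin_design("J4-I_2x2"))
  nk <- lat$nicks[1, ]
  expect_true(nick_label(lat, nk$nick, nk$upstream) %in% c("X_I", "X_II"))
  expect_true(nick_label(lat, nk$nick, nk$downstream) %in% c("X_I", "X_II"))
  expect_equal(nick_label(lat, nk$nick, nk$template), "Y")
  # a strand not involved in the nick gets NA
  other <- setdiff(lat$strands$strand,
                   c(nk$upstream, nk$downstream, nk$template))[1]
  expect_true(is.na(nick_label(lat, nk$nick, other)))
})

test_that("design JSON and graph TSV round trips are faithful", {
  des <- builtin_design("J4-I_2x2")
  tmp <- tempfile(fileext = ".json")
  write_lattice_design(des, tmp)
  des2 <- read_lattice_design(tmp)
  expect_equal(count_nicks(build_lattice(des2)), count_nicks(build_lattice(des)))
  lat <- build_lattice(des)
  tsv <- tempfile(fileext = ".tsv")
  export_graph(lat, tsv)
  lat2 <- import_lattice_graph(tsv)
  expect_equal(lat2$strands, lat$strands)
  expect_equal(lat2$nicks, lat$nicks)
  expect_equal(lat2$duplexes, lat$duplexes)
})

test_that("invalid designs are rejected", {
  expect_error(builtin_design("nope"), "unknown")
  expect_error(lattice_design("J4", rows = 0L, cols = 6L,
                              connectivity = "square_grid"))
  expect_error(lattice_design("J4", rows = 6L, cols = 6L,
                              connectivity = "brick_wall"))
  expect_error(lattice_design("J4", rows = 2L, cols = 2L,
                              connectivity = "square_grid",
                              domains = list(root = 11L)))
})
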