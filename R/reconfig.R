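#' Ligation-induced reconfiguration of a masked lattice
#'
#' Applies a phosphorylation mask to the base design, seals nicks at
#' efficiency `p`, applies the intermediate-regime survival model (unligated
#' segments dissociate above ~50 degC), and compares the surviving hybridized
#' components against a target shape. This is the loss-of-ligation-function
#' mode: edges left unligatable dissociate on heating and carve sub-lattices
#' out of the complete lattice.
#'
#' @param spec either a list as returned by [read_reconfig_spec()] (fields
#'   `design`, `mask`, `target_shape`) or a `lattice_design`.
#' @param p ligation efficiency.
#' @param seed RNG seed.
#' @param n_reps replicates; with `n_reps = 1` the full component detail of
#'   the single outcome is returned, otherwise the match fraction over
#'   replicates.
#' @param mask,target_shape used when `spec` is a bare design.
#' @param rule a [lockin_rule()].
#' @param regime thermal regime applied after ligation (default
#'   intermediate).
#' @return object of class `reconfig_result`: list with `components` (list of
#'   motif-coordinate matrices of each surviving hybridized component, largest
#'   first), `match` (is the target shape exactly one of the components),
#'   `match_fraction` (over replicates), `n_reps`, `p`.
#' @export
reconfigure <- function(spec, p, seed = NULL, n_reps = 1L,
                        mask = NULL, target_shape = NULL,
                        rule = lockin_rule(),
                        regime = thermal_regime("intermediate")) {
  if (inherits(spec, "lattice_design")) {
    spec <- list(design = spec, mask = mask %||% spec$mask,
                 target_shape = target_shape)
  }
  lat <- build_lattice(spec$design)
  lat <- apply_phosphorylation_mask(lat, spec$mask)
  target <- spec$target_shape
  one <- function(s) {
    oc <- seal_nicks(lat, p, s)
    surv <- surviving_structure(lat, oc, regime, rule)
    comps <- surviving_components(lat, surv)
    match <- !is.null(target) && any(vapply(comps, function(cm)
      shapes_equal(cm, target), TRUE))
    list(components = comps, match = match)
  }
  seeds <- if (is.null(seed)) rep(list(NULL), n_reps) else
    as.list(seed + seq_len(n_reps) - 1L)
  res <- lapply(seeds, one)
  matches <- vapply(res, `[[`, TRUE, "match")
  structure(list(components = res[[1L]]$components,
                 match = matches[1L],
                 match_fraction = mean(matches),
                 n_reps = n_reps, p = p),
            class = "reconfig_result")
}

# motif-coordinate matrices of the hybridized components of a survivor
surviving_components <- function(lattice, surv) {
  if (length(surv$retained_strands) == 0L) return(list())
  dp <- lattice$duplexes[lattice$duplexes$duplex %in% surv$present_duplexes, ]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(surv$retained_strands)
  if (nrow(dp) > 0L) {
    g <- igraph::add_edges(g, t(as.matrix(dp[, c("strand_a", "strand_b")])))
  }
  comp <- igraph::components(g)$membership
  st <- lattice$strands
  mo <- lattice$motifs
  out <- lapply(split(names(comp), comp), function(ids) {
    ms <- unique(st$motif[match(ids, st$strand)])
    i <- match(ms, mo$motif)
    m <- cbind(row = mo$row[i], col = mo$col[i])
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  })
  out[order(-vapply(out, nrow, 0L))]
}

shapes_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(FALSE)
  ka <- unique(paste(a[, 1], a[, 2]))
  kb <- unique(paste(b[, 1], b[, 2]))
  setequal(ka, kb)
}

#' @export
print.reconfig_result <- function(x, ...) {
  cat("<reconfig_result> p=", x$p, ": ", length(x$components),
      " surviving component(s); match=", x$match,
      if (x$n_reps > 1) sprintf(" (fraction %.3f over %d reps)",
                                x$match_fraction, x$n_reps),
      "\n", sep = "")
  invisible(x)
}

#' Sheet-to-tube topology classification
#'
#' For a lattice with complementary boundary overhangs on its east and west
#' sides, classifies the post-ligation configuration. A boundary duplex is
#' *permanent* (ON) when it is complementary and either one of its nicks is
#' sealed (ligation locks the transient sticky end into a long fused segment)
#' or its length is at or above `permanent_len` base pairs (the 10-bp
#' sticky-end positive control pairs stably without ligation). Short
#' unligated overhangs (e.g. 3 nt) are transient (OFF) and the sheet stays
#' planar. The lattice is *tubular* when permanent boundary duplexes close
#' the east-west wrap in every row (strict closure; lower `row_fraction` for
#' partial-closure studies).
#'
#' @param lattice a `lattice_graph` built from an overhang-boundary design.
#' @param outcome a [seal_nicks()] outcome.
#' @param permanent_len permanent-length threshold in bp (default 10).
#' @param row_fraction fraction of rows whose boundary duplex must be
#'   permanent (default 1 = all rows).
#' @return object of class `topology_report`: list with `classification`
#'   (`"planar"` or `"tubular"`), `wrapping_cycle_found`, and a
#'   `boundary_states` data frame (row, present, sealed, permanent).
#' @export
classify_topology <- function(lattice, outcome, permanent_len = 10L,
                              row_fraction = 1) {
  des <- lattice$design
  if (is.null(des) || des$boundary$policy != "overhang") {
    stop("configuration error: topology classification requires an ",
         "overhang-boundary design", call. = FALSE)
  }
  rows <- des$rows
  nk <- lattice$nicks
  bnd <- lattice$edges[lattice$edges$class == "boundary", , drop = FALSE]
  states <- data.frame(row = 0:(rows - 1), present = FALSE, sealed = FALSE,
                       permanent = FALSE)
  if (isTRUE(des$boundary$complementary) && nrow(bnd) > 0L) {
    for (i in seq_len(nrow(bnd))) {
      r <- as.integer(sub("^b_r(\\d+)_EW$", "\\1", bnd$edge[i]))
      sealed <- any(outcome$sealed[nk$nick[which(nk$edge == bnd$edge[i])]])
      len <- lattice$duplexes$length_bp[
        which(lattice$duplexes$edge == bnd$edge[i])]
      states$present[states$row == r] <- TRUE
      states$sealed[states$row == r] <- sealed
      states$permanent[states$row == r] <- sealed || len >= permanent_len
    }
  }
  closed <- mean(states$permanent) >= row_fraction
  structure(list(classification = if (closed) "tubular" else "planar",
                 wrapping_cycle_found = closed,
                 boundary_states = states),
            class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat("<topology_report>", x$classification, "-",
      sum(x$boundary_states$permanent), "of", nrow(x$boundary_states),
      "rows permanently closed\n")
  invisible(x)
}

#' Census of covalent rings and their catenation graph
#'
#' Collects the circular species of a sealing outcome and links two rings in
#' the catenation graph when they share at least one duplex (a hybridized
#' segment) in the assembled lattice — the declared surrogate for topological
#' interlocking in a woven wireframe lattice, conservative and isolated in
#' one predicate so a geometric test could replace it. The census *spans*
#' when one catenation component contains rings touching all four sides of
#' the motif grid (site-percolation convention).
#'
#' @param lattice a `lattice_graph`.
#' @param outcome a [seal_nicks()] outcome.
#' @return object of class `ring_census`: list with `rings` (circular species
#'   data frame from [enumerate_products()]), `catenation_edges` (two-column
#'   matrix of ring indices), `components` (membership vector), `spanning`
#'   (logical).
#' @export
ring_census <- function(lattice, outcome) {
  prods <- enumerate_products(lattice, outcome)
  rings <- prods[prods$circular, , drop = FALSE]
  rownames(rings) <- NULL
  nr <- nrow(rings)
  members <- lapply(strsplit(rings$members, "+", fixed = TRUE), unique)
  ring_of <- integer(0)
  if (nr > 0) {
    ring_of <- rep(seq_len(nr), lengths(members))
    names(ring_of) <- unlist(members)
  }
  dp <- lattice$duplexes
  ia <- ring_of[dp$strand_a]; ib <- ring_of[dp$strand_b]
  keep <- !is.na(ia) & !is.na(ib) & ia != ib
  edges <- unique(cbind(pmin(ia[keep], ib[keep]), pmax(ia[keep], ib[keep])))
  comp <- if (nr == 0) integer(0) else {
    g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(seq_len(nr))
    if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
    igraph::components(g)$membership
  }
  spanning <- FALSE
  if (nr > 0) {
    mo <- lattice$motifs
    st <- lattice$strands
    rows <- max(mo$row); cols <- max(mo$col)
    touches <- function(ring_ids) {
      ms <- unique(st$motif[st$strand %in% unlist(members[ring_ids])])
      i <- match(ms, mo$motif)
      any(mo$row[i] == 0) && any(mo$row[i] == rows) &&
        any(mo$col[i] == 0) && any(mo$col[i] == cols)
    }
    spanning <- any(vapply(split(seq_len(nr), comp), touches, TRUE))
  }
  structure(list(rings = rings, catenation_edges = edges,
                 components = comp, spanning = spanning),
            class = "ring_census")
}

#' @export
print.ring_census <- function(x, ...) {
  cat("<ring_census>", nrow(x$rings), "rings,",
      nrow(x$catenation_edges), "catenation links; spanning =", x$spanning, "\n")
  invisible(x)
}

#' Chain-mail percolation probability
#'
#' Monte-Carlo probability that the catenation graph of covalent rings spans
#' the lattice (touches all four sides in one interlocked component) — the
#' chain-mail supermolecule regime. Monotone in `p` under a fixed seed.
#'
#' @param lattice a `lattice_graph`.
#' @param p ligation efficiency.
#' @param n_reps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return list with `probability`, `se`, `n_reps`, `p`.
#' @export
percolation_probability <- function(lattice, p, n_reps = 200L, seed = NULL) {
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  N <- nrow(lattice$nicks)
  u <- matrix(local_runif(n_reps * N, seed), nrow = n_reps)
  hits <- vapply(seq_len(n_reps), function(r) {
    sealed <- lattice$nicks$ligatable & (u[r, ] < p)
    names(sealed) <- lattice$nicks$nick
    oc <- structure(list(sealed = sealed, p = p, seed = seed),
                    class = "ligation_outcome")
    ring_census(lattice, oc)$spanning
  }, TRUE)
  f <- mean(hits)
  list(probability = f, se = sqrt(f * (1 - f) / n_reps),
       n_reps = n_reps, p = p)
}

#' Species surviving exonuclease digestion
#'
#' Toy digestion rule: exonucleases require free strand ends, so only
#' covalently closed (circular) species — and hence any all-circular
#' interlocked component — survive; every species with free ends is removed.
#' Whether a nicked-but-hybridized duplex would in fact be spared by a
#' specific exonuclease is biochemical detail outside this rule, which keys
#' on covalent circularity only.
#'
#' @param lattice a `lattice_graph`.
#' @param outcome a [seal_nicks()] outcome.
#' @return data frame of surviving species (circular subset of
#'   [enumerate_products()]).
#' @export
exonuclease_survival <- function(lattice, outcome) {
  prods <- enumerate_products(lattice, outcome)
  out <- prods[prods$circular, , drop = FALSE]
  rownames(out) <- NULL
  out
}
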