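#' Lock-in classification rule
#'
#' After ligation, a component strand is *fully* locked in when either of its
#' own terminal nicks (labelled X_I at its 5' end, X_II at its 3' end) is
#' sealed: the strand is then covalently buried in a longer ligated segment
#' whose combined duplex cannot dissociate at the intermediate temperature
#' regime (the kinetically interlocking multi-unit effect). Sealing only the
#' nick on the complementary strand across one of its duplexes (label Y) has
#' a *partial* effect: the strand's pairing segments then sit on a continuous
#' ligated template.
#'
#' `partial_policy` controls how the partial effect is scored:
#' \describe{
#'   \item{retain_if_all_duplexes_templated}{default; a strand with no sealed
#'     terminal nick is retained only if every nick it templates is sealed
#'     (vacuously true for strands that template none, e.g. corner strands
#'     with unpaired stems), and it keeps at least one intact duplex through
#'     the removal cascade. Nicks sitting on boundary sticky-end duplexes at
#'     or above the permanence length are exempt from the requirement — such
#'     duplexes pair stably without ligation.}
#'   \item{retain_never}{partial lock-in confers no retention.}
#'   \item{retain_always}{any strand survives unless stranded by the cascade.}
#' }
#'
#' @param partial_policy one of the policies above.
#' @return an object of class `lockin_rule`.
#' @export
lockin_rule <- function(partial_policy = c("retain_if_all_duplexes_templated",
                                           "retain_never", "retain_always")) {
  structure(list(partial_policy = match.arg(partial_policy)),
            class = "lockin_rule")
}

#' Thermal regime label
#'
#' Temperature enters the stability model only as a regime: `"low"` (below
#' the melting of the short root/stem domains; nothing dissociates),
#' `"intermediate"` (above the short-domain melting but below that of the
#' combined ligated segment; unligated components dissociate) and `"high"`
#' (above all duplex melting; only covalent products persist, dissolved).
#'
#' @param regime `"low"`, `"intermediate"` or `"high"`.
#' @return character scalar (validated).
#' @export
thermal_regime <- function(regime = c("intermediate", "low", "high")) {
  match.arg(regime)
}

#' Lock-in status of one strand under a ligation outcome
#'
#' @param lattice a `lattice_graph`.
#' @param outcome a [seal_nicks()] outcome.
#' @param strand strand id.
#' @param rule a [lockin_rule()].
#' @param permanent_len templated nicks sitting on boundary sticky-end
#'   duplexes of at least this length (bp) are never *required* to be sealed:
#'   such a duplex pairs stably without ligation, so its unsealed nick does
#'   not destabilize the strand (default 10).
#' @return `"full"`, `"partial"` or `"none"`.
#' @export
strand_lock_status <- function(lattice, outcome, strand,
                               rule = lockin_rule(), permanent_len = 10L) {
  if (!strand %in% lattice$strands$strand) {
    stop("lookup error: unknown strand id '", strand, "'", call. = FALSE)
  }
  nk <- lattice$nicks
  sealed <- outcome$sealed
  term <- nk$nick[nk$upstream == strand | nk$downstream == strand]
  if (length(term) && any(sealed[term])) return("full")
  switch(rule$partial_policy,
    retain_never = "none",
    retain_always = "partial",
    retain_if_all_duplexes_templated = {
      req <- nick_required(lattice, permanent_len)
      y <- nk$nick[nk$template == strand & req]
      if (length(y) == 0L || all(sealed[y])) "partial" else "none"
    })
}

# internal: which nicks must be sealed to stabilize the strand they template.
# Nicks on boundary duplexes at/above the permanence length are exempt: the
# sticky end pairs stably without ligation.
nick_required <- function(lattice, permanent_len = 10L) {
  nk <- lattice$nicks
  dp <- lattice$duplexes
  perm_edges <- dp$edge[dp$class == "boundary" & dp$length_bp >= permanent_len]
  perm_edges <- perm_edges[!is.na(perm_edges)]
  is.na(nk$edge) | !(nk$edge %in% perm_edges)
}

# internal: per-strand status vector (vectorized over strands)
strand_status_all <- function(lattice, sealed, rule, permanent_len = 10L) {
  st <- lattice$strands$strand
  nk <- lattice$nicks
  full <- st %in% c(nk$upstream[sealed[nk$nick]], nk$downstream[sealed[nk$nick]])
  part <- switch(rule$partial_policy,
    retain_never = rep(FALSE, length(st)),
    retain_always = rep(TRUE, length(st)),
    retain_if_all_duplexes_templated = {
      req <- nick_required(lattice, permanent_len)
      unsealed_templates <- nk$template[req & !sealed[nk$nick]]
      !(st %in% unsealed_templates)
    })
  status <- ifelse(full, "full", ifelse(part, "partial", "none"))
  names(status) <- st
  status
}

# internal: which duplexes are present given retained strands and sealed nicks.
# Intramotif duplexes persist while both strands are present (the assembled
# structure holds through the ligated network); an intermotif duplex needs at
# least one of its flanking nicks sealed (above 50 degC even a 10-11 bp stem
# duplex melts when unligated); a boundary sticky-end duplex is additionally
# permanent at or above `permanent_len` bp (the unligated positive control).
duplex_locked <- function(lattice, sealed, permanent_len = 10L) {
  dp <- lattice$duplexes
  nk <- lattice$nicks
  inter <- dp$class %in% c("intermotif", "boundary")
  sealed_by_edge <- tapply(sealed[nk$nick], nk$edge, any)
  locked <- rep(TRUE, nrow(dp))
  has_edge <- !is.na(dp$edge)
  lk <- unname(sealed_by_edge[dp$edge[inter & has_edge]]) |
    (dp$class[inter & has_edge] == "boundary" &
       dp$length_bp[inter & has_edge] >= permanent_len)
  lk[is.na(lk)] <- FALSE
  locked[inter & has_edge] <- lk
  locked[inter & !has_edge] <- FALSE
  locked
}

duplex_present <- function(lattice, present_strands, sealed,
                           permanent_len = 10L) {
  dp <- lattice$duplexes
  dp$strand_a %in% present_strands & dp$strand_b %in% present_strands &
    duplex_locked(lattice, sealed, permanent_len)
}

#' Structure surviving a thermal regime
#'
#' In the `low` regime the lattice is unchanged. In the `intermediate` regime,
#' strands with lock-in status `none` are removed; unligated intermotif (and
#' short boundary) duplexes dissolve; and removal is cascaded to a fixed point
#' because deleting a strand deletes duplexes that may have been another
#' partially locked strand's only anchor. In the `high` regime no assembled
#' lattice remains: only covalently joined multi-strand (or circular) products
#' persist as dissolved species.
#'
#' @param lattice a `lattice_graph`.
#' @param outcome a [seal_nicks()] outcome.
#' @param regime a [thermal_regime()] label.
#' @param rule a [lockin_rule()].
#' @param permanent_len boundary sticky-end duplexes of at least this length
#'   (bp) survive without ligation (default 10: the 10-bp sticky-end positive
#'   control is permanent, 3-nt overhangs are transient). Regular intermotif
#'   stem duplexes always need a sealed flanking nick — above 50 degC even a
#'   10-11 bp stem melts when unligated.
#' @return an object of class `surviving_structure`: list with
#'   `retained_strands`, `present_duplexes`, `regime`, `removed_strands`,
#'   `dissolved_species` (high regime), and the `lattice`.
#' @export
surviving_structure <- function(lattice, outcome,
                                regime = thermal_regime("intermediate"),
                                rule = lockin_rule(),
                                permanent_len = 10L) {
  regime <- thermal_regime(regime)
  st <- lattice$strands$strand
  if (regime == "low") {
    return(structure(list(lattice = lattice, regime = regime,
                          retained_strands = st,
                          removed_strands = character(0),
                          present_duplexes =
                            lattice$duplexes$duplex,
                          dissolved_species = NULL),
                     class = "surviving_structure"))
  }
  if (regime == "high") {
    prods <- enumerate_products(lattice, outcome)
    keep <- prods$circular | prods$n_strands >= 2L
    return(structure(list(lattice = lattice, regime = regime,
                          retained_strands = character(0),
                          removed_strands = st,
                          present_duplexes = character(0),
                          dissolved_species = prods[keep, , drop = FALSE]),
                     class = "surviving_structure"))
  }
  sealed <- outcome$sealed
  status <- strand_status_all(lattice, sealed, rule, permanent_len)
  # partial lock-in only holds a strand that is hybridized (directly or
  # through other partially held strands) to the covalently locked network:
  # grow the retained set outward from the fully locked strands
  present <- st[status == "full"]
  partials <- st[status == "partial"]
  repeat {
    dp <- lattice$duplexes[duplex_locked(lattice, sealed, permanent_len), ]
    reach <- unique(c(dp$strand_b[dp$strand_a %in% present],
                      dp$strand_a[dp$strand_b %in% present]))
    add <- setdiff(intersect(reach, partials), present)
    if (length(add) == 0L) break
    present <- c(present, add)
  }
  present <- st[st %in% present]
  dpres <- duplex_present(lattice, present, sealed, permanent_len)
  structure(list(lattice = lattice, regime = regime,
                 retained_strands = present,
                 removed_strands = setdiff(st, present),
                 present_duplexes = lattice$duplexes$duplex[dpres],
                 dissolved_species = NULL),
            class = "surviving_structure")
}

#' @export
print.surviving_structure <- function(x, ...) {
  cat("<surviving_structure> regime=", x$regime, ": ",
      length(x$retained_strands), "/",
      length(x$retained_strands) + length(x$removed_strands),
      " strands retained\n", sep = "")
  invisible(x)
}

#' Intact-lattice proportion under Monte-Carlo nick sealing
#'
#' Repeats [seal_nicks()] plus the intermediate-regime survival model and
#' scores each replicate as intact per the chosen criterion:
#' `all_strands_retained` (default, deliberately conservative: some scored
#' dissociation events would in reality be transient, so this criterion
#' underestimates survival) or
#' `single_connected_component` (the retained strands are non-empty and form
#' one hybridized component; loss of individual strands is tolerated).
#'
#' The replicate indicator is exactly monotone nondecreasing in `p` under a
#' fixed seed (common random numbers), because the sealed set grows with `p`
#' and every retention rule is monotone in the sealed set.
#'
#' @param lattice a `lattice_graph`.
#' @param p ligation efficiency.
#' @param regime thermal regime (default `"intermediate"`).
#' @param rule a [lockin_rule()].
#' @param criterion `"all_strands_retained"` or `"single_connected_component"`.
#' @param n_reps number of Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return object of class `intact_result`: list with `intact_fraction`,
#'   `se` (binomial standard error), `flags`, `n_reps`, `criterion`, `p`.
#' @export
intact_proportion <- function(lattice, p,
                              regime = thermal_regime("intermediate"),
                              rule = lockin_rule(),
                              criterion = c("all_strands_retained",
                                            "single_connected_component"),
                              n_reps = 1000L, seed = NULL) {
  criterion <- match.arg(criterion)
  regime <- thermal_regime(regime)
  if (n_reps < 1L) stop("n_reps must be >= 1", call. = FALSE)
  if (p < 0 || p > 1) stop("domain error: p must be in [0, 1]", call. = FALSE)
  pre <- intact_precompute(lattice, rule)
  N <- nrow(lattice$nicks)
  u <- matrix(local_runif(n_reps * N, seed), nrow = n_reps)
  flags <- vapply(seq_len(n_reps), function(r) {
    sealed <- lattice$nicks$ligatable & (u[r, ] < p)
    names(sealed) <- lattice$nicks$nick
    intact_one(lattice, sealed, pre, regime, rule, criterion)
  }, TRUE)
  f <- mean(flags)
  structure(list(intact_fraction = f,
                 se = sqrt(f * (1 - f) / n_reps),
                 flags = flags, n_reps = n_reps,
                 criterion = criterion, p = p, seed = seed),
            class = "intact_result")
}

# precomputed index structures for the fast intact path
intact_precompute <- function(lattice, rule, permanent_len = 10L) {
  st <- lattice$strands$strand
  nk <- lattice$nicks
  sidx <- seq_along(st); names(sidx) <- st
  nidx <- seq_len(nrow(nk)); names(nidx) <- nk$nick
  term <- lapply(st, function(s)
    unname(nidx[nk$nick[nk$upstream == s | nk$downstream == s]]))
  req <- nick_required(lattice, permanent_len)
  ynk <- lapply(st, function(s) unname(nidx[nk$nick[nk$template == s & req]]))
  dp <- lattice$duplexes
  inter <- dp$class %in% c("intermotif", "boundary")
  edge_nicks <- lapply(dp$edge, function(e)
    if (is.na(e)) integer(0) else unname(nidx[nk$nick[nk$edge == e]]))
  list(st = st, sidx = sidx, term = term, ynk = ynk,
       dp_a = unname(sidx[dp$strand_a]), dp_b = unname(sidx[dp$strand_b]),
       dp_inter = inter, dp_bnd = dp$class == "boundary",
       dp_len = dp$length_bp, edge_nicks = edge_nicks)
}

# fast single-replicate intact indicator (same model as surviving_structure;
# the two are asserted equal in the test suite)
intact_one <- function(lattice, sealed, pre, regime, rule, criterion,
                       permanent_len = 10L) {
  ns <- length(pre$st)
  full <- vapply(pre$term, function(ix) length(ix) > 0 && any(sealed[ix]), TRUE)
  part <- switch(rule$partial_policy,
    retain_never = rep(FALSE, ns),
    retain_always = rep(TRUE, ns),
    retain_if_all_duplexes_templated =
      vapply(pre$ynk, function(ix) length(ix) == 0 || all(sealed[ix]), TRUE))
  dup_locked <- !pre$dp_inter |
    (pre$dp_inter &
       (vapply(pre$edge_nicks, function(ix) length(ix) > 0 && any(sealed[ix]),
               TRUE) | (pre$dp_bnd & pre$dp_len >= permanent_len)))
  # grow retention outward from the fully locked strands (same closure as
  # surviving_structure)
  present <- full
  repeat {
    reach <- rep(FALSE, ns)
    a_on <- dup_locked & present[pre$dp_a]
    b_on <- dup_locked & present[pre$dp_b]
    reach[pre$dp_b[a_on]] <- TRUE
    reach[pre$dp_a[b_on]] <- TRUE
    add <- part & reach & !present
    if (!any(add)) break
    present <- present | add
  }
  if (criterion == "all_strands_retained") return(all(present))
  if (!any(present)) return(FALSE)
  dup_on <- dup_locked & present[pre$dp_a] & present[pre$dp_b]
  n_components(pre$st[present],
               cbind(pre$st[pre$dp_a[dup_on]], pre$st[pre$dp_b[dup_on]])) == 1L
}

#' @export
print.intact_result <- function(x, ...) {
  cat(sprintf("<intact_result> p=%.3g: intact %.4f +/- %.4f (%d reps, %s)\n",
              x$p, x$intact_fraction, x$se, x$n_reps, x$criterion))
  invisible(x)
}

#' Exhaustive intact proportion over all sealed states
#'
#' Enumerates every subset of the ligatable nicks (2^N states, N <= 22),
#' evaluates the survival model through [surviving_structure()] and weights
#' each state by its Bernoulli probability. Exact counterpart of
#' [intact_proportion()] for small (sub-)lattices.
#'
#' @inheritParams intact_proportion
#' @return the exact intact proportion (numeric scalar).
#' @export
intact_proportion_exact <- function(lattice, p,
                                    regime = thermal_regime("intermediate"),
                                    rule = lockin_rule(),
                                    criterion = c("all_strands_retained",
                                                  "single_connected_component")) {
  criterion <- match.arg(criterion)
  nk <- lattice$nicks
  lig <- nk$nick[nk$ligatable]
  N <- length(lig)
  if (N > 22L) stop("capacity error: too many ligatable nicks for exhaustive ",
                    "enumeration", call. = FALSE)
  total <- 0
  for (s in 0:(2^N - 1)) {
    on <- as.logical(bitwAnd(s, bitwShiftL(1L, 0:(max(N, 1) - 1L)))[seq_len(N)])
    w <- p^sum(on) * (1 - p)^(N - sum(on))
    if (w == 0) next
    oc <- ligation_outcome(lattice, lig[on])
    surv <- surviving_structure(lattice, oc, regime, rule)
    ok <- if (criterion == "all_strands_retained") {
      length(surv$removed_strands) == 0L
    } else {
      intact_connected(lattice, surv)
    }
    if (ok) total <- total + w
  }
  total
}

intact_connected <- function(lattice, surv) {
  if (length(surv$retained_strands) == 0L) return(FALSE)
  dp <- lattice$duplexes[lattice$duplexes$duplex %in% surv$present_duplexes, ]
  n_components(surv$retained_strands,
               as.matrix(dp[, c("strand_a", "strand_b")])) == 1L
}

# number of connected components over `vertices` with an edge matrix (2 cols)
n_components <- function(vertices, edges) {
  if (length(vertices) == 0L) return(0L)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(vertices)
  if (nrow(edges) > 0L) {
    g <- igraph::add_edges(g, t(edges))
  }
  igraph::components(g)$no
}

#' Intact proportion across a grid of ligation efficiencies
#'
#' One [intact_proportion()] per grid point, sharing the seed so the curve is
#' monotone under common random numbers.
#'
#' @param lattice a `lattice_graph`.
#' @param p_grid numeric vector of efficiencies in \[0, 1\].
#' @inheritParams intact_proportion
#' @return data frame with columns `p`, `intact_fraction`, `se`, `n_reps`,
#'   `criterion`.
#' @export
efficiency_scan <- function(lattice, p_grid,
                            regime = thermal_regime("intermediate"),
                            rule = lockin_rule(),
                            criterion = "all_strands_retained",
                            n_reps = 1000L, seed = NULL) {
  res <- lapply(p_grid, function(p)
    intact_proportion(lattice, p, regime, rule, criterion, n_reps, seed))
  data.frame(p = p_grid,
             intact_fraction = vapply(res, `[[`, 0, "intact_fraction"),
             se = vapply(res, `[[`, 0, "se"),
             n_reps = n_reps, criterion = criterion)
}
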