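#' Simulate stochastic nick sealing
#'
#' Each ligatable nick is sealed independently with probability `p` (the
#' single-parameter ligation efficiency). Non-ligatable nicks are never
#' sealed. Uniform draws are made once per nick in stable nick-id order, so
#' outcomes at different `p` under the same seed are coupled by common random
#' numbers: the sealed set is nondecreasing in `p`.
#'
#' @param lattice a [build_lattice()] result.
#' @param p ligation efficiency in \[0, 1\].
#' @param seed integer RNG seed.
#' @return an object of class `ligation_outcome`: named logical vector
#'   `sealed` over all nick ids, plus `p` and `seed`.
#' @export
seal_nicks <- function(lattice, p, seed = NULL) {
  stopifnot(inherits(lattice, "lattice_graph"))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("domain error: ligation efficiency p must be in [0, 1]", call. = FALSE)
  }
  n <- nrow(lattice$nicks)
  u <- local_runif(n, seed)
  sealed <- lattice$nicks$ligatable & (u < p)
  names(sealed) <- lattice$nicks$nick
  structure(list(sealed = sealed, p = p, seed = seed),
            class = "ligation_outcome")
}

# evaluate expr under a local seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

local_runif <- function(n, seed) with_seed(seed, stats::runif(n))

#' Construct a ligation outcome from an explicit sealed set
#'
#' Mostly useful for tests and exhaustive enumeration.
#' @param lattice a `lattice_graph`.
#' @param sealed_ids character vector of sealed nick ids (must be ligatable).
#' @return a `ligation_outcome`.
#' @export
ligation_outcome <- function(lattice, sealed_ids) {
  nk <- lattice$nicks
  bad <- setdiff(sealed_ids, nk$nick)
  if (length(bad)) stop("unknown nick id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  sealed <- nk$nick %in% sealed_ids
  if (any(sealed & !nk$ligatable)) {
    stop("only ligatable nicks may be sealed", call. = FALSE)
  }
  names(sealed) <- nk$nick
  structure(list(sealed = sealed, p = NA_real_, seed = NULL),
            class = "ligation_outcome")
}

#' Enumerate covalent ligation products
#'
#' Merges component strands along sealed nicks (a sealed nick joins the 3'
#' terminus of its upstream strand to the 5' terminus of its downstream
#' strand). Maximal covalent paths are linear species; closed walks are
#' circular species. Total nucleotides are conserved.
#'
#' @param lattice a `lattice_graph`.
#' @param outcome a [seal_nicks()] outcome.
#' @return a data frame of product species with columns `length_nt`,
#'   `circular`, `n_strands`, `members` (canonical `+`-joined strand ids)
#'   and `count` (multiplicity in this outcome).
#' @export
enumerate_products <- function(lattice, outcome) {
  stopifnot(inherits(outcome, "ligation_outcome"))
  st <- lattice$strands
  ns <- nrow(st)
  idx <- seq_len(ns); names(idx) <- st$strand
  nk <- lattice$nicks[outcome$sealed[lattice$nicks$nick], , drop = FALSE]
  succ <- rep(NA_integer_, ns); pred <- rep(NA_integer_, ns)
  if (nrow(nk)) {
    up <- idx[nk$upstream]; dn <- idx[nk$downstream]
    succ[up] <- dn; pred[dn] <- up
  }
  visited <- rep(FALSE, ns)
  rows <- vector("list", ns); nr <- 0L
  emit <- function(chain, circular) {
    nr <<- nr + 1L
    rows[[nr]] <<- list(length_nt = sum(st$length_nt[chain]),
                        circular = circular,
                        n_strands = length(chain),
                        members = paste(sort(st$strand[chain]), collapse = "+"))
  }
  # linear species: walk from strands with no covalent predecessor
  for (s in idx[is.na(pred)]) {
    chain <- integer(0); cur <- s
    while (!is.na(cur)) { chain <- c(chain, cur); visited[cur] <- TRUE; cur <- succ[cur] }
    emit(chain, FALSE)
  }
  # remaining strands are on cycles
  for (s in idx[!visited]) {
    if (visited[s]) next
    chain <- integer(0); cur <- s
    repeat {
      chain <- c(chain, cur); visited[cur] <- TRUE; cur <- succ[cur]
      if (cur == s) break
    }
    emit(chain, TRUE)
  }
  rows <- rows[seq_len(nr)]
  out <- data.frame(
    length_nt = vapply(rows, `[[`, 0, "length_nt"),
    circular = vapply(rows, `[[`, TRUE, "circular"),
    n_strands = vapply(rows, `[[`, 0, "n_strands"),
    members = vapply(rows, `[[`, "", "members"),
    stringsAsFactors = FALSE)
  # products partition the strand set, so composition keys are unique
  out$count <- 1L
  out <- out[order(-out$length_nt, out$members), ]
  rownames(out) <- NULL
  out
}

#' Designed covalent cycles of a lattice
#'
#' The circular species obtained when every nick (ligatable or not) is sealed:
#' the closed covalent walks of the design. For the 2x2 J4 lattice this is the
#' single 4-strand ring whose closure requires 4 sealed nicks; it is the
#' species assayed for ligation-efficiency calibration.
#'
#' @param lattice a `lattice_graph`.
#' @return a list of cycles, each a list with `members` (strand ids),
#'   `nicks` (the nick ids that must seal to close the cycle), `length_nt`.
#' @export
designed_cycles <- function(lattice) {
  all_sealed <- lattice$nicks$nick
  sealed <- rep(TRUE, length(all_sealed)); names(sealed) <- all_sealed
  oc <- structure(list(sealed = sealed, p = 1, seed = NULL),
                  class = "ligation_outcome")
  prods <- enumerate_products(lattice, oc)
  circ <- prods[prods$circular, , drop = FALSE]
  nk <- lattice$nicks
  lapply(seq_len(nrow(circ)), function(i) {
    members <- strsplit(circ$members[i], "+", fixed = TRUE)[[1]]
    nicks <- nk$nick[nk$upstream %in% members & nk$downstream %in% members]
    list(members = members, nicks = nicks, length_nt = circ$length_nt[i])
  })
}

#' Distribution of ligation products over sealing outcomes
#'
#' In `exact` mode, sums over all 2^N sealed states of the N ligatable nicks,
#' weighting each state by p^k (1-p)^(N-k); in `monte_carlo` mode, averages
#' over `n_reps` seeded [seal_nicks()] outcomes. Species are keyed by strand
#' composition; per-outcome mass fractions (species nucleotides over total
#' nucleotides) always sum to one.
#'
#' @param lattice a `lattice_graph`.
#' @param p ligation efficiency.
#' @param mode `"exact"` or `"monte_carlo"`.
#' @param n_reps Monte-Carlo replicates (default 10000).
#' @param seed RNG seed for Monte-Carlo mode.
#' @return an object of class `product_distribution`: list with a `species`
#'   data frame (`length_nt`, `circular`, `members`, `mass_fraction` = mean
#'   fraction of total mass, `frequency` = probability the species occurs),
#'   `mode`, `n`, `p`.
#' @export
product_distribution <- function(lattice, p, mode = c("exact", "monte_carlo"),
                                 n_reps = 10000L, seed = NULL) {
  mode <- match.arg(mode)
  if (p < 0 || p > 1) stop("domain error: p must be in [0, 1]", call. = FALSE)
  nk <- lattice$nicks
  lig <- nk$nick[nk$ligatable]
  N <- length(lig)
  total_nt <- sum(lattice$strands$length_nt)
  acc <- new.env(parent = emptyenv())
  add <- function(prods, w) {
    # a member set can occur open (n-1 nicks sealed) or closed (all n), so
    # the species key must carry the circular flag as well
    key <- paste0(prods$members, "|", prods$circular)
    mf <- prods$length_nt * prods$count / total_nt
    for (i in seq_along(key)) {
      cur <- acc[[key[i]]]
      if (is.null(cur)) {
        acc[[key[i]]] <- list(length_nt = prods$length_nt[i],
                              circular = prods$circular[i],
                              n_strands = prods$n_strands[i],
                              mass = w * mf[i], freq = w)
      } else {
        cur$mass <- cur$mass + w * mf[i]
        cur$freq <- cur$freq + w
        acc[[key[i]]] <- cur
      }
    }
  }
  if (mode == "exact") {
    if (N > 22L) {
      stop("capacity error: exact enumeration over 2^", N, " sealed states ",
           "exceeds the 2^22 cap; use mode = \"monte_carlo\"", call. = FALSE)
    }
    for (s in 0:(2^N - 1L)) {
      on <- as.logical(bitwAnd(s, bitwShiftL(1L, 0:(max(N, 1) - 1L)))[seq_len(N)])
      k <- sum(on)
      w <- p^k * (1 - p)^(N - k)
      if (w == 0) next
      oc <- ligation_outcome(lattice, lig[on])
      add(enumerate_products(lattice, oc), w)
    }
    wtot <- 1
  } else {
    u <- matrix(local_runif(n_reps * N, seed), nrow = n_reps)
    for (r in seq_len(n_reps)) {
      oc <- ligation_outcome(lattice, lig[u[r, ] < p])
      add(enumerate_products(lattice, oc), 1)
    }
    wtot <- n_reps
  }
  keys <- ls(acc)
  species <- data.frame(
    length_nt = vapply(keys, function(k) acc[[k]]$length_nt, 0),
    circular = vapply(keys, function(k) acc[[k]]$circular, TRUE),
    n_strands = vapply(keys, function(k) acc[[k]]$n_strands, 0),
    members = sub("\\|(TRUE|FALSE)$", "", keys),
    mass_fraction = vapply(keys, function(k) acc[[k]]$mass, 0) / wtot,
    frequency = vapply(keys, function(k) acc[[k]]$freq, 0) / wtot,
    stringsAsFactors = FALSE, row.names = NULL)
  species <- species[order(-species$length_nt, species$members), ]
  rownames(species) <- NULL
  structure(list(species = species, mode = mode,
                 n = if (mode == "exact") 2^N else n_reps, p = p),
            class = "product_distribution")
}

#' @export
print.product_distribution <- function(x, ...) {
  cat("<product_distribution> mode=", x$mode, " p=", x$p, " n=", x$n,
      " (", nrow(x$species), " species)\n", sep = "")
  print(utils::head(x$species, 10))
  invisible(x)
}

#' Estimate ligation efficiency from a circular-product fraction
#'
#' A designed covalent cycle closes only when all of its `n_nicks` nicks are
#' sealed, so under independent per-nick sealing at efficiency p the circular
#' fraction is f = p^n and the estimator is `p_hat = f^(1/n_nicks)`. Any
#' correction for incompletely assembled lattices must be applied to `f`
#' upstream.
#'
#' @param f observed circular-product fraction in \[0, 1\].
#' @param n_nicks number of nicks that must seal to close the assayed cycle.
#' @return list with `p_hat`, `n_nicks`, `f`.
#' @examples
#' estimate_efficiency(0.25, 2)$p_hat  # 0.5
#' @export
estimate_efficiency <- function(f, n_nicks) {
  if (!is.numeric(f) || is.na(f) || f < 0 || f > 1) {
    stop("domain error: circular fraction f must be in [0, 1]", call. = FALSE)
  }
  n_nicks <- as.integer(n_nicks)
  if (is.na(n_nicks) || n_nicks < 1L) {
    stop("domain error: n_nicks must be >= 1", call. = FALSE)
  }
  structure(list(p_hat = f^(1 / n_nicks), n_nicks = n_nicks, f = f),
            class = "efficiency_estimate")
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("<efficiency_estimate> p_hat = %.4f (f = %.4g over a %d-nick cycle)\n",
              x$p_hat, x$f, x$n_nicks))
  invisible(x)
}

#' Predict a denaturing-gel band pattern from a product distribution
#'
#' Denaturing PAGE separates covalent species by size (and circular topology);
#' composition-keyed species of equal length and circularity co-migrate and
#' are merged into one band. Band intensity is proportional to the mean mass
#' fraction; bands below a detectability floor are suppressed.
#'
#' @param dist a [product_distribution()].
#' @param floor minimum mass fraction for a band to be reported
#'   (default 0.005).
#' @return data frame with `length_nt`, `circular`, `intensity` (mass
#'   fraction), `frequency`.
#' @export
predict_gel_pattern <- function(dist, floor = 0.005) {
  stopifnot(inherits(dist, "product_distribution"))
  sp <- dist$species
  agg <- stats::aggregate(sp[, c("mass_fraction", "frequency")],
                          by = list(length_nt = sp$length_nt,
                                    circular = sp$circular),
                          FUN = sum)
  names(agg)[names(agg) == "mass_fraction"] <- "intensity"
  agg <- agg[agg$intensity >= floor, ]
  agg <- agg[order(-agg$length_nt, agg$circular), ]
  rownames(agg) <- NULL
  agg
}
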