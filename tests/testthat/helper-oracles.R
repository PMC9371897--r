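# Independent brute-force oracles, deliberately written with different
# algorithms than the package internals.

# union-find covalent-product oracle: strands joined by sealed nicks
oracle_products <- function(lattice, sealed_ids) {
  st <- lattice$strands$strand
  parent <- seq_along(st)
  names(parent) <- st
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nk <- lattice$nicks[lattice$nicks$nick %in% sealed_ids, , drop = FALSE]
  for (i in seq_len(nrow(nk))) {
    a <- find(match(nk$upstream[i], st)); b <- find(match(nk$downstream[i], st))
    if (a != b) parent[a] <- b
  }
  root <- vapply(seq_along(st), find, 0L)
  groups <- split(st, root)
  len <- lattice$strands$length_nt
  do.call(rbind, lapply(groups, function(g) {
    k <- sum(nk$upstream %in% g)  # sealed nicks internal to the group
    data.frame(members = paste(sort(g), collapse = "+"),
               length_nt = sum(len[match(g, st)]),
               n_strands = length(g),
               circular = k == length(g))
  }))
}

# exhaustive designed-ring count for a fully sealed lattice: number of
# interior plaquettes of the motif grid
expected_ring_count <- function(design) (design$rows - 1L) * (design$cols - 1L)
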