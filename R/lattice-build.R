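#' Build an explicit strand/duplex/nick graph from a lattice design
#'
#' Assembles the lattice described by a [lattice_design()] into an explicit
#' graph of component strands, paired duplexes, and nicks.
#'
#' Strand layout for junction motifs: each motif contributes one strand per
#' arm. In cyclic (compass) arm order, strand *k* runs 5'->3' from the
#' single-stranded stem of arm *k*, through the root (inbound) half of arm *k*,
#' around the junction, and out along the root (outbound) half of arm *k+1*,
#' ending flush at the tip of arm *k+1*. Each arm's root duplex therefore
#' pairs two consecutive strands of the motif; each intermotif edge pairs the
#' stems of two facing strands and carries exactly two nicks, one on each
#' motif's side, each joining a 3' root terminus to the 5' phosphate of the
#' facing stem on a continuous complementary template. Sealing a nick fuses
#' a root and a stem into one continuous duplex (21 bp for an 11-bp root plus
#' 10-bp stem).
#'
#' DX tiles are built with the same machinery on diagonal arms (NW/NE/SE/SW)
#' in half-offset brick rows; the DX-I configuration additionally splits one
#' strand per tile with an internal nick inside a rigidity domain.
#'
#' Nick and edge identifiers are stable: grid coordinates are 0-based
#' row-major; edges are named after the lower-coordinate motif plus direction
#' (e.g. `e_r0c0_E`), nicks as `<edge>:a` (lower-motif side) and `<edge>:b`.
#'
#' @param design a [lattice_design()].
#' @return an object of class `lattice_graph`: a list with data frames
#'   `motifs`, `strands`, `duplexes`, `edges`, `nicks` and the originating
#'   `design`.
#' @examples
#' lat <- build_lattice(builtin_design("J4-I"))
#' count_nicks(lat)                    # 120
#' nrow(lat$edges)                     # 60
#' @export
build_lattice <- function(design) {
  design <- as_lattice_design(design)
  rows <- design$rows; cols <- design$cols
  motif_id <- function(r, c) sprintf("m_r%dc%d", r, c)
  grid <- expand.grid(col = 0:(cols - 1), row = 0:(rows - 1))
  motifs <- data.frame(motif = motif_id(grid$row, grid$col),
                       row = grid$row, col = grid$col,
                       stringsAsFactors = FALSE)

  arms_of <- motif_arms(design)        # named list motif -> arm vector (cyclic order)
  edges <- lattice_edges(design, motif_id)

  # which (motif, arm) slots are paired by an edge or boundary duplex
  paired <- unique(rbind(
    data.frame(motif = edges$motif_a, arm = edges$arm_a, stringsAsFactors = FALSE),
    data.frame(motif = edges$motif_b, arm = edges$arm_b, stringsAsFactors = FALSE)))
  paired_key <- paste(paired$motif, paired$arm)

  is_dx1 <- design$motif_type == "DX" && design$internal_nicks_per_motif >= 1L
  root_len <- design$domains$root %||% design$domains$rigidity
  stem_len <- design$domains$stem %||% design$domains$sticky

  strands <- list(); duplexes <- list(); nicks <- list()
  # per-(motif,arm) ownership maps used to wire edges
  stem_owner <- character(); root_out_owner <- character(); tip_root_len <- integer()
  stem_len_at <- integer()

  for (mi in seq_len(nrow(motifs))) {
    m <- motifs$motif[mi]
    arms <- arms_of[[m]]
    n <- length(arms)
    for (j in seq_len(n)) {
      arm <- arms[j]
      arm_next <- arms[j %% n + 1L]
      key <- paste(m, arm)
      armpaired <- key %in% paired_key
      slen <- if (!armpaired) 0L else {
        b <- edges[edges$class == "boundary" &
                   ((edges$motif_a == m & edges$arm_a == arm) |
                    (edges$motif_b == m & edges$arm_b == arm)), ]
        if (nrow(b) > 0) design$boundary$length else stem_len
      }
      stem_len_at[key] <- slen
      sid <- sprintf("s_%s_%s", m, arm)
      if (is_dx1 && j == 1L) {
        # split strand: internal nick inside the rigidity domain of arm 1
        head_len <- root_len %/% 2L
        tail_len <- root_len - head_len
        sid_b <- paste0(sid, "i")
        strands[[length(strands) + 1L]] <- data.frame(
          strand = c(sid, sid_b), motif = m,
          stem_arm = c(arm, NA_character_),
          length_nt = c(slen + head_len, tail_len + root_len),
          stringsAsFactors = FALSE)
        stem_owner[key] <- sid
        root_out_owner[paste(m, arm_next)] <- sid_b
        tip_root_len[key] <- head_len
        # the arm-j root duplex is split into two sub-duplexes
        partner <- sprintf("s_%s_%s", m, arms[n])  # strand whose root_out is at arm j
        duplexes[[length(duplexes) + 1L]] <- data.frame(
          duplex = sprintf("d_%s_%s.%d", m, arm, 1:2),
          class = "intramotif", length_bp = c(head_len, tail_len),
          strand_a = c(sid, sid_b), strand_b = partner,
          edge = NA_character_, motif = m, stringsAsFactors = FALSE)
        nicks[[length(nicks) + 1L]] <- data.frame(
          nick = sprintf("%s:i1", m), class = "internal",
          edge = NA_character_, side = NA_character_,
          upstream = sid, downstream = sid_b,
          template = partner, fused_length = root_len,
          ligatable = TRUE, stringsAsFactors = FALSE)
      } else {
        strands[[length(strands) + 1L]] <- data.frame(
          strand = sid, motif = m, stem_arm = arm,
          length_nt = slen + 2L * root_len, stringsAsFactors = FALSE)
        stem_owner[key] <- sid
        root_out_owner[paste(m, arm_next)] <- sid
        tip_root_len[key] <- root_len
      }
    }
    # intramotif root duplexes for the non-split arms
    start_j <- if (is_dx1) 2L else 1L
    for (j in start_j:n) {
      arm <- arms[j]
      prev_arm <- arms[(j - 2L) %% n + 1L]
      owner_in <- stem_owner[paste(m, arm)]
      if (is_dx1 && j == 1L) next
      # root_in at arm j belongs to strand stem_owner(arm j) (or its tail part)
      s_in <- if (is_dx1 && j == 1L) NA_character_ else owner_in
      duplexes[[length(duplexes) + 1L]] <- data.frame(
        duplex = sprintf("d_%s_%s", m, arm),
        class = "intramotif", length_bp = root_len,
        strand_a = s_in,
        strand_b = root_out_owner[paste(m, arm)],
        edge = NA_character_, motif = m, stringsAsFactors = FALSE)
    }
  }

  strands <- do.call(rbind, strands)
  rownames(strands) <- NULL

  # intermotif / boundary duplexes and their two nicks
  if (nrow(edges) > 0) {
    for (ei in seq_len(nrow(edges))) {
      e <- edges[ei, ]
      key_a <- paste(e$motif_a, e$arm_a); key_b <- paste(e$motif_b, e$arm_b)
      sa <- stem_owner[key_a]; sb <- stem_owner[key_b]
      dlen <- stem_len_at[key_a]
      duplexes[[length(duplexes) + 1L]] <- data.frame(
        duplex = paste0("d_", e$edge),
        class = if (e$class == "boundary") "boundary" else "intermotif",
        length_bp = dlen, strand_a = sa, strand_b = sb,
        edge = e$edge, motif = NA_character_, stringsAsFactors = FALSE)
      nicks[[length(nicks) + 1L]] <- data.frame(
        nick = paste0(e$edge, c(":a", ":b")),
        class = if (e$class == "boundary") "boundary" else "edge",
        edge = e$edge, side = c("a", "b"),
        upstream = c(root_out_owner[key_a], root_out_owner[key_b]),
        downstream = c(sb, sa),
        template = c(sa, sb),
        fused_length = c(tip_root_len[key_a] + dlen, tip_root_len[key_b] + dlen),
        ligatable = TRUE, stringsAsFactors = FALSE)
    }
  }

  duplexes <- do.call(rbind, duplexes); rownames(duplexes) <- NULL
  nicks <- if (length(nicks)) do.call(rbind, nicks) else
    data.frame(nick = character(), class = character(), edge = character(),
               side = character(), upstream = character(),
               downstream = character(), template = character(),
               fused_length = integer(), ligatable = logical(),
               stringsAsFactors = FALSE)
  rownames(nicks) <- NULL
  # stable order: nicks sorted by id for reproducible seeded sealing
  nicks <- nicks[order(nicks$nick), , drop = FALSE]
  rownames(nicks) <- NULL

  stopifnot(!anyDuplicated(nicks$nick), !anyDuplicated(strands$strand),
            !anyDuplicated(nicks$upstream), !anyDuplicated(nicks$downstream))

  lat <- structure(
    list(design = design, motifs = motifs, strands = strands,
         duplexes = duplexes, edges = edges[, c("edge", "class", "motif_a",
                                                "motif_b", "arm_a", "arm_b")],
         nicks = nicks),
    class = "lattice_graph")
  apply_phosphorylation_mask(lat, design$mask)
}

# cyclic (compass-order) arms per motif
motif_arms <- function(design) {
  rows <- design$rows; cols <- design$cols
  out <- list()
  for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
    m <- sprintf("m_r%dc%d", r, c)
    out[[m]] <- switch(design$motif_type,
      J4 = c("N", "E", "S", "W"),
      DX = c("NW", "NE", "SE", "SW"),
      J3 = {
        v <- if ((r + c) %% 2L == 0L) "S" else "N"
        # compass cyclic order N, E, S, W restricted to the present arms
        intersect(c("N", "E", "S", "W"), c("E", "W", v))
      })
  }
  out
}

# edge table: lower-coordinate motif first (owns the id)
lattice_edges <- function(design, motif_id) {
  rows <- design$rows; cols <- design$cols
  es <- list()
  add <- function(id, ma, aa, mb, ab, class = "intermotif") {
    es[[length(es) + 1L]] <<- data.frame(
      edge = id, class = class, motif_a = ma, motif_b = mb,
      arm_a = aa, arm_b = ab, stringsAsFactors = FALSE)
  }
  if (design$connectivity == "square_grid") {
    for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
      if (c < cols - 1) add(sprintf("e_r%dc%d_E", r, c),
                            motif_id(r, c), "E", motif_id(r, c + 1), "W")
      if (r < rows - 1) add(sprintf("e_r%dc%d_S", r, c),
                            motif_id(r, c), "S", motif_id(r + 1, c), "N")
    }
  } else if (design$connectivity == "brick_wall") {
    for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
      if (c < cols - 1) add(sprintf("e_r%dc%d_E", r, c),
                            motif_id(r, c), "E", motif_id(r, c + 1), "W")
      if ((r + c) %% 2L == 0L && r < rows - 1)
        add(sprintf("e_r%dc%d_S", r, c),
            motif_id(r, c), "S", motif_id(r + 1, c), "N")
    }
  } else { # dx_rows: half-offset brick rows, joints to the row below
    for (r in 0:(rows - 1)) for (c in 0:(cols - 1)) {
      if (r >= rows - 1) next
      if (r %% 2L == 0L) {       # unshifted row above shifted row
        if (c >= 1) add(sprintf("e_r%dc%d_SW", r, c),
                        motif_id(r, c), "SW", motif_id(r + 1, c - 1), "NE")
        add(sprintf("e_r%dc%d_SE", r, c),
            motif_id(r, c), "SE", motif_id(r + 1, c), "NW")
      } else {                   # shifted row above unshifted row
        add(sprintf("e_r%dc%d_SW", r, c),
            motif_id(r, c), "SW", motif_id(r + 1, c), "NE")
        if (c < cols - 1) add(sprintf("e_r%dc%d_SE", r, c),
                              motif_id(r, c), "SE", motif_id(r + 1, c + 1), "NW")
      }
    }
  }
  # sheet-closure boundary duplexes (E side of last column to W side of first)
  if (design$boundary$policy == "overhang" &&
      isTRUE(design$boundary$complementary)) {
    for (r in 0:(rows - 1)) {
      add(sprintf("b_r%d_EW", r),
          motif_id(r, cols - 1), "E", motif_id(r, 0), "W", class = "boundary")
    }
  }
  if (length(es) == 0) {
    return(data.frame(edge = character(), class = character(),
                      motif_a = character(), motif_b = character(),
                      arm_a = character(), arm_b = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, es)
}

#' @export
print.lattice_graph <- function(x, ...) {
  cat("<lattice_graph> ", x$design$name, ": ", nrow(x$motifs), " motifs, ",
      nrow(x$strands), " strands, ",
      sum(x$edges$class == "intermotif"), " intermotif edges, ",
      count_nicks(x), " nicks (", count_nicks(x, ligatable_only = TRUE),
      " ligatable)\n", sep = "")
  invisible(x)
}

#' Count nicks in an assembled lattice
#'
#' @param lattice a [build_lattice()] result.
#' @param ligatable_only if `TRUE`, count only nicks whose downstream 5' end is
#'   phosphorylated under the current mask.
#' @return integer count.
#' @export
count_nicks <- function(lattice, ligatable_only = FALSE) {
  stopifnot(inherits(lattice, "lattice_graph"))
  if (ligatable_only) sum(lattice$nicks$ligatable) else nrow(lattice$nicks)
}

#' Length of the continuous duplex formed by sealing a nick
#'
#' The combined length, in base pairs, of the paired domains flanking the nick
#' (e.g. an 11-bp root plus a 10-bp stem gives 21 bp for the J4-I lattice).
#'
#' @param lattice a `lattice_graph`.
#' @param nick a nick id.
#' @return integer length in bp.
#' @export
ligated_segment_length <- function(lattice, nick) {
  i <- match(nick, lattice$nicks$nick)
  if (is.na(i)) stop("lookup error: unknown nick id '", nick, "'", call. = FALSE)
  lattice$nicks$fused_length[i]
}

#' Apply a phosphorylation mask to a lattice
#'
#' Sets the `ligatable` flag of every nick according to the mask: only nicks
#' whose downstream 5' end carries a phosphate can be sealed by ligase.
#' Idempotent.
#'
#' @param lattice a `lattice_graph`.
#' @param mask `"all"`, a character vector of nick ids, or a list with one of
#'   `nicks`, `strands` (nicks whose downstream strand is listed), or
#'   `cut_edges` (all nicks except those on the listed edges).
#' @return the lattice with updated `ligatable` flags.
#' @export
apply_phosphorylation_mask <- function(lattice, mask) {
  stopifnot(inherits(lattice, "lattice_graph"))
  nk <- lattice$nicks
  if (is.character(mask) && !identical(mask, "all")) mask <- list(nicks = mask)
  if (identical(mask, "all")) {
    lig <- rep(TRUE, nrow(nk))
  } else {
    validate_mask_spec(mask)
    if (!is.null(mask$nicks)) {
      ids <- unlist(mask$nicks)
      bad <- setdiff(ids, nk$nick)
      if (length(bad)) stop("configuration error: mask references unknown nick id(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
      lig <- nk$nick %in% ids
    } else if (!is.null(mask$strands)) {
      ids <- unlist(mask$strands)
      bad <- setdiff(ids, lattice$strands$strand)
      if (length(bad)) stop("configuration error: mask references unknown strand id(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
      lig <- nk$downstream %in% ids
    } else {
      ids <- unlist(mask$cut_edges)
      bad <- setdiff(ids, lattice$edges$edge)
      if (length(bad)) stop("configuration error: mask references unknown edge id(s): ",
                            paste(bad, collapse = ", "), call. = FALSE)
      lig <- !(nk$edge %in% ids)
    }
  }
  lattice$nicks$ligatable <- lig
  lattice
}

#' Classify a nick relative to a focal strand
#'
#' A nick is `X_I`/`X_II` for the strand whose 5'/3' terminus it joins (sealing
#' it locks that strand in fully) and `Y` for the strand it templates (the
#' continuous complementary strand spanning the nick; sealing gives partial
#' lock-in).
#'
#' @param lattice a `lattice_graph`.
#' @param nick nick id.
#' @param strand focal strand id.
#' @return `"X_I"`, `"X_II"`, `"Y"` or `NA` if unrelated.
#' @export
nick_label <- function(lattice, nick, strand) {
  i <- match(nick, lattice$nicks$nick)
  if (is.na(i)) stop("lookup error: unknown nick id '", nick, "'", call. = FALSE)
  n <- lattice$nicks[i, ]
  if (identical(n$downstream, strand)) return("X_I")
  if (identical(n$upstream, strand)) return("X_II")
  if (identical(n$template, strand)) return("Y")
  NA_character_
}

#' Export / import a lattice graph as a plain-text edge list
#'
#' Writes a typed, tab-separated edge list (motif, strand, duplex and nick
#' records) that [import_lattice_graph()] can round-trip into a
#' `lattice_graph` with identical identifiers and counts.
#'
#' @param lattice a `lattice_graph`.
#' @param path output file path.
#' @return `export_graph()` returns `path` invisibly;
#'   `import_lattice_graph()` returns a `lattice_graph`.
#' @export
export_graph <- function(lattice, path) {
  stopifnot(inherits(lattice, "lattice_graph"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  w("# nicklattice graph v1")
  for (i in seq_len(nrow(lattice$motifs)))
    w("motif", lattice$motifs$motif[i], lattice$motifs$row[i], lattice$motifs$col[i])
  for (i in seq_len(nrow(lattice$strands)))
    w("strand", lattice$strands$strand[i], lattice$strands$motif[i],
      lattice$strands$stem_arm[i], lattice$strands$length_nt[i])
  for (i in seq_len(nrow(lattice$edges)))
    w("edge", lattice$edges$edge[i], lattice$edges$class[i],
      lattice$edges$motif_a[i], lattice$edges$motif_b[i],
      lattice$edges$arm_a[i], lattice$edges$arm_b[i])
  for (i in seq_len(nrow(lattice$duplexes)))
    w("duplex", lattice$duplexes$duplex[i], lattice$duplexes$class[i],
      lattice$duplexes$length_bp[i], lattice$duplexes$strand_a[i],
      lattice$duplexes$strand_b[i], lattice$duplexes$edge[i],
      lattice$duplexes$motif[i])
  for (i in seq_len(nrow(lattice$nicks)))
    w("nick", lattice$nicks$nick[i], lattice$nicks$class[i],
      lattice$nicks$edge[i], lattice$nicks$side[i],
      lattice$nicks$upstream[i], lattice$nicks$downstream[i],
      lattice$nicks$template[i], lattice$nicks$fused_length[i],
      lattice$nicks$ligatable[i])
  invisible(path)
}

#' @rdname export_graph
#' @export
import_lattice_graph <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- strsplit(ln, "\t", fixed = TRUE)
  type <- vapply(f, `[[`, "", 1L)
  pick <- function(t) f[type == t]
  col <- function(recs, i) vapply(recs, `[[`, "", i)
  na_ <- function(x) ifelse(x == "NA", NA_character_, x)
  mo <- pick("motif")
  motifs <- data.frame(motif = col(mo, 2), row = as.integer(col(mo, 3)),
                       col = as.integer(col(mo, 4)), stringsAsFactors = FALSE)
  st <- pick("strand")
  strands <- data.frame(strand = col(st, 2), motif = col(st, 3),
                        stem_arm = na_(col(st, 4)),
                        length_nt = as.integer(col(st, 5)),
                        stringsAsFactors = FALSE)
  ed <- pick("edge")
  edges <- data.frame(edge = col(ed, 2), class = col(ed, 3),
                      motif_a = col(ed, 4), motif_b = col(ed, 5),
                      arm_a = col(ed, 6), arm_b = col(ed, 7),
                      stringsAsFactors = FALSE)
  du <- pick("duplex")
  duplexes <- data.frame(duplex = col(du, 2), class = col(du, 3),
                         length_bp = as.integer(col(du, 4)),
                         strand_a = col(du, 5), strand_b = col(du, 6),
                         edge = na_(col(du, 7)), motif = na_(col(du, 8)),
                         stringsAsFactors = FALSE)
  nk <- pick("nick")
  nicks <- data.frame(nick = col(nk, 2), class = col(nk, 3),
                      edge = na_(col(nk, 4)), side = na_(col(nk, 5)),
                      upstream = col(nk, 6), downstream = col(nk, 7),
                      template = col(nk, 8),
                      fused_length = as.integer(col(nk, 9)),
                      ligatable = as.logical(col(nk, 10)),
                      stringsAsFactors = FALSE)
  structure(list(design = NULL, motifs = motifs, strands = strands,
                 duplexes = duplexes, edges = edges, nicks = nicks),
            class = "lattice_graph")
}
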