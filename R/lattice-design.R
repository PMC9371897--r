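#' Lattice design configurations
#'
#' A `lattice_design` is a declarative description of an addressable DNA
#' lattice: the motif type (4-arm junction, 3-arm junction, or double-crossover
#' tile), the grid dimensions, the connectivity pattern, the domain lengths,
#' the boundary policy and the phosphorylation mask. [build_lattice()] turns a
#' design into an explicit strand/duplex/nick graph.
#'
#' Domain semantics follow the wireframe-lattice convention: each junction arm
#' carries a double-stranded *root* domain and a single-stranded *stem* domain;
#' two complementary stem domains of facing arms pair into an intermotif edge.
#' DX tiles use *rigidity* (intramotif duplex) and *sticky* (intermotif)
#' domains; internally the builder treats rigidity/sticky as root/stem.
#'
#' @param motif_type one of `"J4"`, `"J3"`, `"DX"`.
#' @param rows,cols grid dimensions (motifs), both >= 1.
#' @param connectivity `"square_grid"` (J4), `"brick_wall"` (J3) or
#'   `"dx_rows"` (DX half-offset brick rows).
#' @param domains named list of domain lengths in nucleotides. Junction motifs
#'   require `root` and `stem`; DX motifs `rigidity` and `sticky`.
#' @param boundary boundary policy: `list(policy = "blunt")` (default; boundary
#'   arms carry no single-stranded extension) or
#'   `list(policy = "overhang", sides = c("E","W"), length = 3,
#'   complementary = TRUE)` for sticky-end sheet-closure designs.
#' @param internal_nicks_per_motif integer; extra nicks inside each motif
#'   (used by the DX-I configuration; 0 otherwise).
#' @param mask phosphorylation mask: `"all"` (every nick 5'-phosphorylated,
#'   the default), or a list with exactly one of `nicks` (character vector of
#'   nick ids), `strands` (nicks whose downstream 5' end belongs to a listed
#'   strand), or `cut_edges` (all nicks ligatable except those on the listed
#'   edges).
#' @param name optional display name.
#'
#' @return an object of class `lattice_design`.
#' @seealso [builtin_design()], [read_lattice_design()], [build_lattice()]
#' @export
lattice_design <- function(motif_type, rows, cols,
                           connectivity = NULL,
                           domains = list(root = 11L, stem = 10L),
                           boundary = list(policy = "blunt"),
                           internal_nicks_per_motif = 0L,
                           mask = "all",
                           name = NULL) {
  motif_type <- match.arg(motif_type, c("J4", "J3", "DX"))
  if (is.null(connectivity)) {
    connectivity <- switch(motif_type,
      J4 = "square_grid", J3 = "brick_wall", DX = "dx_rows")
  }
  connectivity <- match.arg(connectivity, c("square_grid", "brick_wall", "dx_rows"))
  ok <- switch(motif_type,
    J4 = connectivity == "square_grid",
    J3 = connectivity == "brick_wall",
    DX = connectivity == "dx_rows")
  if (!ok) {
    stop("configuration error: connectivity '", connectivity,
         "' is not compatible with motif type '", motif_type, "'", call. = FALSE)
  }
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1L || cols < 1L) {
    stop("configuration error: rows and cols must be integers >= 1", call. = FALSE)
  }
  if (motif_type == "DX") {
    need <- c("rigidity", "sticky")
  } else {
    need <- c("root", "stem")
  }
  if (!all(need %in% names(domains))) {
    stop("configuration error: domains must include ",
         paste(need, collapse = " and "), " for motif type ", motif_type,
         call. = FALSE)
  }
  domains <- lapply(domains, as.integer)
  if (any(unlist(domains) < 1L)) {
    stop("configuration error: all domain lengths must be >= 1 nt", call. = FALSE)
  }
  boundary$policy <- match.arg(boundary$policy, c("blunt", "overhang"))
  if (boundary$policy == "overhang") {
    if (is.null(boundary$sides)) boundary$sides <- c("E", "W")
    if (is.null(boundary$length)) boundary$length <- 3L
    boundary$length <- as.integer(boundary$length)
    if (is.null(boundary$complementary)) boundary$complementary <- TRUE
    if (!setequal(boundary$sides, c("E", "W"))) {
      stop("configuration error: overhang boundary is supported on the E/W sides",
           call. = FALSE)
    }
    if (motif_type != "J4") {
      stop("configuration error: overhang boundary requires a J4 lattice",
           call. = FALSE)
    }
  }
  validate_mask_spec(mask)
  structure(
    list(motif_type = motif_type, rows = rows, cols = cols,
         connectivity = connectivity, domains = domains,
         boundary = boundary,
         internal_nicks_per_motif = as.integer(internal_nicks_per_motif),
         mask = mask, name = name %||% motif_type),
    class = "lattice_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_mask_spec <- function(mask) {
  if (identical(mask, "all")) return(invisible(TRUE))
  if (!is.list(mask) ||
      sum(c("nicks", "strands", "cut_edges") %in% names(mask)) != 1L) {
    stop("configuration error: mask must be \"all\" or a list with exactly one of ",
         "'nicks', 'strands', 'cut_edges'", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.lattice_design <- function(x, ...) {
  cat("<lattice_design> ", x$name, ": ", x$motif_type, " ",
      x$rows, "x", x$cols, " (", x$connectivity, ")\n", sep = "")
  cat("  domains:", paste(names(x$domains), unlist(x$domains),
                          sep = "=", collapse = ", "), "\n")
  cat("  boundary:", x$boundary$policy,
      if (x$boundary$policy == "overhang")
        paste0("(", x$boundary$length, " nt, ",
               if (isTRUE(x$boundary$complementary)) "complementary"
               else "non-complementary", ")"),
      "\n")
  invisible(x)
}

# single source of truth for the shipped design configurations
builtin_design_list <- function() {
  list(
    `J4-I` = list(motif_type = "J4", rows = 6, cols = 6,
                  domains = list(root = 11, stem = 10)),
    `J4-II` = list(motif_type = "J4", rows = 6, cols = 6,
                   domains = list(root = 13, stem = 6)),
    `J4-III` = list(motif_type = "J4", rows = 6, cols = 6,
                    domains = list(root = 16, stem = 10)),
    `J3` = list(motif_type = "J3", rows = 6, cols = 7,
                domains = list(root = 11, stem = 10)),
    `DX-I` = list(motif_type = "DX", rows = 6, cols = 6,
                  domains = list(rigidity = 21, sticky = 10),
                  internal_nicks_per_motif = 1),
    `DX-II` = list(motif_type = "DX", rows = 6, cols = 6,
                   domains = list(rigidity = 11, sticky = 11)),
    `J4-I_2x2` = list(motif_type = "J4", rows = 2, cols = 2,
                      domains = list(root = 11, stem = 10)),
    `J4-I_3x3` = list(motif_type = "J4", rows = 3, cols = 3,
                      domains = list(root = 11, stem = 10)),
    `fig4d_tube` = list(motif_type = "J4", rows = 6, cols = 6,
                        domains = list(root = 11, stem = 10),
                        boundary = list(policy = "overhang",
                                        sides = c("E", "W"),
                                        length = 3, complementary = TRUE))
  )
}

#' Built-in lattice designs
#'
#' Returns one of the shipped lattice configurations: the three 6x6 4-arm
#' junction lattices (`"J4-I"`, `"J4-II"`, `"J4-III"`), the 6x7 3-arm junction
#' brick-wall lattice (`"J3"`), the two 6x6 DX-tile lattices (`"DX-I"`,
#' `"DX-II"`), the small calibration lattices (`"J4-I_2x2"`, `"J4-I_3x3"`)
#' and the sticky-end tube variant (`"fig4d_tube"`).
#'
#' The J4/J3 configurations carry the reference structural accounting
#' (120/120/120/108 ligatable nicks). The DX wiring is a minimal construction
#' chosen to realize the reference nick counts (146 and 110); see the package
#' vignette.
#'
#' @param name design name (see above).
#' @return a [lattice_design()].
#' @export
builtin_design <- function(name) {
  defs <- builtin_design_list()
  if (!name %in% names(defs)) {
    stop("unknown built-in design '", name, "'; available: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  }
  do.call(lattice_design, c(defs[[name]], list(name = name)))
}

#' Read / write lattice design configurations (JSON)
#'
#' @param path file path.
#' @return `read_lattice_design()` returns a [lattice_design()];
#'   `write_lattice_design()` returns `path` invisibly.
#' @export
read_lattice_design <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_lattice_design(x)
}

#' @rdname read_lattice_design
#' @param design a [lattice_design()].
#' @export
write_lattice_design <- function(design, path) {
  x <- unclass(design)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Coerce a plain list (e.g. parsed JSON) to a lattice design
#' @param x a named list with the fields of [lattice_design()].
#' @return a [lattice_design()].
#' @export
as_lattice_design <- function(x) {
  if (inherits(x, "lattice_design")) return(x)
  keep <- intersect(names(x),
                    c("motif_type", "rows", "cols", "connectivity", "domains",
                      "boundary", "internal_nicks_per_motif", "mask", "name"))
  x <- x[keep]
  if (!is.null(x$domains)) x$domains <- as.list(x$domains)
  if (!is.null(x$boundary)) x$boundary <- as.list(x$boundary)
  if (!is.null(x$mask) && !identical(x$mask, "all")) x$mask <- as.list(x$mask)
  do.call(lattice_design, x)
}

#' Read a reconfiguration specification (mask + target shape)
#'
#' A reconfiguration spec names a base design, a phosphorylation mask and the
#' set of motif coordinates expected to survive the ligate-then-heat
#' treatment. The shipped fixtures `fig4a_mask.json`, `fig4b_mask.json` and
#' `fig4c_mask.json` carve the 6x6 J4-I lattice along straight seams with
#' 96, 96 and 108 ligatable nicks respectively.
#'
#' @param path JSON file with fields `base` (built-in design name or inline
#'   design), `mask`, and `target_shape` (list of `[row, col]` pairs).
#' @return a list with elements `design`, `mask`, `target_shape` (integer
#'   matrix with columns row, col).
#' @export
read_reconfig_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- if (is.character(x$base)) builtin_design(x$base) else
    as_lattice_design(x$base)
  mask <- if (identical(x$mask, "all")) "all" else as.list(x$mask)
  validate_mask_spec(mask)
  ts <- x$target_shape
  if (is.list(ts)) ts <- do.call(rbind, ts)
  ts <- matrix(as.integer(ts), ncol = 2,
               dimnames = list(NULL, c("row", "col")))
  list(design = design, mask = mask, target_shape = ts)
}
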