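#' @useDynLib fireflyfold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# --- lattice specifications -------------------------------------------------

cubic_offsets <- function() {
  matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
         ncol = 3, byrow = TRUE)
}

fcc_offsets <- function() {
  m <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  m <- as.matrix(m[abs(m$x) + abs(m$y) + abs(m$z) == 2, , drop = FALSE])
  dimnames(m) <- NULL
  m[order(m[, 1], m[, 2], m[, 3]), , drop = FALSE]
}

#' Lattice specification
#'
#' Defines one of the two supported three-dimensional lattices. The cubic
#' lattice is the integer grid with unit-step adjacency (6 neighbours per
#' node). The FCC (face-centred-cubic) lattice is represented as the integer
#' points with even coordinate sum, with the 12 neighbour offsets that are
#' permutations of (+-1, +-1, 0); this keeps all adjacency arithmetic
#' integral. The basis matrix (columns are primitive lattice vectors of unit
#' length) is retained only for exporting Cartesian geometry, see
#' [fcc_to_cartesian()].
#'
#' @param kind `"cubic"` or `"fcc"`.
#' @return An object of class `lattice_spec` with fields `kind`,
#'   `neighbor_offsets` (a k x 3 integer matrix, k = 6 or 12) and
#'   `basis_matrix` (3 x 3).
#' @export
#' @examples
#' lattice_spec("cubic")
#' nrow(lattice_spec("fcc")$neighbor_offsets) # 12
lattice_spec <- function(kind = c("cubic", "fcc")) {
  kind <- match.arg(kind)
  if (kind == "cubic") {
    off <- cubic_offsets()
    basis <- diag(3)
  } else {
    off <- fcc_offsets()
    # unit-length primitive vectors with pairwise dot products 1/2
    basis <- cbind(c(1, 0, 0),
                   c(1 / 2, sqrt(3) / 2, 0),
                   c(1 / 2, sqrt(3) / 6, sqrt(6) / 3))
  }
  structure(list(kind = kind, neighbor_offsets = off, basis_matrix = basis),
            class = "lattice_spec")
}

as_lattice <- function(lattice) {
  if (inherits(lattice, "lattice_spec")) return(lattice)
  if (is.character(lattice) && length(lattice) == 1L)
    return(lattice_spec(lattice))
  stop("`lattice` must be a lattice_spec or one of \"cubic\", \"fcc\"")
}

is_fcc <- function(lattice) as_lattice(lattice)$kind == "fcc"

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf("<lattice_spec: %s, %d neighbour offsets>\n",
              x$kind, nrow(x$neighbor_offsets)))
  invisible(x)
}

check_point <- function(p, lattice, arg = "p") {
  if (!is.numeric(p) || length(p) != 3L || any(p != round(p)))
    stop(sprintf("`%s` must be an integer vector of length 3", arg))
  if (is_fcc(lattice) && sum(p) %% 2 != 0)
    stop(sprintf("`%s` is not an FCC lattice point: coordinate sum %d is odd",
                 arg, sum(p)))
  as.integer(p)
}

#' Lattice adjacency predicate
#'
#' Two cubic points are adjacent when their coordinate deltas sum to 1 in
#' absolute value; two FCC points when each delta is at most 1 in absolute
#' value and the deltas sum to 2. FCC points must have even coordinate sum.
#'
#' @param p,q Integer coordinate vectors of length 3.
#' @param lattice A [lattice_spec()] or lattice name.
#' @return Logical scalar; symmetric in `p` and `q`.
#' @export
#' @examples
#' are_adjacent(c(0, 0, 0), c(1, 0, 0), "cubic") # TRUE
#' are_adjacent(c(0, 0, 0), c(1, 1, 0), "fcc")   # TRUE
are_adjacent <- function(p, q, lattice) {
  lattice <- as_lattice(lattice)
  p <- check_point(p, lattice, "p")
  q <- check_point(q, lattice, "q")
  d <- abs(p - q)
  if (lattice$kind == "fcc") all(d <= 1L) && sum(d) == 2L else sum(d) == 1L
}

#' Neighbours of a lattice point
#'
#' @inheritParams are_adjacent
#' @return An integer matrix with one neighbour per row (6 rows cubic,
#'   12 rows FCC).
#' @export
#' @examples
#' nrow(lattice_neighbors(c(0, 0, 0), "cubic")) # 6
lattice_neighbors <- function(p, lattice) {
  lattice <- as_lattice(lattice)
  p <- check_point(p, lattice, "p")
  sweep(lattice$neighbor_offsets, 2, p, "+")
}

# --- conformations ----------------------------------------------------------

#' Construct a lattice conformation
#'
#' A conformation is a residue sequence embedded as a self-avoiding walk:
#' coordinates are pairwise distinct and consecutive residues occupy
#' adjacent lattice nodes. Sequences are normalised to lower case.
#'
#' @param sequence Single string over the h/p alphabet or the 20 one-letter
#'   amino-acid codes.
#' @param coords Integer matrix, one row per residue, columns x, y, z.
#' @param lattice A [lattice_spec()] or lattice name.
#' @param validate Check the self-avoiding-walk invariants (default `TRUE`).
#' @return An object of class `conformation`.
#' @export
#' @examples
#' sq <- conformation("hhhh", rbind(c(0, 0, 0), c(1, 0, 0),
#'                                  c(1, 1, 0), c(0, 1, 0)), "cubic")
#' contacts(sq)
conformation <- function(sequence, coords, lattice, validate = TRUE) {
  lattice <- as_lattice(lattice)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  sequence <- tolower(sequence)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (ncol(coords) != 3L)
    stop("`coords` must have 3 columns (x, y, z)")
  if (nrow(coords) != nchar(sequence))
    stop(sprintf("sequence length %d does not match %d coordinate rows",
                 nchar(sequence), nrow(coords)))
  dimnames(coords) <- NULL
  conf <- structure(list(sequence = sequence, coords = coords,
                         lattice = lattice),
                    class = "conformation")
  if (validate) validate_conformation(conf)
  conf
}

#' Validate a conformation's invariants
#'
#' Errors naming the violated invariant (duplicate site, broken chain bond,
#' or FCC parity) and the offending residue index; returns the conformation
#' invisibly when valid.
#'
#' @param conf A [conformation()].
#' @export
validate_conformation <- function(conf) {
  stopifnot(inherits(conf, "conformation"))
  v <- cpp_validate(conf$coords, is_fcc(conf$lattice))
  if (v[1] == 1L)
    stop(sprintf("self-avoidance violated: residue %d occupies a duplicated site", v[2]))
  if (v[1] == 2L)
    stop(sprintf("chain connectivity violated: residues %d and %d are not lattice-adjacent",
                 v[2], v[2] + 1L))
  if (v[1] == 3L)
    stop(sprintf("FCC parity violated: residue %d has odd coordinate sum", v[2]))
  invisible(conf)
}

#' Test a conformation without raising an error
#' @param conf A [conformation()].
#' @return Logical scalar.
#' @export
is_valid_conformation <- function(conf) {
  inherits(conf, "conformation") &&
    cpp_validate(conf$coords, is_fcc(conf$lattice))[1] == 0L
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation: %d residues on the %s lattice>\n",
              nrow(x$coords), x$lattice$kind))
  cat(" sequence:", x$sequence, "\n")
  invisible(x)
}

#' Non-consecutive lattice contacts of a conformation
#'
#' A contact is a pair of residues occupying adjacent lattice nodes that are
#' not consecutive in the chain.
#'
#' @param conf A valid [conformation()].
#' @return Integer matrix of 1-based index pairs (i, j), i < j; zero rows if
#'   there are no contacts.
#' @export
contacts <- function(conf) {
  validate_conformation(conf)
  m <- cpp_contacts(conf$coords, is_fcc(conf$lattice))
  colnames(m) <- c("i", "j")
  m
}

#' Random self-avoiding walk for a sequence
#'
#' Grows a walk from the origin, choosing uniformly among unoccupied
#' neighbour sites; a dead-ended walk is restarted (the growth distribution
#' is therefore not uniform over all walks, which the search does not
#' require). Driven by R's global RNG: call `set.seed()` for reproducibility.
#'
#' @param sequence Residue string.
#' @param lattice A [lattice_spec()] or lattice name.
#' @param max_restarts Retry budget for dead-ended growth (default 1000).
#' @return A valid [conformation()] anchored at the origin.
#' @export
#' @examples
#' set.seed(1)
#' random_self_avoiding_walk("hphp", "cubic")
random_self_avoiding_walk <- function(sequence, lattice, max_restarts = 1000L) {
  lattice <- as_lattice(lattice)
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  m <- cpp_random_saw(nchar(sequence), is_fcc(lattice), as.integer(max_restarts))
  if (is.null(m))
    stop(sprintf("self-avoiding-walk generation failed after %d restarts",
                 max_restarts))
  conformation(sequence, m, lattice, validate = FALSE)
}

#' Exhaustively enumerate self-avoiding walks
#'
#' Yields every self-avoiding walk of `n` nodes starting at the origin. With
#' `canonical = TRUE` (default) the first step is fixed to the lattice's
#' first neighbour offset, quotienting the trivial first-bond symmetry so
#' each walk appears exactly once per symmetry class of that quotient.
#' Guarded: enumeration is refused above `max_n` (default 12 cubic, 8 FCC)
#' because the walk count grows exponentially.
#'
#' @param n Number of nodes (residues).
#' @param lattice A [lattice_spec()] or lattice name.
#' @param canonical Fix the first step (default `TRUE`).
#' @param max_n Guard limit override.
#' @return List of n x 3 integer coordinate matrices.
#' @export
#' @examples
#' length(enumerate_walks(2, "cubic", canonical = FALSE)) # 6
enumerate_walks <- function(n, lattice, canonical = TRUE, max_n = NULL) {
  lattice <- as_lattice(lattice)
  if (is.null(max_n)) max_n <- if (lattice$kind == "fcc") 8L else 12L
  if (n > max_n)
    stop(sprintf(paste0("refusing to enumerate walks of %d nodes on the %s ",
                        "lattice (guard limit %d); raise `max_n` only if you ",
                        "accept the exponential cost"), n, lattice$kind, max_n))
  stopifnot(n >= 1)
  cpp_enumerate_walks(as.integer(n), is_fcc(lattice), canonical)
}

#' Count self-avoiding walks without storing them
#' @inheritParams enumerate_walks
#' @return Walk count (double).
#' @export
count_walks <- function(n, lattice, canonical = TRUE, max_n = NULL) {
  lattice <- as_lattice(lattice)
  if (is.null(max_n)) max_n <- if (lattice$kind == "fcc") 8L else 12L
  if (n > max_n) stop("walk count refused above the guard limit")
  cpp_count_walks(as.integer(n), is_fcc(lattice), canonical)
}

# --- conformation I/O -------------------------------------------------------

#' Write a conformation as a tab-separated coordinate table
#'
#' The header line carries the lattice kind; columns are index, residue,
#' x, y, z. Round-trips through [read_conformation()] bit-exactly.
#'
#' @param conf A [conformation()].
#' @param path Output file path.
#' @export
write_conformation <- function(conf, path) {
  validate_conformation(conf)
  res <- strsplit(conf$sequence, "")[[1]]
  lines <- c(sprintf("# lattice: %s", conf$lattice$kind),
             "index\tresidue\tx\ty\tz",
             sprintf("%d\t%s\t%d\t%d\t%d", seq_along(res), res,
                     conf$coords[, 1], conf$coords[, 2], conf$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a conformation written by [write_conformation()]
#'
#' @param path Input file path.
#' @return A validated [conformation()].
#' @export
read_conformation <- function(path) {
  lines <- readLines(path)
  header <- grep("^# lattice:", lines, value = TRUE)
  if (length(header) != 1L)
    stop("missing '# lattice:' header line in conformation file")
  kind <- trimws(sub("^# lattice:", "", header))
  body <- lines[!startsWith(lines, "#")]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           colClasses = c("integer", "character", "integer",
                                          "integer", "integer"))
  tab <- tab[order(tab$index), , drop = FALSE]
  conformation(paste(tab$residue, collapse = ""),
               as.matrix(tab[, c("x", "y", "z")]), kind)
}

#' Export FCC conformation coordinates to Cartesian space
#'
#' Maps the integer FCC representation onto the lattice's unit-length
#' primitive basis (write-only, for visualisation); nearest neighbours come
#' out at Euclidean distance 1.
#'
#' @param conf A [conformation()] on the FCC lattice.
#' @return Numeric n x 3 matrix of Cartesian coordinates.
#' @export
fcc_to_cartesian <- function(conf) {
  validate_conformation(conf)
  if (conf$lattice$kind != "fcc")
    stop("Cartesian export is defined for FCC conformations")
  xyz <- conf$coords
  # integer rep -> primitive-cell coefficients (a,b,c); all integral because
  # coordinate sums are even
  a <- (xyz[, 1] + xyz[, 2] - xyz[, 3]) / 2
  b <- (xyz[, 1] - xyz[, 2] + xyz[, 3]) / 2
  cc <- (-xyz[, 1] + xyz[, 2] + xyz[, 3]) / 2
  t(conf$lattice$basis_matrix %*% rbind(a, b, cc))
}
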