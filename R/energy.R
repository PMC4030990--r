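# Energy models: HP100 and pairwise contact-matrix scoring.

AA20 <- strsplit("acdefghiklmnpqrstvwy", "")[[1]]

#' Construct a contact-energy matrix
#'
#' A symmetric matrix of pairwise contact energies keyed by residue letter.
#' The standard use is the 20-letter amino-acid alphabet, but any alphabet
#' is accepted (the two-letter h/p matrix used in tests exercises the
#' HP-equivalence identity).
#'
#' @param entries Square numeric matrix with identical row and column names
#'   (single letters).
#' @param name Label carried along for reporting.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(entries, name = "custom") {
  entries <- as.matrix(entries)
  if (nrow(entries) != ncol(entries))
    stop("contact matrix must be square")
  rn <- tolower(rownames(entries)); cn <- tolower(colnames(entries))
  if (is.null(rn) || is.null(cn) || !identical(rn, cn))
    stop("contact matrix must have identical row and column letter labels")
  if (anyNA(entries))
    stop("contact matrix contains missing values")
  if (max(abs(entries - t(entries))) > 1e-12)
    stop("contact matrix is not symmetric within 1e-12")
  dimnames(entries) <- list(rn, cn)
  structure(entries, name = name, class = c("contact_matrix", "matrix"))
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix '%s': %d x %d>\n", attr(x, "name"),
              nrow(x), ncol(x)))
  invisible(x)
}

#' Load a contact matrix from a delimited text file
#'
#' The format is '#'-prefixed comment lines, one header row of residue
#' letters, then labelled rows containing either the full matrix or the
#' lower triangle (including the diagonal). Full matrices are verified
#' symmetric within 1e-12; lower triangles are mirrored. For the 20-letter
#' alphabet all 20 residues must be present.
#'
#' @param path File path.
#' @param name Label; defaults to the file name.
#' @return A [contact_matrix()].
#' @export
#' @examples
#' mj <- load_contact_matrix(system.file("extdata",
#'   "mjb_miyazawa_jernigan_1996.txt", package = "fireflyfold"))
#' mj["c", "c"]
load_contact_matrix <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) < 2L) stop("contact matrix file has no data rows")
  header <- tolower(strsplit(lines[1], "[[:space:],]+")[[1]])
  header <- header[nzchar(header)]
  k <- length(header)
  rows <- lines[-1]
  if (length(rows) != k)
    stop(sprintf("expected %d labelled rows after the header, found %d",
                 k, length(rows)))
  m <- matrix(NA_real_, k, k, dimnames = list(header, header))
  row_labels <- character(k)
  lower_only <- FALSE
  for (r in seq_len(k)) {
    parts <- strsplit(rows[r], "[[:space:],]+")[[1]]
    parts <- parts[nzchar(parts)]
    lab <- tolower(parts[1])
    row_labels[r] <- lab
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals))
      stop(sprintf("non-numeric cell in row '%s' (column %d)",
                   lab, which(is.na(vals))[1] + 1L))
    if (!(length(vals) %in% c(r, k)))
      stop(sprintf(
        "row '%s' has %d values; expected %d (lower triangle) or %d (full)",
        lab, length(vals), r, k))
    if (length(vals) < k) lower_only <- TRUE
    m[r, seq_along(vals)] <- vals
  }
  if (!setequal(row_labels, header) || anyDuplicated(row_labels))
    stop("row labels do not match the header letters")
  if (lower_only) {
    # triangular input presumes rows in header order
    if (!identical(row_labels, header))
      stop("lower-triangle input requires rows in header order")
    up <- t(m)[upper.tri(m)]
    m[upper.tri(m)] <- up
  } else if (!identical(row_labels, header)) {
    rownames(m) <- row_labels
    m <- m[header, , drop = FALSE]
  }
  if (!lower_only && max(abs(m - t(m))) > 1e-12) {
    bad <- which(abs(m - t(m)) > 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("asymmetry beyond 1e-12 at cell (%s, %s)",
                 header[bad[1]], header[bad[2]]))
  }
  if (anyNA(m)) stop("contact matrix has missing cells after mirroring")
  if (k == 20L && !setequal(header, AA20))
    stop("20-letter matrix does not cover the amino-acid alphabet")
  contact_matrix(m, name = name)
}

#' Packaged Miyazawa-Jernigan contact-energy matrix
#'
#' Loads the packaged transcription of the Miyazawa & Jernigan (1996)
#' Table 5 pairwise contact energies (the solvent-expulsion variant,
#' often called MJb; units of RT).
#'
#' @return A [contact_matrix()].
#' @export
mj_matrix <- function() {
  load_contact_matrix(system.file("extdata", "mjb_miyazawa_jernigan_1996.txt",
                                  package = "fireflyfold"),
                      name = "MJb")
}

#' Energy model
#'
#' Either the HP100 model (energy = minus the number of non-consecutive h-h
#' contacts; sequences over \{h, p\} only) or a pairwise contact-matrix model
#' (energy = sum of matrix entries over all non-consecutive contacts).
#'
#' @param kind `"hp"` or `"contact"`.
#' @param matrix A [contact_matrix()]; required for `kind = "contact"`.
#' @return An object of class `energy_model`.
#' @export
#' @examples
#' energy_model("hp")
energy_model <- function(kind = c("hp", "contact"), matrix = NULL) {
  kind <- match.arg(kind)
  if (kind == "contact") {
    if (is.null(matrix)) stop("contact model requires a contact matrix")
    stopifnot(inherits(matrix, "contact_matrix"))
  } else if (!is.null(matrix)) {
    stop("the HP100 model takes no contact matrix")
  }
  structure(list(kind = kind, matrix = matrix), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  if (x$kind == "hp") cat("<energy_model: HP100>\n")
  else cat(sprintf("<energy_model: contact matrix '%s'>\n",
                   attr(x$matrix, "name")))
  invisible(x)
}

check_alphabet <- function(sequence, model) {
  letters_ <- unique(strsplit(sequence, "")[[1]])
  if (model$kind == "hp") {
    bad <- setdiff(letters_, c("h", "p"))
    if (length(bad))
      stop(sprintf("HP100 accepts only h/p sequences; found '%s'",
                   paste(bad, collapse = "', '")))
  } else {
    bad <- setdiff(letters_, rownames(model$matrix))
    if (length(bad))
      stop(sprintf("residue '%s' is not in the contact-matrix alphabet",
                   paste(bad, collapse = "', '")))
  }
  invisible(TRUE)
}

# 0-based type indices into the model's matrix, for the C++ core.
# For HP the matrix is the 2x2 h/p equivalence matrix (-1 on (h,h)).
model_codes <- function(sequence, model) {
  if (model$kind == "hp") {
    emat <- matrix(c(-1, 0, 0, 0), 2, 2)
    types <- ifelse(strsplit(sequence, "")[[1]] == "h", 0L, 1L)
  } else {
    emat <- unclass(model$matrix)
    attr(emat, "name") <- NULL
    types <- match(strsplit(sequence, "")[[1]], rownames(model$matrix)) - 1L
  }
  list(types = types, emat = emat)
}

#' HP100 energy of a conformation
#'
#' Minus the number of contacts whose residues are both hydrophobic ('h').
#'
#' @param conf A valid [conformation()] with an h/p sequence.
#' @return Integer energy (always <= 0).
#' @export
#' @examples
#' sq <- conformation("hhhh", rbind(c(0, 0, 0), c(1, 0, 0),
#'                                  c(1, 1, 0), c(0, 1, 0)), "cubic")
#' hp_energy(sq) # -1
hp_energy <- function(conf) {
  validate_conformation(conf)
  check_alphabet(conf$sequence, energy_model("hp"))
  ish <- strsplit(conf$sequence, "")[[1]] == "h"
  -cpp_hh_contacts(conf$coords, is_fcc(conf$lattice), ish)
}

#' Pairwise contact-matrix energy of a conformation
#'
#' Sum of the matrix entries over all non-consecutive lattice contacts.
#'
#' @param conf A valid [conformation()].
#' @param matrix A [contact_matrix()] covering the sequence alphabet.
#' @return Numeric energy.
#' @export
contact_energy <- function(conf, matrix) {
  validate_conformation(conf)
  model <- energy_model("contact", matrix)
  check_alphabet(conf$sequence, model)
  mc <- model_codes(conf$sequence, model)
  cpp_contact_energy(conf$coords, is_fcc(conf$lattice), mc$types, mc$emat)
}

#' Evaluate a conformation under an energy model
#'
#' Dispatches to [hp_energy()] or [contact_energy()]; if `counters` (an
#' environment) is supplied, its `energy_evals` field is incremented by one,
#' which is how the package's evaluation accounting hooks in.
#'
#' @param conf A valid [conformation()].
#' @param model An [energy_model()].
#' @param counters Optional environment with a numeric `energy_evals` field.
#' @return Numeric energy.
#' @export
eval_energy <- function(conf, model, counters = NULL) {
  stopifnot(inherits(model, "energy_model"))
  e <- if (model$kind == "hp") hp_energy(conf)
       else contact_energy(conf, model$matrix)
  if (!is.null(counters))
    counters$energy_evals <- (counters$energy_evals %||% 0) + 1
  e
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fresh evaluation-counter environment
#' @return Environment with `energy_evals` initialised to 0.
#' @export
new_counters <- function() {
  e <- new.env(parent = emptyenv())
  e$energy_evals <- 0
  e
}

# --- sequence input ---------------------------------------------------------

#' Read sequences from FASTA or plain text
#'
#' FASTA files (first non-blank character '>') are parsed with seqinr;
#' otherwise each non-empty, non-comment line is one bare sequence.
#' Sequences are normalised to lower case. The h/p alphabet is auto-detected.
#'
#' @param path File path.
#' @return Named character vector of sequences with a logical `is_hp`
#'   attribute.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path)
  first <- lines[nzchar(trimws(lines))][1]
  if (!is.na(first) && startsWith(trimws(first), ">")) {
    fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
    seqs <- tolower(vapply(fa, function(s) as.character(s)[1], ""))
    names(seqs) <- names(fa)
  } else {
    keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
    seqs <- tolower(trimws(lines[keep]))
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  attr(seqs, "is_hp") <- vapply(
    seqs, function(s) all(strsplit(s, "")[[1]] %in% c("h", "p")), TRUE)
  seqs
}
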