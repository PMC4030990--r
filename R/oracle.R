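# Exhaustive ground-truth optimum for short chains.

#' Exact minimum energy by exhaustive enumeration
#'
#' Walks every self-avoiding conformation of the sequence (with the first
#' step fixed; the energy is invariant under lattice symmetries) and
#' returns the exact minimum energy with one witness conformation. Refused
#' above the walk-enumeration guard limit (12 nodes cubic, 8 FCC by
#' default) because the conformation count grows exponentially.
#'
#' @param sequence Residue string.
#' @param lattice A [lattice_spec()] or lattice name.
#' @param model An [energy_model()].
#' @param max_n Guard limit override.
#' @return List with `min_energy` and `witness` (a [conformation()]).
#' @export
#' @examples
#' enumerate_min_energy("hhhh", "cubic", energy_model("hp"))$min_energy # -1
enumerate_min_energy <- function(sequence, lattice, model, max_n = NULL) {
  lattice <- as_lattice(lattice)
  stopifnot(inherits(model, "energy_model"))
  sequence <- tolower(sequence)
  check_alphabet(sequence, model)
  n <- nchar(sequence)
  if (is.null(max_n)) max_n <- if (lattice$kind == "fcc") 8L else 12L
  if (n > max_n)
    stop(sprintf(paste0("refusing to enumerate conformations of %d residues ",
                        "on the %s lattice (guard limit %d)"),
                 n, lattice$kind, max_n))
  mc <- model_codes(sequence, model)
  res <- cpp_enum_min_energy(as.integer(n), is_fcc(lattice), mc$types, mc$emat)
  list(min_energy = res$min_energy,
       witness = conformation(sequence, res$witness, lattice,
                              validate = FALSE))
}
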