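# Pull-move neighbourhood: enumeration, application, reversal, descent.
#
# A pull move relocates an anchor residue to a free target site; when the
# chain bond cannot be kept with a single relocation, the adjacent residue
# in the pull direction moves to an auxiliary bridge site and the remaining
# residues are pulled along previously occupied sites until the chain
# reconnects. Both chain ends can additionally initiate "end drags": the
# end residue jumps to any free site reachable through a bridge site
# adjacent to its old position, dragging the chain after it. The end drags
# are what make the move set reversible (the reverse of a pull that
# propagates to a chain end is itself an end drag); reversibility and a
# completeness spot-check are verified exhaustively in the test suite.

move_from_row <- function(row) {
  structure(list(
    anchor_index = row[1] + 1L,
    direction = if (row[2] == 0L) "toward_head" else "toward_tail",
    target = row[3:5],
    auxiliary = if (row[6] == 1L) row[7:9] else NULL,
    affected_range = c(row[10] + 1L, row[11] + 1L)
  ), class = "pull_move")
}

move_to_row <- function(move) {
  stopifnot(inherits(move, "pull_move"))
  as.integer(c(move$anchor_index - 1L,
               if (move$direction == "toward_head") 0L else 1L,
               move$target,
               if (is.null(move$auxiliary)) c(0L, 0L, 0L, 0L)
               else c(1L, move$auxiliary),
               move$affected_range - 1L))
}

#' @export
print.pull_move <- function(x, ...) {
  cat(sprintf("<pull_move: anchor %d %s -> (%s)%s, affects [%d, %d]>\n",
              x$anchor_index, x$direction,
              paste(x$target, collapse = ","),
              if (is.null(x$auxiliary)) ""
              else sprintf(" via (%s)", paste(x$auxiliary, collapse = ",")),
              x$affected_range[1], x$affected_range[2]))
  invisible(x)
}

#' Enumerate all legal pull moves of a conformation
#'
#' Returns every legal pull move in a deterministic order (sorted by anchor
#' index, direction, then target and auxiliary coordinates) so that seeded
#' runs are reproducible. Applying any returned move yields a valid
#' conformation. A length-1 chain has no moves (documented convention).
#'
#' @param conf A valid [conformation()].
#' @return List of `pull_move` objects; fields `anchor_index`, `direction`,
#'   `target`, `auxiliary` (or `NULL`), `affected_range` (1-based inclusive).
#' @export
enumerate_pull_moves <- function(conf) {
  validate_conformation(conf)
  m <- cpp_enum_moves(conf$coords, is_fcc(conf$lattice))
  lapply(seq_len(nrow(m)), function(r) move_from_row(m[r, ]))
}

#' Apply a pull move to a conformation
#'
#' The move is validated against the current conformation before
#' application: a stale or illegal move (occupied target, changed geometry)
#' raises an error and leaves `conf` untouched. Residues outside the
#' affected range keep their coordinates.
#'
#' @param conf A valid [conformation()].
#' @param move A `pull_move` from [enumerate_pull_moves()].
#' @return The new [conformation()], with attribute `affected_range`.
#' @export
apply_pull_move <- function(conf, move) {
  validate_conformation(conf)
  res <- cpp_apply_move(conf$coords, is_fcc(conf$lattice), move_to_row(move))
  if (is.null(res))
    stop("illegal or stale pull move: not in the conformation's current move set")
  out <- conformation(conf$sequence, res$coords, conf$lattice,
                      validate = FALSE)
  attr(out, "affected_range") <- c(res$lo, res$hi)
  out
}

#' Greedy pull-move descent to a local minimum
#'
#' Repeatedly evaluates every legal pull move and applies one chosen
#' uniformly at random among those that strictly lower the energy, until no
#' strictly improving move exists. Every energy evaluation (the starting
#' conformation plus one per candidate per sweep) is counted; with a
#' `counters` environment the count feeds the search's initialisation-stage
#' accounting. Termination is guaranteed because the energy strictly
#' decreases over a finite conformation set.
#'
#' @param conf A valid [conformation()].
#' @param model An [energy_model()].
#' @param counters Optional environment; `energy_evals` is incremented by
#'   the number of evaluations performed.
#' @return The descended [conformation()], with attributes `energy` and
#'   `evals`.
#' @export
#' @examples
#' set.seed(1)
#' line <- conformation("hhhh", cbind(0:3, 0L, 0L), "cubic")
#' attr(greedy_descent(line, energy_model("hp")), "energy") # -1
greedy_descent <- function(conf, model, counters = NULL) {
  validate_conformation(conf)
  stopifnot(inherits(model, "energy_model"))
  check_alphabet(conf$sequence, model)
  mc <- model_codes(conf$sequence, model)
  res <- cpp_greedy_descent(conf$coords, is_fcc(conf$lattice),
                            mc$types, mc$emat)
  if (!is.null(counters))
    counters$energy_evals <- (counters$energy_evals %||% 0) + res$evals
  out <- conformation(conf$sequence, res$coords, conf$lattice,
                      validate = FALSE)
  attr(out, "energy") <- res$energy
  attr(out, "evals") <- res$evals
  out
}
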