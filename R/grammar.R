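#' Stochastic context-free grammar parameters
#'
#' Builds the parameter table of the nested structure grammar used by the
#' sampler. The grammar has a single non-terminal family generating
#' unpaired emissions, pair-enclosing emissions and bifurcations; a
#' structure's weight is
#' \deqn{q_u^{\#unpaired} \cdot w_{init}^{\#helices} \prod_{(i,j)}
#'       w_{pair}(i,j) \cdot w_{stack}^{\#stacked}}
#' where a pair counts as stacked when the pair immediately outside it,
#' \eqn{(i-1, j+1)}, is also present, and a helix is a maximal run of
#' directly nested pairs. Only the six canonical pair types
#' (AU, UA, CG, GC, GU, UG) carry positive weight; all other base
#' combinations have weight zero and can never pair.
#'
#' The defaults favour long stacked canonical helices the way real RNA
#' thermodynamics does, through two opposing terms: `init_penalty` is a
#' helix-nucleation cost paid once per helix, while the stacking bonus
#' rewards contiguous stacking, so the net per-pair extension factor of a
#' growing helix is `pair_weight * stack_bonus` (about 2-4 for canonical
#' pairs, about 1 for wobble pairs). Short isolated helices are therefore
#' barely worth opening, whereas long helices dominate -- which is what
#' makes sparse per-molecule single-strandedness constraints decisive
#' between competing folds. These are deliberately simple, documented
#' weights, not trained parameters, and every entry can be overridden or
#' loaded from a YAML file with [read_grammar()].
#'
#' @param pair_weights named numeric vector with entries `AU`, `UA`, `CG`,
#'   `GC`, `GU`, `UG`; non-negative linear weights.
#' @param unpaired_weight positive weight of an unpaired base.
#' @param stack_bonus multiplicative bonus (> 0) for a pair stacked directly
#'   on its enclosing pair.
#' @param init_penalty multiplicative cost (> 0, normally << 1) paid once
#'   per helix for opening it.
#' @param min_hairpin minimum number of unpaired bases in a hairpin loop
#'   (at least 2; default 3, the steric minimum).
#' @return An object of class `scfg_grammar`.
#' @examples
#' g <- scfg_grammar()
#' g$pair_weights
#' @export
scfg_grammar <- function(pair_weights = c(AU = 1.25, UA = 1.25, CG = 2,
                                          GC = 2, GU = 0.5, UG = 0.5),
                         unpaired_weight = 1,
                         stack_bonus = 2,
                         init_penalty = 0.002,
                         min_hairpin = 3) {
  needed <- c("AU", "UA", "CG", "GC", "GU", "UG")
  if (!all(needed %in% names(pair_weights)))
    .stopf("pair_weights must name all of: %s", paste(needed, collapse = ", "))
  pair_weights <- pair_weights[needed]
  if (any(!is.finite(pair_weights)) || any(pair_weights < 0))
    .stopf("pair weights must be finite and >= 0")
  if (!is.finite(unpaired_weight) || unpaired_weight <= 0)
    .stopf("unpaired_weight must be > 0")
  if (!is.finite(stack_bonus) || stack_bonus <= 0)
    .stopf("stack_bonus must be > 0")
  if (!is.finite(init_penalty) || init_penalty <= 0)
    .stopf("init_penalty must be > 0")
  if (!.is_count(min_hairpin) || min_hairpin < 2)
    .stopf("min_hairpin must be an integer >= 2 (the grammar cannot close a 1-base hairpin loop)")
  structure(
    list(pair_weights = pair_weights,
         unpaired_weight = unpaired_weight,
         stack_bonus = stack_bonus,
         init_penalty = init_penalty,
         min_hairpin = as.integer(min_hairpin)),
    class = "scfg_grammar")
}

#' @export
print.scfg_grammar <- function(x, ...) {
  cat("SCFG grammar parameters\n")
  cat("  pair weights:   ",
      paste(sprintf("%s=%g", names(x$pair_weights), x$pair_weights),
            collapse = " "), "\n")
  cat("  unpaired weight:", x$unpaired_weight, "\n")
  cat("  stack bonus:    ", x$stack_bonus, "\n")
  cat("  init penalty:   ", x$init_penalty, "\n")
  cat("  min hairpin:    ", x$min_hairpin, "\n")
  invisible(x)
}

# 5x5 linear pair-weight matrix over A,C,G,U,N for the C++ engine
.pair_matrix <- function(grammar) {
  m <- matrix(0, 5, 5, dimnames = list(c("A", "C", "G", "U", "N"),
                                       c("A", "C", "G", "U", "N")))
  pw <- grammar$pair_weights
  m["A", "U"] <- pw[["AU"]]; m["U", "A"] <- pw[["UA"]]
  m["C", "G"] <- pw[["CG"]]; m["G", "C"] <- pw[["GC"]]
  m["G", "U"] <- pw[["GU"]]; m["U", "G"] <- pw[["UG"]]
  m
}

#' Read or write grammar parameters as YAML
#'
#' @param path file path.
#' @return `read_grammar()` returns an `scfg_grammar`; `write_grammar()`
#'   returns `path` invisibly.
#' @export
read_grammar <- function(path) {
  y <- yaml::read_yaml(path)
  scfg_grammar(pair_weights = unlist(y$pair_weights),
               unpaired_weight = y$unpaired_weight,
               stack_bonus = y$stack_bonus,
               init_penalty = y$init_penalty,
               min_hairpin = y$min_hairpin)
}

#' @param grammar an `scfg_grammar` object.
#' @rdname read_grammar
#' @export
write_grammar <- function(grammar, path) {
  stopifnot(inherits(grammar, "scfg_grammar"))
  yaml::write_yaml(list(pair_weights = as.list(grammar$pair_weights),
                        unpaired_weight = grammar$unpaired_weight,
                        stack_bonus = grammar$stack_bonus,
                        init_penalty = grammar$init_penalty,
                        min_hairpin = grammar$min_hairpin),
                   path)
  invisible(path)
}
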