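# Propositional layer: the sixteen propositions of the inference framework.
#
#   P1  C2/C1 < 1 (gradient into the cell, internalization exists)
#   P2  C2/C1 > 1 (externalization exists)
#   P3  C2/C1 = 1 (partial balance)
#   P4  C3 has reached the binding capacity C0
#   P5, P6, P7    non-decrease of C1, C2, C3 between two times
#   P8  IN >= AS;  P9  EX <= DIS;  P10 EX >= ECT-;  P11 IN <= ECT+
#   P12 net association exists; P13 net dissociation exists
#   P14, P15, P16 non-decrease of C2/C1, C3/C1, C3/C2
#
# Structural axioms tie the ratio trends to the field trends and the field
# trends to the mechanism-rate comparisons; exclusivity axioms encode that
# opposing mechanisms cannot both be net-present in one representative cell.

prop_names <- paste0("P", 1:16)

.bool_cache <- new.env(parent = emptyenv())

# All 2^16 assignments as a data.frame of logicals (built once).
all_assignments <- function() {
  if (is.null(.bool_cache$M)) {
    g <- do.call(expand.grid, stats::setNames(
      rep(list(c(FALSE, TRUE)), 16), prop_names))
    .bool_cache$M <- g
  }
  .bool_cache$M
}

# Evaluate a formula string over P1..P16 on an assignment data.frame.
# Supported connectives: !, &, |, xor(a,b), implies(a,b), iff(a,b),
# TRUE/FALSE literals and parentheses.
eval_formula <- function(formula, assignments) {
  env <- list2env(assignments, parent = baseenv())
  assign("implies", function(a, b) !a | b, envir = env)
  assign("iff", function(a, b) a == b, envir = env)
  assign("xor", function(a, b) base::xor(a, b), envir = env)
  v <- eval(parse(text = formula)[[1]], envir = env)
  if (length(v) == 1) v <- rep(v, nrow(assignments))
  stop_if(!is.logical(v) || length(v) != nrow(assignments),
          "malformed formula: ", formula)
  v
}

#' Structural and exclusivity axioms of the inference framework
#'
#' The axioms connect the trend propositions: the mechanism-rate comparisons
#' determine the field trends (`xor(P8,P9) <-> P6`, `xor(P10,P11) <-> P5`,
#' `P12 <-> P7`), a field-pair trend in the informative direction determines
#' the ratio trend (both sufficiency families, e.g. `P6 & !P5 -> P14` and
#' `!P6 & P5 -> !P14`), exactly one transmembrane direction holds, net
#' association and dissociation exclude each other, and saturation of the
#' binding sites suppresses association.
#'
#' @return Character vector of axiom formulas.
#' @export
rtm_axioms <- function() {
  c(# transmembrane direction: exactly one of P1, P2, P3
    "(P1 | P2 | P3) & !(P1 & P2) & !(P1 & P3) & !(P2 & P3)",
    # net association vs dissociation are mutually exclusive
    "!(P12 & P13)",
    # saturated binding sites inhibit association
    "implies(P4, !P12)",
    # mechanism-rate comparisons <-> field trends
    "iff(P12, P7)",
    "iff(xor(P8, P9), P6)",
    "iff(xor(P10, P11), P5)",
    # field trends -> ratio trends (both sufficiency families)
    "implies(P6 & !P5, P14)", "implies(!P6 & P5, !P14)",
    "implies(P7 & !P5, P15)", "implies(!P7 & P5, !P15)",
    "implies(P7 & !P6, P16)", "implies(!P7 & P6, !P16)")
}

# Assignments satisfying all axioms (cached).
axiom_models <- function() {
  if (is.null(.bool_cache$models)) {
    M <- all_assignments()
    keep <- rep(TRUE, nrow(M))
    for (ax in rtm_axioms()) keep <- keep & eval_formula(ax, M)
    .bool_cache$models <- M[keep, , drop = FALSE]
  }
  .bool_cache$models
}

#' Certify a propositional derivation by exhaustive enumeration
#'
#' Enumerates every truth assignment of `P1..P16` consistent with the
#' framework axioms ([rtm_axioms()]) and checks that the conclusion holds in
#' every model of the premises.  This is the derivation-free oracle used to
#' certify the printed inference chains and the scenario-table conclusions.
#'
#' @param premises Character vector of formula strings (may be empty).
#' @param conclusion Formula string.
#' @param use_axioms Restrict the enumeration to axiom-consistent
#'   assignments (default) or run over the full assignment space.
#' @return List with `valid` (logical), `n_premise_models` (number of
#'   axiom-consistent assignments satisfying the premises) and
#'   `counterexample` (first violating assignment as a named logical vector,
#'   or `NULL`).
#' @export
verify_by_truth_table <- function(premises, conclusion, use_axioms = TRUE) {
  M <- if (use_axioms) axiom_models() else all_assignments()
  keep <- rep(TRUE, nrow(M))
  for (p in premises) keep <- keep & eval_formula(p, M)
  Mp <- M[keep, , drop = FALSE]
  ok <- eval_formula(conclusion, Mp)
  bad <- which(!ok)
  list(valid = length(bad) == 0,
       n_premise_models = nrow(Mp),
       counterexample = if (length(bad)) unlist(Mp[bad[1], ]) else NULL)
}

#' The printed inference chain for the rising-ratio / falling-C3/C2 scenario
#'
#' The derivation steps that take the framework from the trend axioms to the
#' conclusion "internalization dominates positive extracellular transport"
#' when `C2/C1` and `C3/C1` rise, `C3/C2` falls, net dissociation holds and
#' the transmembrane direction is inward.  Each step is a
#' premises/conclusion pair certifiable with [verify_by_truth_table()].
#'
#' @return Data frame with columns `step`, `premises` (list column),
#'   `conclusion`.
#' @export
derivation_chain <- function() {
  steps <- list(
    list("transposition of the C3/C2 sufficiency",
         character(0), "implies(!P16, !P7 | P6)"),
    list("substituted C3/C2 transposition",
         character(0), "implies(!P16, !P12 | xor(P8, P9))"),
    list("C2/C1 trend implication",
         character(0), "implies(P14, xor(P8, P9) | !xor(P10, P11))"),
    list("C3/C1 trend implication",
         character(0), "implies(P15, P12 | !xor(P10, P11))"),
    list("conjunction of the three instantiated implications",
         c("P14", "P15", "!P16"),
         paste("(xor(P8, P9) | !xor(P10, P11)) &",
               "(P12 | !xor(P10, P11)) & (!P12 | xor(P8, P9))")),
    list("dissociation collapses the exclusive disjunction",
         c("P14", "P15", "!P16", "!P12", "!P8"),
         "!xor(P10, P11)"),
    list("inward transmembrane direction removes P10",
         c("P14", "P15", "!P16", "!P12", "!P8", "!P10"),
         "!P11"))
  data.frame(step = vapply(steps, `[[`, "", 1),
             premises = I(lapply(steps, `[[`, 2)),
             conclusion = vapply(steps, `[[`, "", 3))
}
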