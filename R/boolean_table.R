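# Scenario table of the inference framework: for each of the 8 ratio-trend
# rows x {association, dissociation} x {inward, outward, balanced}
# transmembrane direction, the mechanism conclusion.  The table is data; the
# enumeration oracle recomputes every cell independently (see
# verify_scenario_table).

#' Transmembrane transport direction from the concentration ratio
#'
#' `IN` when `C2/C1 < 1 - tol` (gradient into the cell), `EX` when
#' `C2/C1 > 1 + tol`, `EQ` (partial balance) otherwise.  Scale-invariant in
#' the two concentrations.
#'
#' @param ratio_C2C1 Ratio value(s), >= 0.
#' @param tol Balance tolerance (dimensionless).
#' @return Character vector in `{"IN", "EX", "EQ"}`.
#' @export
tmt_direction <- function(ratio_C2C1, tol = 1e-9) {
  if (any(ratio_C2C1 < 0)) stop("ratio must be non-negative", call. = FALSE)
  out <- rep("EQ", length(ratio_C2C1))
  out[ratio_C2C1 < 1 - tol] <- "IN"
  out[ratio_C2C1 > 1 + tol] <- "EX"
  out
}

# Per-row general conclusion formulas (after the reaction split), exactly as
# printed in the framework's scenario table.  X-of-the-derivation is already
# collapsed: under association the exclusive disjunction xor(P8,P9) reduces
# to P8, under dissociation to P9.
branch_formulas <- function() {
  f <- c(
    "III|AS" = "P8 | !xor(P10, P11)",
    "III|DIS" = "!xor(P10, P11) & !P9",
    "IID|AS" = "P8",
    "IID|DIS" = "!xor(P10, P11)",
    "IDI|AS" = "iff(P8, xor(P10, P11))",
    "IDI|DIS" = "iff(P9, xor(P10, P11))",
    "IDD|AS" = "P8 & xor(P10, P11)",
    "IDD|DIS" = "P9 | !xor(P10, P11)",
    "DII|AS" = "!P8 | xor(P10, P11)",
    "DII|DIS" = "!P9 & !xor(P10, P11)",
    "DID|AS" = "iff(P8, xor(P10, P11))",
    "DID|DIS" = "iff(P9, xor(P10, P11))",
    "DDI|AS" = "!P8 | xor(P10, P11)",
    "DDI|DIS" = "!P9 | xor(P10, P11)",
    "DDD|AS" = "P8 & xor(P10, P11)",
    "DDD|DIS" = "!P9 | xor(P10, P11)")
  f
}

# Mechanism-existence substitutions applied to a branch formula for a given
# transmembrane direction: dominance claims about an absent mechanism are
# false, except "EX <= DIS", which holds vacuously when dissociation exists
# and externalization does not.
cell_substitution <- function(reaction, tmt) {
  sub <- list()
  if (reaction == "AS") sub$P9 <- FALSE else sub$P8 <- FALSE
  if (tmt == "IN") {
    sub$P10 <- FALSE
    if (reaction == "DIS") sub$P9 <- TRUE
  } else if (tmt == "EX") {
    sub$P11 <- FALSE
    sub$P8 <- FALSE
  } else {
    sub$P10 <- FALSE; sub$P11 <- FALSE; sub$P8 <- FALSE
    sub$P9 <- reaction == "DIS"
  }
  sub
}

# Formula rendering of each conclusion label over the dominance propositions.
label_formulas <- function() {
  c(IN_GE_AS = "P8", IN_LE_AS = "!P8",
    IN_GE_ECTp = "!P11", IN_LE_ECTp = "P11",
    IN_GE_AS_or_IN_GE_ECTp = "P8 | !P11",
    IN_LE_AS_or_IN_LE_ECTp = "!P8 | P11",
    IN_GE_AS_and_IN_LE_ECTp = "P8 & P11",
    IN_GE_AS_iff_IN_LE_ECTp = "iff(P8, P11)",
    EX_LE_ECTm = "!P10", EX_GE_ECTm = "P10",
    EX_LE_DIS = "P9", EX_GE_DIS = "!P9",
    EX_LE_ECTm_and_EX_GE_DIS = "!P10 & !P9",
    EX_LE_DIS_or_EX_LE_ECTm = "P9 | !P10",
    EX_GE_DIS_or_EX_GE_ECTm = "!P9 | P10",
    EX_LE_DIS_iff_EX_GE_ECTm = "iff(P9, P10)",
    TAUTOLOGY = "TRUE", CONTRADICTION = "FALSE")
}

#' The 48-cell scenario conclusion table
#'
#' One row per combination of the three ratio trends (I/D for `C2/C1`,
#' `C3/C1`, `C3/C2`), the net reaction (AS/DIS, read off the `C3` trend) and
#' the transmembrane direction (IN/EX/EQ, read off the later `C2/C1` level).
#' `label` is the cell conclusion; `refine_I`/`refine_D` are the sharper
#' conclusions available when the `C1` trend (non-decreasing / decreasing)
#' is known, where the table states one.
#'
#' @return Data frame with 48 rows.
#' @export
scenario_table <- function() {
  L <- function(t21, t31, t32, reaction, tmt, label,
                refine_I = NA_character_, refine_D = NA_character_) {
    data.frame(t21 = t21, t31 = t31, t32 = t32, reaction = reaction,
               tmt = tmt, label = label, refine_I = refine_I,
               refine_D = refine_D)
  }
  rows <- list(
    # (I, I, I)
    L("I","I","I","AS","IN","IN_GE_AS_or_IN_GE_ECTp", refine_I = "IN_GE_AS"),
    L("I","I","I","AS","EX","EX_LE_ECTm"),
    L("I","I","I","AS","EQ","TAUTOLOGY"),
    L("I","I","I","DIS","IN","CONTRADICTION"),
    L("I","I","I","DIS","EX","EX_LE_ECTm_and_EX_GE_DIS"),
    L("I","I","I","DIS","EQ","CONTRADICTION"),
    # (I, I, D)
    L("I","I","D","AS","IN","IN_GE_AS"),
    L("I","I","D","AS","EX","CONTRADICTION"),
    L("I","I","D","AS","EQ","CONTRADICTION"),
    L("I","I","D","DIS","IN","IN_GE_ECTp"),
    L("I","I","D","DIS","EX","EX_LE_ECTm"),
    L("I","I","D","DIS","EQ","TAUTOLOGY"),
    # (I, D, I)
    L("I","D","I","AS","IN","IN_GE_AS_iff_IN_LE_ECTp",
      refine_I = "IN_GE_AS", refine_D = "IN_LE_AS"),
    L("I","D","I","AS","EX","EX_LE_ECTm"),
    L("I","D","I","AS","EQ","TAUTOLOGY"),
    L("I","D","I","DIS","IN","IN_LE_ECTp"),
    L("I","D","I","DIS","EX","EX_LE_DIS_iff_EX_GE_ECTm",
      refine_I = "EX_LE_DIS", refine_D = "EX_GE_DIS"),
    L("I","D","I","DIS","EQ","CONTRADICTION"),
    # (I, D, D)
    L("I","D","D","AS","IN","IN_GE_AS_and_IN_LE_ECTp"),
    L("I","D","D","AS","EX","CONTRADICTION"),
    L("I","D","D","AS","EQ","CONTRADICTION"),
    L("I","D","D","DIS","IN","TAUTOLOGY"),
    L("I","D","D","DIS","EX","EX_LE_DIS_or_EX_LE_ECTm",
      refine_I = "EX_LE_DIS"),
    L("I","D","D","DIS","EQ","TAUTOLOGY"),
    # (D, I, I)
    L("D","I","I","AS","IN","IN_LE_AS_or_IN_LE_ECTp", refine_D = "IN_LE_AS"),
    L("D","I","I","AS","EX","TAUTOLOGY"),
    L("D","I","I","AS","EQ","TAUTOLOGY"),
    L("D","I","I","DIS","IN","CONTRADICTION"),
    L("D","I","I","DIS","EX","EX_LE_ECTm_and_EX_GE_DIS"),
    L("D","I","I","DIS","EQ","CONTRADICTION"),
    # (D, I, D)
    L("D","I","D","AS","IN","IN_GE_AS_iff_IN_LE_ECTp",
      refine_I = "IN_GE_AS", refine_D = "IN_LE_AS"),
    L("D","I","D","AS","EX","EX_LE_ECTm"),
    L("D","I","D","AS","EQ","TAUTOLOGY"),
    L("D","I","D","DIS","IN","IN_LE_ECTp"),
    L("D","I","D","DIS","EX","EX_LE_DIS_iff_EX_GE_ECTm",
      refine_I = "EX_LE_DIS", refine_D = "EX_GE_DIS"),
    L("D","I","D","DIS","EQ","CONTRADICTION"),
    # (D, D, I)
    L("D","D","I","AS","IN","IN_LE_AS_or_IN_LE_ECTp", refine_D = "IN_LE_AS"),
    L("D","D","I","AS","EX","TAUTOLOGY"),
    L("D","D","I","AS","EQ","TAUTOLOGY"),
    L("D","D","I","DIS","IN","IN_LE_ECTp"),
    L("D","D","I","DIS","EX","EX_GE_DIS_or_EX_GE_ECTm",
      refine_D = "EX_GE_DIS"),
    L("D","D","I","DIS","EQ","CONTRADICTION"),
    # (D, D, D)
    L("D","D","D","AS","IN","IN_GE_AS_and_IN_LE_ECTp"),
    L("D","D","D","AS","EX","CONTRADICTION"),
    L("D","D","D","AS","EQ","CONTRADICTION"),
    L("D","D","D","DIS","IN","IN_LE_ECTp"),
    L("D","D","D","DIS","EX","EX_GE_DIS_or_EX_GE_ECTm",
      refine_D = "EX_GE_DIS"),
    L("D","D","D","DIS","EQ","CONTRADICTION"))
  do.call(rbind, rows)
}

# Truth vector of a formula over the 16 assignments of (P8, P9, P10, P11)
# with a substitution list applied (substituted propositions are overridden).
dominance_truth <- function(formula, sub) {
  g <- do.call(expand.grid, stats::setNames(
    rep(list(c(FALSE, TRUE)), 4), c("P8", "P9", "P10", "P11")))
  for (nm in names(sub)) g[[nm]] <- sub[[nm]]
  eval_formula(formula, g)
}

#' Infer the mechanism conclusion for one ratio-trend scenario
#'
#' Looks up the scenario cell for the three ratio trends, the net reaction
#' and the transmembrane direction, then applies the `C1`-trend refinement
#' where the table provides one (the "black indicator" layer: a decreasing
#' `C1` sharpens several disjunctive or biconditional conclusions).
#'
#' @param s A list or one-row data frame with elements `trend_C2C1`,
#'   `trend_C3C1`, `trend_C3C2` (`"I"`/`"D"`), `reaction` (`"AS"`/`"DIS"`;
#'   alternatively `trend_C3` from which it is read), `tmt`
#'   (`"IN"`/`"EX"`/`"EQ"`), and optionally `trend_C1` (`"I"`/`"D"`) and
#'   `saturated` (logical).
#' @return List with `label`, `base_label`, `provenance` (the cell key),
#'   `refined` (whether the C1 trend sharpened the conclusion) and
#'   `saturated`.
#' @export
infer_mechanisms <- function(s) {
  reaction <- s$reaction %||% (if (identical(s$trend_C3, "D")) "DIS" else "AS")
  tab <- scenario_table()
  hit <- tab[tab$t21 == s$trend_C2C1 & tab$t31 == s$trend_C3C1 &
               tab$t32 == s$trend_C3C2 & tab$reaction == reaction &
               tab$tmt == s$tmt, ]
  stop_if(nrow(hit) != 1, "scenario does not match a unique table cell")
  label <- hit$label
  refined <- FALSE
  if (!is.null(s$trend_C1) && !is.na(s$trend_C1)) {
    ref <- if (s$trend_C1 == "I") hit$refine_I else hit$refine_D
    if (!is.na(ref)) { label <- ref; refined <- TRUE }
  }
  list(label = label, base_label = hit$label,
       provenance = paste0(hit$t21, hit$t31, hit$t32, "|", reaction, "|", s$tmt),
       refined = refined, saturated = isTRUE(s$saturated))
}

#' Certify the scenario table against the enumeration oracle
#'
#' Independently recomputes every cell of [scenario_table()]: the printed
#' per-row conclusion formula is substituted with the mechanism-existence
#' values for the cell, evaluated over all assignments of the dominance
#' propositions, and compared with the stored label's formula.  Contradiction
#' cells must have zero satisfying assignments, tautology cells must be
#' unconstrained, and every other cell's label must be semantically
#' equivalent to the substituted formula.  Additionally certifies that each
#' per-row formula is entailed, under the framework axioms, by the trend
#' premises of its row, and that the refinement labels follow when the `C1`
#' trend is added.
#'
#' @return Data frame with one row per cell and logical columns
#'   `label_equivalent`, `row_formula_entailed`, `refinements_entailed`,
#'   plus `n_models` (satisfying dominance assignments of the cell).
#' @export
verify_scenario_table <- function() {
  tab <- scenario_table()
  bf <- branch_formulas()
  lf <- label_formulas()
  out <- tab[c("t21", "t31", "t32", "reaction", "tmt", "label")]
  out$label_equivalent <- FALSE
  out$row_formula_entailed <- FALSE
  out$refinements_entailed <- TRUE
  out$n_models <- NA_integer_
  trend_lit <- function(p, v) if (v == "I") p else paste0("!", p)
  for (k in seq_len(nrow(tab))) {
    row <- tab[k, ]
    key <- paste0(row$t21, row$t31, row$t32, "|", row$reaction)
    f <- bf[[key]]
    sub <- cell_substitution(row$reaction, row$tmt)
    tv_cell <- dominance_truth(f, sub)
    tv_label <- dominance_truth(lf[[row$label]], sub)
    out$label_equivalent[k] <- identical(tv_cell, tv_label)
    out$n_models[k] <- sum(tv_cell)
    # the row formula must follow from the trend premises under the axioms
    prem <- c(trend_lit("P14", row$t21), trend_lit("P15", row$t31),
              trend_lit("P16", row$t32),
              if (row$reaction == "AS") "P12" else "!P12",
              vapply(names(sub), function(nm)
                if (sub[[nm]]) nm else paste0("!", nm), ""))
    out$row_formula_entailed[k] <- verify_by_truth_table(prem, f)$valid
    # refinement labels must be equivalent once the C1 trend is fixed
    for (tc1 in c("I", "D")) {
      ref <- if (tc1 == "I") row$refine_I else row$refine_D
      if (is.na(ref)) next
      sub5 <- sub
      p5 <- tc1 == "I"
      if (row$tmt == "IN") sub5$P11 <- p5
      if (row$tmt == "EX") sub5$P10 <- p5
      eq <- identical(dominance_truth(f, sub5),
                      dominance_truth(lf[[ref]], sub5))
      out$refinements_entailed[k] <- out$refinements_entailed[k] && eq
    }
  }
  out
}
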