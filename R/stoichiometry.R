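#' Anaerobic fermentation pathway specification
#'
#' Describes one of three NADH-reoxidizing fermentation pathways and the
#' per-step ATP coefficients of its ledger (all moles per mole of the named
#' step's substrate, user-overridable):
#'
#' * `LACTATE` — homolactate fermentation: glucose to 2 pyruvate, both
#'   reduced to lactate to reoxidize the 2 cytosolic NADH.
#' * `OPINE` — opine formation: pyruvate condensed with an amino acid;
#'   redox-equivalent to lactate formation.
#' * `MALATE_DISMUTATION` — glycolysis stops at phosphoenolpyruvate (PEP);
#'   ATP-dependent PEP carboxykinase fixes CO2 to give oxaloacetate, whose
#'   reduction to malate reoxidizes cytosolic NADH. Mitochondrial malate is
#'   split between an oxidative branch (to acetate, producing 2 NADH per
#'   malate) and a reductive branch (fumarate reduction to succinate via
#'   rhodoquinone, consuming 1 NADH per fumarate), with the 1:2 split fixed
#'   by redox closure; succinate is by default carried on to propionate.
#'
#' `chemiosmotic_atp_per_fumarate_reduced` (default 0.75) is a calibration
#' of the proton-motive ATP gained per NADH pushed through the truncated
#' chain onto fumarate; with the other defaults it puts the dismutation
#' yield at exactly 5 ATP/glucose, 2.5-fold the homolactate yield.
#'
#' @param pathway `"LACTATE"`, `"OPINE"` or `"MALATE_DISMUTATION"`.
#' @param pepck_atp_per_pep ATP per PEP carboxylated (default +1; the
#'   yield-generating convention for this step, see the package vignette).
#' @param acetate_branch_atp_per_acetate substrate-level ATP per acetate
#'   formed (default +1).
#' @param propionate_atp_per_propionate ATP per succinate carried on to
#'   propionate (default +1).
#' @param chemiosmotic_atp_per_fumarate_reduced see above (default 0.75).
#' @param glycolysis_net_atp_to_pep net glycolytic ATP down to PEP
#'   (default 0: the 2 ATP invested are repaid by phosphoglycerate kinase).
#' @param glycolysis_net_atp_to_pyruvate net glycolytic ATP down to
#'   pyruvate (default +2).
#' @param reduced_end_product `"PROPIONATE"` (default) or `"SUCCINATE"`
#'   (excrete succinate directly; zeroes the propionate ATP term).
#' @return an object of class `"pathway_spec"`.
#' @export
pathway_spec <- function(pathway = c("MALATE_DISMUTATION", "LACTATE", "OPINE"),
                         pepck_atp_per_pep = 1,
                         acetate_branch_atp_per_acetate = 1,
                         propionate_atp_per_propionate = 1,
                         chemiosmotic_atp_per_fumarate_reduced = 0.75,
                         glycolysis_net_atp_to_pep = 0,
                         glycolysis_net_atp_to_pyruvate = 2,
                         reduced_end_product = c("PROPIONATE", "SUCCINATE")) {
  pathway <- match.arg(pathway)
  reduced_end_product <- match.arg(reduced_end_product)
  coefs <- c(pepck_atp_per_pep = pepck_atp_per_pep,
             acetate_branch_atp_per_acetate = acetate_branch_atp_per_acetate,
             propionate_atp_per_propionate = propionate_atp_per_propionate,
             chemiosmotic_atp_per_fumarate_reduced =
               chemiosmotic_atp_per_fumarate_reduced,
             glycolysis_net_atp_to_pep = glycolysis_net_atp_to_pep,
             glycolysis_net_atp_to_pyruvate = glycolysis_net_atp_to_pyruvate)
  if (!all(is.finite(coefs))) stop_usage("all ATP coefficients must be finite")
  structure(list(pathway = pathway, coefficients = coefs,
                 reduced_end_product = reduced_end_product),
            class = "pathway_spec")
}

#' Redox-balanced split of mitochondrial malate
#'
#' The oxidative branch (malate to pyruvate to acetyl-CoA/acetate) produces
#' 2 NADH per malate; the reductive branch (malate to fumarate to
#' succinate) consumes 1 NADH per fumarate reduced. Closure of the
#' mitochondrial NADH ledger, `2 x oxidized = 1 x reduced`, forces a
#' 1:2 oxidized:reduced split.
#'
#' @param malate_moles moles of malate entering mitochondria (> 0).
#' @return named numeric vector `c(oxidized = m/3, reduced = 2m/3)`.
#' @examples
#' dismutation_split(3)  # c(oxidized = 1, reduced = 2)
#' @export
dismutation_split <- function(malate_moles) {
  if (!is.numeric(malate_moles) || length(malate_moles) != 1L ||
      !is.finite(malate_moles) || malate_moles <= 0)
    stop_usage("malate_moles must be a single positive number")
  c(oxidized = malate_moles / 3, reduced = 2 * malate_moles / 3)
}

#' Net ATP yield and redox ledger of a fermentation pathway
#'
#' Builds the full NADH ledger (itemized by compartment and reaction) and
#' the end-product tally per mole of glucose, verifying redox closure
#' (NADH produced must equal NADH consumed).
#'
#' @param spec a [pathway_spec()].
#' @return an object of class `"yield_result"`: `pathway`,
#'   `net_atp_per_glucose`, `end_products` (named moles per glucose),
#'   `nadh_ledger` (data.frame: compartment, reaction, produced, consumed),
#'   `atp_terms` (itemized ATP contributions), `co2_fixed`, `co2_released`.
#' @examples
#' pathway_yield(pathway_spec("LACTATE"))$net_atp_per_glucose            # 2
#' pathway_yield(pathway_spec("MALATE_DISMUTATION"))$net_atp_per_glucose # 5
#' @export
pathway_yield <- function(spec) {
  stopifnot(inherits(spec, "pathway_spec"))
  k <- spec$coefficients
  if (spec$pathway %in% c("LACTATE", "OPINE")) {
    product <- if (spec$pathway == "LACTATE") "lactate" else "opine"
    ledger <- data.frame(
      compartment = c("cytosol", "cytosol"),
      reaction = c("glycolysis (glucose -> 2 pyruvate)",
                   sprintf("pyruvate -> %s", product)),
      produced = c(2, 0), consumed = c(0, 2), stringsAsFactors = FALSE)
    atp_terms <- c(glycolysis = unname(k["glycolysis_net_atp_to_pyruvate"]))
    res <- list(pathway = spec$pathway,
                net_atp_per_glucose = unname(k["glycolysis_net_atp_to_pyruvate"]),
                end_products = setNames(2, product),
                nadh_ledger = ledger, atp_terms = atp_terms,
                co2_fixed = 0, co2_released = 0)
  } else {
    split <- dismutation_split(2)  # 2 malate per glucose
    ox <- split[["oxidized"]]; red <- split[["reduced"]]
    ledger <- data.frame(
      compartment = c("cytosol", "cytosol", "mitochondrion", "mitochondrion"),
      reaction = c("glycolysis (glucose -> 2 PEP)",
                   "oxaloacetate -> malate (malate dehydrogenase)",
                   "oxidative branch (malate -> pyruvate -> acetyl-CoA)",
                   "reductive branch (fumarate reduction via rhodoquinone)"),
      produced = c(2, 0, 2 * ox, 0),
      consumed = c(0, 2, 0, red), stringsAsFactors = FALSE)
    atp_terms <- c(
      glycolysis = unname(2 * k["glycolysis_net_atp_to_pep"]),
      pepck = unname(2 * k["pepck_atp_per_pep"]),
      acetate_branch = unname(ox * k["acetate_branch_atp_per_acetate"]),
      chemiosmotic = unname(red * k["chemiosmotic_atp_per_fumarate_reduced"]),
      propionate = if (spec$reduced_end_product == "PROPIONATE")
        unname(red * k["propionate_atp_per_propionate"]) else 0)
    products <- c(acetate = ox)
    if (spec$reduced_end_product == "PROPIONATE") {
      products["propionate"] <- red
      co2_released <- 2 * ox + red  # decarboxylations: 2/malate oxidized, 1/succinate
    } else {
      products["succinate"] <- red
      co2_released <- 2 * ox
    }
    res <- list(pathway = spec$pathway,
                net_atp_per_glucose = sum(atp_terms),
                end_products = products, nadh_ledger = ledger,
                atp_terms = atp_terms, co2_fixed = 2, co2_released = co2_released)
  }
  imbalance <- sum(res$nadh_ledger$produced) - sum(res$nadh_ledger$consumed)
  if (abs(imbalance) > 1e-9) {
    items <- paste(sprintf("%s [%s]: +%.3f/-%.3f", res$nadh_ledger$reaction,
                           res$nadh_ledger$compartment, res$nadh_ledger$produced,
                           res$nadh_ledger$consumed), collapse = "; ")
    stop_data(sprintf("NADH ledger does not close (imbalance %.3f): %s",
                      imbalance, items))
  }
  structure(res, class = "yield_result")
}

#' @export
print.yield_result <- function(x, ...) {
  cat(sprintf("%s: net ATP per glucose = %.3f\n", x$pathway,
              x$net_atp_per_glucose))
  cat("ATP terms:\n")
  for (nm in names(x$atp_terms))
    cat(sprintf("  %-15s %+.3f\n", nm, x$atp_terms[nm]))
  cat("end products (mol/mol glucose):\n")
  for (nm in names(x$end_products))
    cat(sprintf("  %-15s %.3f\n", nm, x$end_products[nm]))
  cat(sprintf("CO2 fixed %.3f, released %.3f\n", x$co2_fixed, x$co2_released))
  cat("NADH ledger (produced = consumed):\n")
  lg <- x$nadh_ledger
  for (i in seq_len(nrow(lg)))
    cat(sprintf("  %-13s %-55s +%.3f / -%.3f\n", lg$compartment[i],
                lg$reaction[i], lg$produced[i], lg$consumed[i]))
  invisible(x)
}

#' Ratio of net ATP yields of two pathways
#'
#' @param a,b [pathway_spec()] objects (numerator, denominator).
#' @return `pathway_yield(a)` net ATP divided by `pathway_yield(b)` net ATP.
#' @examples
#' yield_ratio(pathway_spec("MALATE_DISMUTATION"), pathway_spec("LACTATE"))  # 2.5
#' @export
yield_ratio <- function(a, b) {
  ya <- pathway_yield(a); yb <- pathway_yield(b)
  if (yb$net_atp_per_glucose == 0)
    stop_data("denominator pathway has zero net ATP yield")
  ya$net_atp_per_glucose / yb$net_atp_per_glucose
}
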