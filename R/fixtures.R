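# Bundled example networks and the pipeline self-test.

OR_GATE_RULES <- "
# single OR-gate automaton with two self-copy inputs
x* = x1 or x2
x1* = x1
x2* = x2
"

# Six-node example regulatory network: two constant inputs (i1, i2), two
# genes (g1, g2), and two proteins (P1, P2) with a negative feedback loop:
# P1 requires g1 and the absence of P2; P2 requires g2 and i2; P1 promotes
# g2 while i1 drives g1.
EXAMPLE_GRN_RULES <- "
g1* = i1
g2* = P1
P1* = g1 and not P2
P2* = g2 and i2
i1* = i1
i2* = i2
"

# SYNTHETIC reconstruction of the single-cell Drosophila segment-polarity
# Boolean network (n = 17), written from the standard published update
# equations of the model (inputs SLP, nWG, nHH; genes wg, en, hh, ptc, ci
# with their protein products; SMO, PH, CIA, CIR signalling states).  This
# is NOT the authors' distributed model file, which is not bundled; the
# reconstruction reproduces the published module counts at seed sizes 1-4
# and the headline module sizes, and is labelled synthetic accordingly.
SPN_CELL_SYNTHETIC_RULES <- "
SLP* = SLP
nWG* = nWG
nHH* = nHH
wg* = (CIA and SLP and not CIR) or (wg and (CIA or SLP) and not CIR)
WG* = wg
en* = nWG and not SLP
EN* = en
hh* = EN and not CIR
HH* = hh
ptc* = CIA and not EN and not CIR
PTC* = ptc or (PTC and not nHH)
PH* = PTC and nHH
SMO* = not PTC or nHH
ci* = not EN
CI* = ci
CIA* = CI and (SMO or nHH)
CIR* = CI and not SMO and not nHH
"

#' Load a bundled fixture network
#'
#' Available fixtures:
#' \describe{
#'   \item{`or_gate`}{three nodes: an OR gate over two self-copy inputs.}
#'   \item{`example_grn`}{the six-node regulatory network with inputs
#'     `i1`, `i2`, genes `g1`, `g2`, and proteins `P1`, `P2` under a
#'     negative feedback loop.}
#'   \item{`example_grn_lattice4`}{the six-node network composed over a
#'     periodic linear lattice of 4 cells, with each cell's `i1` input
#'     replaced by the left neighbour's `P2` (20 variables).}
#'   \item{`spn_cell_synthetic`}{a synthetic reconstruction of the 17-node
#'     single-cell Drosophila segment-polarity Boolean network, written
#'     from the model's standard published update equations (not the
#'     authors' distributed file).}
#'   \item{`spn_parasegment_synthetic`}{the synthetic single-cell model
#'     composed over a periodic lattice of 4 cells, with the nWG/nHH
#'     inputs replaced by the neighbouring cells' WG/HH nodes (60
#'     variables).}
#'   \item{`random:n=..,k=..,bias=..,seed=..`}{a seeded random network from
#'     [generate_random_bn()].}
#' }
#'
#' @param name fixture name.
#' @return a `boolean_network`.
#' @export
load_fixture <- function(name) {
  if (startsWith(name, "random:")) {
    kv <- strsplit(sub("^random:", "", name), ",", fixed = TRUE)[[1]]
    pairs <- strsplit(kv, "=", fixed = TRUE)
    args <- stats::setNames(
      lapply(pairs, function(p) as.numeric(p[2])),
      vapply(pairs, `[[`, character(1), 1))
    return(do.call(generate_random_bn, args))
  }
  switch(name,
         or_gate = parse_rules(OR_GATE_RULES),
         example_grn = parse_rules(EXAMPLE_GRN_RULES),
         example_grn_lattice4 = {
           template <- parse_rules(EXAMPLE_GRN_RULES)
           compose_lattice(lattice_spec(template, cells = 4,
                                        coupling = list(i1 = "P2[-1]"),
                                        boundary = "periodic"))
         },
         spn_cell_synthetic = parse_rules(SPN_CELL_SYNTHETIC_RULES),
         spn_parasegment_synthetic = {
           template <- parse_rules(SPN_CELL_SYNTHETIC_RULES)
           compose_lattice(lattice_spec(
             template, cells = 4,
             coupling = list(nWG = "WG[-1] or WG[1]",
                             nHH = "HH[-1] or HH[1]"),
             boundary = "periodic"))
         },
         stop("unknown fixture: '", name, "'"))
}

#' Run the pipeline self-test on a fixture
#'
#' Executes the full pipeline (schemata, DCM, modules, covers) and checks
#' the fixture's expected-values table.  Random fixtures run property
#' checks only (unfolding soundness against the exhaustive oracle).
#'
#' @param name fixture name as for [load_fixture()].
#' @return data frame of checks with columns `check`, `expected`,
#'   `observed`, `pass`; all-pass is also signalled via the
#'   `passed` attribute.
#' @export
run_selftest <- function(name) {
  add <- function(tbl, check, expected, observed) {
    rbind(tbl, data.frame(check = check,
                          expected = as.character(expected),
                          observed = as.character(observed),
                          pass = isTRUE(all.equal(expected, observed)) ||
                            identical(as.character(expected),
                                      as.character(observed))))
  }
  tbl <- data.frame(check = character(0), expected = character(0),
                    observed = character(0), pass = logical(0))
  if (name == "or_gate") {
    net <- load_fixture(name)
    fp <- prime_implicants(net$nodes[["x"]])
    tbl <- add(tbl, "F' ON schemata", "#1,1#",
               paste(sort(fp$pattern[fp$output == 1], method = "radix"), collapse = ","))
    tbl <- add(tbl, "F' OFF schemata", "00",
               paste(fp$pattern[fp$output == 0], collapse = ","))
    cm <- build_cm(net$nodes[["x"]])
    taus <- sort(vapply(cm$t_units, `[[`, integer(1), "tau"))
    tbl <- add(tbl, "t-unit thresholds", "1,2", paste(taus, collapse = ","))
  } else if (name == "example_grn") {
    net <- load_fixture(name)
    dcm <- build_dcm(net)
    tbl <- add(tbl, "s-units", 12L, length(dcm$s_units))
    catalog <- module_catalog(dcm, s_max = 3L)
    tbl <- add(tbl, "complex modules s=1", 6L, catalog$counts$complex[1])
    tbl <- add(tbl, "core complex modules s=2", 2L, catalog$counts$core[2])
    csn <- characteristic_seed_number(dcm, s_max = 3L, catalog = catalog)
    tbl <- add(tbl, "D-bar(Pi*_1)", 0.71, round_half_up(csn$curve$dbar[1], 2))
    tbl <- add(tbl, "D-bar(Pi*_2)", 0.83, round_half_up(csn$curve$dbar[2], 2))
    tbl <- add(tbl, "minimal cover size (s=2)", 3L,
               csn$covers[[2]]$minimal_cover$size)
    tbl <- add(tbl, "D-bar(minimal cover, s=2)", 0.6,
               round_half_up(csn$covers[[2]]$minimal_report$mean, 2))
    tbl <- add(tbl, "characteristic seed number", 2L, csn$s_star)
  } else {
    net <- load_fixture(name)
    dcm <- build_dcm(net)
    vars <- node_names(net)
    ok <- TRUE
    for (v in vars) {
      for (st in c(0L, 1L)) {
        pm <- unfold(dcm, stats::setNames(st, v))
        oracle <- brute_force_stabilization(net, stats::setNames(st, v))
        sound <- all(vapply(pm$module_set, function(su) {
          va <- sunit_variable(su)
          va %in% names(oracle) && oracle[[va]] == sunit_state(su)
        }, logical(1)))
        ok <- ok && sound
      }
    }
    tbl <- add(tbl, "pinning unfolding sound vs oracle", TRUE, ok)
  }
  attr(tbl, "passed") <- all(tbl$pass)
  tbl
}
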