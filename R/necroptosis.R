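#' The five-component TNF death circuit
#'
#' Loads the TNF-induced cell death circuit: activated TRADD (`TRADD`),
#' phosphorylated RIP1 (`RIP1`), phosphorylated RIP3 (`RIP3`), TRADD-activated
#' caspase-8 (`C8a`), and RIP1-activated caspase-8 (`C8b`). TNF stimulation
#' activates TRADD and RIP1 (two `".stim"` edges); TRADD and RIP1 mutually
#' inhibit (competition for the receptor complex); TRADD activates C8a
#' (apoptosis arm); and nine labeled interaction terms `k1`--`k9` couple RIP1,
#' RIP3, and necrosomal C8 (C8b):
#'
#' * `k1` C8 -| RIP1, `k2` RIP1 self-activation, `k3` RIP3 -> RIP1,
#' * `k4` C8 self-activation, `k5` RIP1 -> C8, `k6` RIP3 -| C8,
#' * `k7` RIP1 -> RIP3, `k8` RIP3 self-activation, `k9` C8 -| RIP3.
#'
#' `k5`, `k7`, `k9` form the RIP1-RIP3-C8 incoherent feedforward loop (direct
#' activation RIP1 -> RIP3 versus the indirect RIP1 -> C8 -| RIP3 arm); `k3`
#' is the RIP3-to-RIP1 positive feedback required for death-mode coexistence.
#'
#' The shipped parameterization
#' (`inst/extdata/necroptosis_reference_synthetic.yaml`) is a synthetic
#' reference set: it was calibrated against the published behavior of this
#' circuit (biphasic/emergent RIP1-dependent pRIP3 response, knockout
#' signatures, coexistence window, and the reported H landmarks) rather than
#' transcribed from a published table; see the methods vignette.
#'
#' @param path YAML model specification; default: the shipped synthetic
#'   reference file.
#' @return an object of class `death_circuit`: a list with the embedded
#'   `circuit`, the `label_map` of term labels to edges, and the
#'   `protein_map` of protein names to nodes (C8 covers both `C8a`/`C8b`).
#' @export
necroptosis_model <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "necroptosis_reference_synthetic.yaml",
                        package = "becdyn", mustWork = TRUE)
  circ <- read_circuit_yaml(path)
  label_map <- list(
    k1 = c("C8b", "RIP1"), k2 = c("RIP1", "RIP1"), k3 = c("RIP3", "RIP1"),
    k4 = c("C8b", "C8b"),  k5 = c("RIP1", "C8b"),  k6 = c("RIP3", "C8b"),
    k7 = c("RIP1", "RIP3"), k8 = c("RIP3", "RIP3"), k9 = c("C8b", "RIP3"))
  protein_map <- list(TRADD = "TRADD", RIP1 = "RIP1", RIP3 = "RIP3",
                      C8 = c("C8a", "C8b"))
  structure(list(circuit = circ, label_map = label_map,
                 protein_map = protein_map),
            class = "death_circuit")
}

#' @export
print.death_circuit <- function(x, ...) {
  cat("<death_circuit> TNF five-component model;",
      nrow(x$circuit$edges), "edges,", length(x$label_map), "labeled terms\n")
  invisible(x)
}

#' Scale protein expression or remove interaction terms
#'
#' `set_expression()` models knockdown/knockout by scaling a protein's
#' expression total (C8 scales both activation routes). `knockout_terms()`
#' silences labeled interaction terms by setting their maximal rates to zero;
#' `knockout_proteins()` sets totals to zero.
#'
#' @param model a `death_circuit`.
#' @param protein one of `"TRADD"`, `"RIP1"`, `"RIP3"`, `"C8"`.
#' @param level expression fraction of wild type in `[0, 1]`.
#' @param terms character vector of term labels (`"k1"`...`"k9"`).
#' @param proteins character vector of protein names.
#' @return the modified `death_circuit`.
#' @export
set_expression <- function(model, protein, level) {
  nodes <- model$protein_map[[protein]]
  if (is.null(nodes)) stop("unknown protein: ", protein)
  for (nd in nodes) model$circuit <- set_total(model$circuit, nd, level)
  model
}

#' @rdname set_expression
#' @export
knockout_terms <- function(model, terms) {
  for (tm in terms) {
    e <- model$label_map[[tm]]
    if (is.null(e)) stop("unknown term label: ", tm)
    model$circuit <- set_edge(model$circuit, e[1], e[2], k = 0)
  }
  model
}

#' @rdname set_expression
#' @export
knockout_proteins <- function(model, proteins) {
  for (p in proteins) model <- set_expression(model, p, 0)
  model
}

#' @rdname set_expression
#' @param term single term label.
#' @param k new maximal rate for that term.
#' @export
set_term_k <- function(model, term, k) {
  e <- model$label_map[[term]]
  if (is.null(e)) stop("unknown term label: ", term)
  model$circuit <- set_edge(model$circuit, e[1], e[2], k = k)
  model
}

#' RIP1-dependent pRIP3 dose-response curve
#'
#' Scans RIP1 expression from knockout to wild type and records the
#' steady-state phosphorylated RIP3 level; the reference model shows the
#' characteristic biphasic response with an abrupt rise at low RIP1 followed
#' by a gentle C8-mediated decline.
#'
#' @param model a `death_circuit`.
#' @param rip1_grid RIP1 expression fractions (default 101 points, 0--100%).
#' @param ... passed to [dose_response()].
#' @return a [dose_response()] object (readout `RIP3`).
#' @export
rip3_dose_curve <- function(model, rip1_grid = seq(0, 1, length.out = 101),
                            ...) {
  dose_response(model$circuit, "RIP1", rip1_grid, readout_node = "RIP3", ...)
}

#' Single-term knockout scan
#'
#' Removes each labeled term `k1`...`k9` in turn, recomputes the RIP1 dose
#' response, and reports the biphasic/emergence classification and H. In the
#' reference model, biphasic-emergent dynamics survive every removal except
#' the three incoherent-feedforward terms `k5`, `k7`, `k9`.
#'
#' @param model a `death_circuit`.
#' @param rip1_grid dose grid.
#' @param ... passed to [rip3_dose_curve()].
#' @return data frame with one row per term: `term`, `BD`, `BD_value`, `ED`,
#'   `ED_slope`, `H`.
#' @export
term_knockout_scan <- function(model, rip1_grid = seq(0, 1, length.out = 101),
                               ...) {
  terms <- names(model$label_map)
  rows <- lapply(terms, function(tm) {
    m <- knockout_terms(model, tm)
    cur <- rip3_dose_curve(m, rip1_grid, ...)
    bd <- classify_biphasic(cur)
    ed <- classify_emergent(cur)
    data.frame(term = tm, BD = bd$flag, BD_value = bd$value,
               ED = ed$flag, ED_slope = ed$max_slope,
               H = compute_H(cur), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Expression scan of peak and terminal pRIP3 and H
#'
#' For each expression level of the scanned protein, recomputes the RIP1 dose
#' curve and reports the absolute and relative (divided by the RIP3 total)
#' peak pRIP3, the pRIP3 level at 100% RIP1, and H. The relative peak of the
#' reference model is approximately constant in RIP3 -- the scale-free
#' signature -- while H traces an inverted bell with its minimum near 10%
#' RIP3.
#'
#' @param model a `death_circuit`.
#' @param protein scanned protein (`"RIP3"`, `"TRADD"`, or `"C8"`).
#' @param levels expression fractions in `(0, 1]`.
#' @param rip1_grid dose grid.
#' @param ... passed to [rip3_dose_curve()].
#' @return data frame with columns `level`, `peak_abs`, `peak_rel`,
#'   `end_abs`, `end_rel`, `H`, `converged`.
#' @export
expression_scan <- function(model, protein = "RIP3",
                            levels = seq(0.01, 1, length.out = 101),
                            rip1_grid = seq(0, 1, length.out = 101), ...) {
  if (any(levels <= 0) || any(levels > 1))
    stop("levels must lie in (0, 1]")
  rows <- lapply(levels, function(lv) {
    m <- set_expression(model, protein, lv)
    cur <- rip3_dose_curve(m, rip1_grid, ...)
    r3tot <- m$circuit$nodes$total[node_index(m$circuit, "RIP3")]
    peak <- max(cur$readout)
    endv <- cur$readout[nrow(cur)]
    data.frame(level = lv, peak_abs = peak, peak_rel = peak / r3tot,
               end_abs = endv, end_rel = endv / r3tot,
               H = (peak - endv) / r3tot,
               converged = all(cur$converged))
  })
  do.call(rbind, rows)
}

#' H over the k5-k7 parameter plane
#'
#' Evaluates H on a grid of the two incoherent-feedforward activation
#' strengths `k5` (RIP1 -> C8) and `k7` (RIP1 -> RIP3), all other parameters
#' at their reference values. Both terms reshape peak and terminal pRIP3 in
#' opposite directions, producing a bell-shaped regulation of H with an
#' interior maximum.
#'
#' @param model a `death_circuit`.
#' @param k5_grid,k7_grid positive rate grids (log-spaced recommended).
#' @param rip1_grid dose grid.
#' @param ... passed to [rip3_dose_curve()].
#' @return list with `H` (matrix, rows = k5, cols = k7), `k5`, `k7`,
#'   `max` (max H), `argmax` (named k5/k7 at the maximum), and `nonconverged`
#'   (logical matrix of cells with any nonconverged dose).
#' @export
k5_k7_phase_plane <- function(model, k5_grid, k7_grid,
                              rip1_grid = seq(0, 1, length.out = 101), ...) {
  if (any(k5_grid <= 0) || any(k7_grid <= 0)) stop("rate grids must be positive")
  H <- matrix(NA_real_, length(k5_grid), length(k7_grid))
  bad <- matrix(FALSE, length(k5_grid), length(k7_grid))
  for (i in seq_along(k5_grid)) {
    mi <- set_term_k(model, "k5", k5_grid[i])
    for (jj in seq_along(k7_grid)) {
      m <- set_term_k(mi, "k7", k7_grid[jj])
      cur <- rip3_dose_curve(m, rip1_grid, ...)
      H[i, jj] <- compute_H(cur)
      bad[i, jj] <- !all(cur$converged)
    }
  }
  am <- which(H == max(H, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(H = H, k5 = k5_grid, k7 = k7_grid,
       max = max(H, na.rm = TRUE),
       argmax = c(k5 = k5_grid[am[1]], k7 = k7_grid[am[2]]),
       nonconverged = bad)
}
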