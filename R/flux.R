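#' Score intervals
#'
#' Component efficiencies in the dimer route-flux model are unit-interval
#' scores, optionally ranged (e.g. a variable oligomerization defect scored
#' 0.3-0.5). `score_interval()` normalizes a scalar or length-2 vector to a
#' validated `[lo, hi]` pair within `[0, 1]`.
#'
#' @param x scalar or length-2 numeric in `[0, 1]`.
#' @return numeric `c(lo, hi)`.
#' @export
score_interval <- function(x) {
  if (length(x) == 1) x <- c(x, x)
  if (length(x) != 2 || any(!is.finite(x)))
    stop_invalid("a score interval is one or two finite numbers")
  if (x[1] > x[2]) stop_invalid("interval lower bound exceeds upper bound")
  if (x[1] < 0 || x[2] > 1) stop_invalid("score bounds must lie in [0, 1]")
  as.numeric(x)
}

# internal: endpoint-wise product of non-negative intervals
iv_prod <- function(...) {
  ivs <- list(...)
  lo <- prod(vapply(ivs, `[`, numeric(1), 1))
  hi <- prod(vapply(ivs, `[`, numeric(1), 2))
  c(lo, hi)
}

iv_sum <- function(...) {
  ivs <- list(...)
  c(sum(vapply(ivs, `[`, numeric(1), 1)), sum(vapply(ivs, `[`, numeric(1), 2)))
}

#' Monomer parameter set for the dimer flux model
#'
#' Per-monomer efficiencies of the bifunctional enzyme: the epimerase reaction
#' (UDP-GlcNAc 2-epimerase), the kinase reaction (ManNAc kinase) and the
#' intramolecular transfer of the ManNAc intermediate from the epimerase to
#' the kinase domain of the same monomer.
#'
#' @param variant_label text label.
#' @param epimerase,kinase,intra_transfer scalar or `[lo, hi]` scores in `[0, 1]`.
#' @return list of class `monomer_params`.
#' @export
monomer_params <- function(variant_label, epimerase, kinase, intra_transfer) {
  structure(list(variant_label = variant_label,
                 epimerase = score_interval(epimerase),
                 kinase = score_interval(kinase),
                 intra_transfer = score_interval(intra_transfer)),
            class = "monomer_params")
}

#' Monomer presets
#'
#' The model's variant presets. `WT` has all components at 1. `D207V` leaves
#' both enzymatic reactions intact but halves intramolecular ManNAc transfer
#' (score 0.5); at the dimer level it additionally impairs intermonomer
#' transfer (0.3-0.5, variable with oligomerization status — see
#' [dimer_flux_model()]). `catalytic` represents a catalytic-site variant with
#' both reactions at 0.1; `V603L` has both reactions at 0.2. `D207V_invitro`
#' is a non-default alternative that additionally carries the in vitro
#' epimerase activity (18% of wild type) reported for the corresponding
#' short-isoform mutant; the plain `D207V` preset is the model default, which
#' assigns D207V no enzymatic penalty.
#'
#' @param variant_label one of `"WT"`, `"D207V"`, `"catalytic"`, `"V603L"`,
#'   `"D207V_invitro"`.
#' @return a [monomer_params()] object.
#' @examples
#' monomer_preset("D207V")$intra_transfer   # c(0.5, 0.5)
#' @export
monomer_preset <- function(variant_label) {
  presets <- list(
    WT            = list(1, 1, 1),
    D207V         = list(1, 1, 0.5),
    catalytic     = list(0.1, 0.1, 1),
    V603L         = list(0.2, 0.2, 1),
    D207V_invitro = list(0.18, 1, 0.5)
  )
  p <- presets[[variant_label]]
  if (is.null(p)) stop_invalid("unknown preset: ", variant_label)
  monomer_params(variant_label, p[[1]], p[[2]], p[[3]])
}

# internal: is a monomer a D207V-class (oligomerization-impairing) variant
is_d207v <- function(m) m$variant_label %in% c("D207V", "D207V_invitro")

#' Dimer flux model
#'
#' A dimer of two monomers plus the intermonomer ManNAc transfer score. By
#' default intermonomer transfer is 1 unless at least one monomer is a
#' D207V-class variant, in which case the oligomerization defect makes it
#' variable at 0.3-0.5; pass `inter_transfer` to override.
#'
#' @param monomer1,monomer2 [monomer_params()] objects or preset labels.
#' @param inter_transfer optional scalar or interval override in `[0, 1]`.
#' @return list of class `dimer_flux_model`.
#' @export
dimer_flux_model <- function(monomer1, monomer2, inter_transfer = NULL) {
  if (is.character(monomer1)) monomer1 <- monomer_preset(monomer1)
  if (is.character(monomer2)) monomer2 <- monomer_preset(monomer2)
  if (is.null(inter_transfer))
    inter_transfer <- if (is_d207v(monomer1) || is_d207v(monomer2)) c(0.3, 0.5) else c(1, 1)
  structure(list(monomer1 = monomer1, monomer2 = monomer2,
                 inter_transfer = score_interval(inter_transfer)),
            class = "dimer_flux_model")
}

#' Score of one ManNAc production route
#'
#' A route runs from the epimerase domain of a source monomer through a
#' transfer step to the kinase domain of a destination monomer; its score is
#' the product of the three component scores. With all components non-negative
#' the interval product is endpoint-wise.
#'
#' @param source,dest [monomer_params()] objects.
#' @param transfer transfer-score interval (intramolecular or intermonomer).
#' @return score interval `c(lo, hi)`.
#' @examples
#' route_score(monomer_preset("catalytic"), monomer_preset("WT"), c(0.3, 0.5))
#' @export
route_score <- function(source, dest, transfer) {
  iv_prod(source$epimerase, score_interval(transfer), dest$kinase)
}

#' Predicted ManNAc 6-phosphate production of a dimer
#'
#' Sums the four production routes of the dimer: the intramolecular route
#' within each monomer (own epimerase x own intramolecular transfer x own
#' kinase) and the two intermonomer routes (source epimerase x intermonomer
#' transfer x destination kinase). The wild-type dimer scores 4 (each route 1);
#' `total_relative_to_wt` rescales so wild type is 1. Ranged component scores
#' propagate by interval arithmetic, never collapsed to midpoints.
#'
#' @param model a [dimer_flux_model()].
#' @return list of class `route_scores` with intervals `intra_1`, `intra_2`,
#'   `inter_1to2`, `inter_2to1`, `total` and `total_relative_to_wt`.
#' @examples
#' dimer_production(dimer_flux_model("D207V", "D207V"))$total   # c(1.6, 2.0)
#' @export
dimer_production <- function(model) {
  m1 <- model$monomer1; m2 <- model$monomer2
  intra_1 <- route_score(m1, m1, m1$intra_transfer)
  intra_2 <- route_score(m2, m2, m2$intra_transfer)
  inter_1to2 <- route_score(m1, m2, model$inter_transfer)
  inter_2to1 <- route_score(m2, m1, model$inter_transfer)
  total <- iv_sum(intra_1, intra_2, inter_1to2, inter_2to1)
  structure(list(intra_1 = intra_1, intra_2 = intra_2,
                 inter_1to2 = inter_1to2, inter_2to1 = inter_2to1,
                 total = total, total_relative_to_wt = total / 4),
            class = "route_scores")
}

#' @export
print.route_scores <- function(x, ...) {
  iv <- function(v) if (v[1] == v[2]) sprintf("%.3g", v[1])
                    else sprintf("[%.3g, %.3g]", v[1], v[2])
  cat("dimer production routes:\n")
  for (r in c("intra_1", "intra_2", "inter_1to2", "inter_2to1"))
    cat(sprintf("  %-10s %s\n", r, iv(x[[r]])))
  cat(sprintf("  total      %s  (relative to WT: %s)\n",
              iv(x$total), iv(x$total_relative_to_wt)))
  invisible(x)
}

#' Production totals over all preset pairs
#'
#' Evaluates [dimer_production()] for every ordered pair of the default
#' presets, for tabulating predicted genotype severity.
#'
#' @param labels preset labels to cross.
#' @return data.frame with monomer labels and total/relative interval bounds.
#' @export
flux_preset_grid <- function(labels = c("WT", "D207V", "catalytic", "V603L")) {
  combos <- expand.grid(m1 = labels, m2 = labels, stringsAsFactors = FALSE)
  do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    rs <- dimer_production(dimer_flux_model(combos$m1[i], combos$m2[i]))
    data.frame(monomer1 = combos$m1[i], monomer2 = combos$m2[i],
               total_lo = rs$total[1], total_hi = rs$total[2],
               relative_lo = rs$total_relative_to_wt[1],
               relative_hi = rs$total_relative_to_wt[2],
               stringsAsFactors = FALSE)
  }))
}
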