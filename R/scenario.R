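#' Whole-genome-duplication event descriptor
#'
#' @param kind One of \code{"auto_tetraploidy"}, \code{"allo_tetraploidy"},
#'   \code{"hexaploidy_two_step"}.
#' @param lineage Species-tree branch the event sits on (e.g.
#'   \code{"vertebrate_stem"}).
#' @param time Event age in Ma.
#' @param progenitor_divergences Progenitor divergence ages in Ma: none for
#'   auto-tetraploidy, one for allo-tetraploidy, two (strictly decreasing)
#'   for two-step hexaploidy.
#' @param retention Per-copy survival probability of gene duplicates,
#'   \code{0 < retention <= 1}.
#' @return A list of class \code{"wgd_event"}.
#' @export
wgd_event <- function(kind = c("auto_tetraploidy", "allo_tetraploidy",
                               "hexaploidy_two_step"),
                      lineage, time, progenitor_divergences = numeric(0),
                      retention = 0.8) {
  kind <- match.arg(kind)
  np <- length(progenitor_divergences)
  if (kind == "allo_tetraploidy" && np != 1L)
    stop("allo-tetraploidy requires exactly one progenitor divergence age")
  if (kind == "hexaploidy_two_step") {
    if (np != 2L) stop("two-step hexaploidy requires exactly two divergence ages")
    if (diff(progenitor_divergences) >= 0)
      stop("hexaploidy divergence ages must be strictly decreasing")
  }
  if (kind == "allo_tetraploidy" && progenitor_divergences[1] < time)
    stop("progenitor divergence must predate the merger")
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  structure(list(kind = kind, lineage = lineage, time = time,
                 progenitor_divergences = progenitor_divergences,
                 retention = retention),
            class = "wgd_event")
}

#' Default vertebrate genome-duplication scenario
#'
#' The scripted history emulated by the simulator: a single
#' auto-tetraploidization (1R) on the vertebrate stem whose paralogon
#' divergence (rediploidization) completes at 527 Ma; the
#' cyclostome-gnathostome split at 520 Ma; a gnathostome allo-tetraploidy
#' (2R, jawed vertebrates) with alpha/beta progenitor divergence at 508 Ma;
#' a cyclostome two-step hexaploidy with paralogon divergences at 511 and
#' 493 Ma; the hagfish-lamprey split at 457 Ma; and a gnathostome crown
#' divergence at 430 Ma. One designated chordate linkage group (CLG,
#' default \code{"CLGB"}) retains 1R tetrasomy through both splits and
#' rediploidizes lineage-specifically: on the gnathostome stem at 515 Ma,
#' in hagfish at 431 Ma and in lamprey at 442 Ma; its extra hexaploid
#' copies are treated as lost.
#'
#' @param clg_count Number of chordate linkage groups (default 17).
#' @param rate Substitution rate in substitutions/site/Ma (default 5e-4).
#' @param lineage_specific_clg CLG id with lineage-specific 1R
#'   rediploidization in cyclostomes, or \code{NA} for none.
#' @return An object of class \code{"evolution_scenario"}.
#' @examples
#' sc <- default_scenario()
#' speciation_age(sc, "cyclostome_gnathostome")  # 520
#' @export
default_scenario <- function(clg_count = 17L, rate = 5e-4,
                             lineage_specific_clg = "CLGB") {
  stopifnot(clg_count >= 1, rate > 0)
  clgs <- paste0("CLG", LETTERS[seq_len(clg_count)])
  events <- list(
    `1R` = wgd_event("auto_tetraploidy", "vertebrate_stem", time = 530,
                     retention = 0.85),
    `2R_JV` = wgd_event("allo_tetraploidy", "gnathostome_stem", time = 500,
                        progenitor_divergences = 508, retention = 0.80),
    `2R_CY` = wgd_event("hexaploidy_two_step", "cyclostome_stem", time = 490,
                        progenitor_divergences = c(511, 493),
                        retention = 0.65))
  speciations <- c(root = 600, cyclostome_gnathostome = 520,
                   hagfish_lamprey = 457, gnathostome_crown = 430)
  redip_1R <- setNames(rep(527, clg_count), clgs)
  ls_redip <- c(gnathostome = 515, hagfish = 431, lamprey = 442)
  species <- data.frame(
    species = c("outgroup", "hagfish", "lamprey", "gar", "frog"),
    lineage = c("outgroup", "cyclostome", "cyclostome",
                "gnathostome", "gnathostome"),
    stringsAsFactors = FALSE)
  st <- ape::read.tree(text = paste0(
    "(outgroup:600,((hagfish:457,lamprey:457):63,",
    "(gar:430,frog:430):90):80);"))
  sc <- structure(list(clgs = clgs, clg_count = clg_count, rate = rate,
                       events = events, speciations = speciations,
                       redip_1R = redip_1R,
                       lineage_specific_clg = lineage_specific_clg,
                       ls_redip = ls_redip,
                       species = species, species_tree = st),
                  class = "evolution_scenario")
  validate_scenario(sc)
  sc
}

#' @rdname default_scenario
#' @param scenario An \code{evolution_scenario}.
#' @param which Speciation name (e.g. \code{"cyclostome_gnathostome"},
#'   \code{"hagfish_lamprey"}).
#' @export
speciation_age <- function(scenario, which) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  unname(scenario$speciations[[which]])
}

#' @rdname default_scenario
#' @export
validate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "evolution_scenario"))
  with(scenario, {
    if (clg_count < 1) stop("clg_count must be >= 1")
    if (rate <= 0) stop("rate must be > 0")
    sp <- speciations
    ## 1R rediploidization lies on the vertebrate stem unless the CLG is
    ## scripted as lineage-specific
    anc <- setdiff(clgs, lineage_specific_clg)
    ok <- redip_1R[anc] <= sp["root"] & redip_1R[anc] >= sp["cyclostome_gnathostome"]
    if (!all(ok)) stop("1R rediploidization times must lie on the vertebrate stem")
    hx <- events[["2R_CY"]]$progenitor_divergences
    if (any(hx > sp["cyclostome_gnathostome"]) || any(hx < sp["hagfish_lamprey"]))
      stop("hexaploidy divergences must lie on the cyclostome stem")
    if (!is.na(lineage_specific_clg) && !lineage_specific_clg %in% clgs)
      stop("lineage_specific_clg is not a known CLG")
  })
  invisible(scenario)
}

#' @export
print.evolution_scenario <- function(x, ...) {
  cat("Evolution scenario:", x$clg_count, "CLGs, rate", x$rate, "subst/site/Ma\n")
  cat("  speciations (Ma):",
      paste(names(x$speciations), x$speciations, sep = "=", collapse = ", "), "\n")
  cat("  events:", paste(names(x$events), collapse = ", "), "\n")
  cat("  lineage-specific CLG:", x$lineage_specific_clg, "\n")
  invisible(x)
}
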