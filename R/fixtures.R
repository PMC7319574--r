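#' Deterministic toy genome-scale models
#'
#' `TOY6` is a six-metabolite, six-reaction model with a unique LP optimum:
#' an uptake reaction `UPT` (bounded at 10) feeds `A`, which is converted to
#' `B` and split into two branches producing `C` (ATP-coupled, via `R2`) and
#' `D` (via `R3`); the objective `BIO` consumes one `C` and one `D`, so the
#' optimum is 5 with the uptake at its bound. `REG` regenerates ATP from ADP,
#' making ATP/ADP a proper cofactor pair. `TOY6Z` adds a dead-end uptake
#' `UPT2` producing metabolite `E` that nothing consumes, so mass balance
#' forces its flux to zero at any feasible solution.
#'
#' @param name `"TOY6"` or `"TOY6Z"`.
#' @param file optional path; when given the model is also written there as
#'   SBML (Level 3 + fbc v2).
#' @return a [GEM-class] with cofactors tagged by the default list.
#' @examples
#' objectiveValue(optimizeFlux(makeToyGEM("TOY6")))  # 5
#' @export
makeToyGEM <- function(name = c("TOY6", "TOY6Z"), file = NULL) {
  name <- match.arg(name)
  mets <- data.frame(
    id = c("A", "B", "C", "D", "ATP", "ADP"),
    name = c("metabolite A", "metabolite B", "metabolite C", "metabolite D",
             "ATP", "ADP"),
    compartment = "c",
    formula = c("C6H12O6", "C3H4O3", "C3H6O3", "C2H4O2",
                "C10H16N5O13P3", "C10H15N5O10P2"),
    charge = 0L,
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("UPT", "R1", "R2", "R3", "REG", "BIO"),
    name = c("uptake of A", "A to B", "B to C (ATP-coupled)", "B to D",
             "ATP regeneration", "biomass"),
    lowerBound = 0,
    upperBound = c(10, 1000, 1000, 1000, 1000, 1000),
    objectiveCoefficient = c(0, 0, 0, 0, 0, 1),
    stringsAsFactors = FALSE)
  stoich <- list(
    UPT = c(A = 1),
    R1 = c(A = -1, B = 1),
    R2 = c(B = -1, ATP = -1, C = 1, ADP = 1),
    R3 = c(B = -1, D = 1),
    REG = c(ADP = -1, ATP = 1),
    BIO = c(C = -1, D = -1))
  if (name == "TOY6Z") {
    mets <- rbind(mets, data.frame(
      id = "E", name = "dead-end metabolite E", compartment = "c",
      formula = NA_character_, charge = NA_integer_, stringsAsFactors = FALSE))
    rxns <- rbind(rxns, data.frame(
      id = "UPT2", name = "dead-end uptake of E", lowerBound = 0,
      upperBound = 10, objectiveCoefficient = 0, stringsAsFactors = FALSE))
    stoich$UPT2 <- c(E = 1)
  }
  gem <- GEM(modelId = name, compartments = c(c = "cytosol"),
             metabolites = mets, reactions = rxns, stoichiometry = stoich)
  gem <- tagCofactors(gem)
  if (!is.null(file)) writeSBML(gem, file)
  gem
}

#' Random feasible genome-scale models
#'
#' Builds `nPathways` parallel linear pathways, each an uptake reaction
#' feeding a chain of conversions, all ending in a single biomass reaction
#' that consumes the terminal metabolite of every chain. This guarantees a
#' feasible model with a nonzero optimum equal to the smallest uptake bound.
#' `nExtraEdges` additional random conversion reactions (about a third of
#' them reversible) are then sprinkled between random metabolites. The
#' construction is a pure function of its arguments: the same seed always
#' yields the same model, and the caller's RNG stream is left untouched.
#'
#' @param nPathways number of parallel chains (>= 1).
#' @param pathwayLength metabolites per chain (>= 1).
#' @param nExtraEdges number of extra random conversion reactions (>= 0).
#' @param seed integer seed.
#' @return a [GEM-class] whose [optimizeFlux()] status is `"optimal"`.
#' @export
makeRandomGEM <- function(nPathways = 2, pathwayLength = 4, nExtraEdges = 2,
                          seed = 1L) {
  if (nPathways < 1 || pathwayLength < 1 || nExtraEdges < 0)
    stopf("nPathways and pathwayLength must be >= 1 and nExtraEdges >= 0")
  withSeed(seed, {
    metIds <- as.vector(vapply(seq_len(nPathways), function(p)
      sprintf("M%d_%d", p, seq_len(pathwayLength)), character(pathwayLength)))
    mets <- data.frame(id = metIds, compartment = "c",
                       formula = sample(c("C6H12O6", "C3H4O3", "H2O",
                                          NA_character_),
                                        length(metIds), replace = TRUE),
                       stringsAsFactors = FALSE)
    rxns <- list(); stoich <- list()
    addRxn <- function(id, s, lb, ub, obj = 0) {
      rxns[[length(rxns) + 1L]] <<- data.frame(
        id = id, lowerBound = lb, upperBound = ub,
        objectiveCoefficient = obj, stringsAsFactors = FALSE)
      stoich[[id]] <<- s
    }
    for (p in seq_len(nPathways)) {
      addRxn(sprintf("UPT%d", p),
             stats::setNames(1, sprintf("M%d_1", p)),
             0, round(stats::runif(1, 1, 10), 3))
      if (pathwayLength > 1)
        for (s_ in seq_len(pathwayLength - 1))
          addRxn(sprintf("R%d_%d", p, s_),
                 stats::setNames(c(-1, 1), sprintf("M%d_%d", p, s_ + 0:1)),
                 0, 1000)
    }
    addRxn("BIO",
           stats::setNames(rep(-1, nPathways),
                           sprintf("M%d_%d", seq_len(nPathways), pathwayLength)),
           0, 1000, obj = 1)
    if (nExtraEdges > 0 && length(metIds) >= 2)
      for (k in seq_len(nExtraEdges)) {
        pair <- sample(metIds, 2)
        addRxn(sprintf("EX%d", k), stats::setNames(c(-1, 1), pair),
               if (stats::runif(1) < 1 / 3) -1000 else 0, 1000)
      }
    gem <- GEM(modelId = sprintf("random_%d", seed),
               compartments = c(c = "cytosol"),
               metabolites = mets, reactions = do.call(rbind, rxns),
               stoichiometry = stoich)
    tagCofactors(gem)
  })
}
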