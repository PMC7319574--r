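#' Default cofactor / currency metabolite base identifiers
#'
#' Ubiquitous small molecules (energy and redox carriers, water, protons,
#' inorganic ions) that connect very many reactions. Excluding them from graph
#' and path computations avoids biologically meaningless shortcuts. The list
#' is shipped as a plain-text file (`inst/extdata/cofactors.txt`) and is fully
#' user-overridable in [tagCofactors()] and the command-line interface.
#'
#' @return character vector of lower-case base ids (compartment suffixes
#'   stripped).
#' @examples
#' defaultCofactors()
#' @export
defaultCofactors <- function() {
  path <- system.file("extdata", "cofactors.txt", package = "fluxgraph")
  if (nzchar(path)) {
    x <- readLines(path, warn = FALSE)
    x <- trimws(sub("#.*", "", x))
    x[nzchar(x)]
  } else {
    c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "fad", "fadh2",
      "coa", "accoa", "h2o", "h", "co2", "o2", "nh4", "pi", "ppi", "so4",
      "q8", "q8h2", "gthrd", "gthox")
  }
}

#' Compartment-stripped base id of a metabolite
#'
#' Removes a trailing `_<compartment>` or `[<compartment>]` suffix when the
#' suffix names a declared compartment (the common convention for
#' multi-compartment model ids such as `atp_c` / `atp[m]`), plus a leading
#' `M_` species prefix if present.
#'
#' @param id character vector of metabolite ids.
#' @param compartmentIds declared compartment ids.
#' @return character vector of base ids.
#' @export
metaboliteBaseId <- function(id, compartmentIds = character()) {
  out <- id
  for (cid in compartmentIds) {
    suf <- paste0("_", cid)
    hit <- endsWith(out, suf) & nchar(out) > nchar(suf)
    out[hit] <- substr(out[hit], 1, nchar(out[hit]) - nchar(suf))
    brk <- paste0("[", cid, "]")
    hit <- endsWith(out, brk) & nchar(out) > nchar(brk)
    out[hit] <- substr(out[hit], 1, nchar(out[hit]) - nchar(brk))
  }
  sub("^[Mm]_", "", out)
}

#' Tag cofactor metabolites in a model
#'
#' A metabolite is tagged as a cofactor iff its compartment-stripped base id
#' (case-insensitive, see [metaboliteBaseId()]) is in `cofactorBaseIds`.
#' Tagging is idempotent and replaces any previous tagging.
#'
#' @param gem a [GEM-class].
#' @param cofactorBaseIds character vector of base ids; defaults to
#'   [defaultCofactors()].
#' @return the updated `GEM`; the number of tagged metabolites is
#'   `sum(metabolites(gem)$isCofactor)`.
#' @examples
#' gem <- tagCofactors(makeToyGEM("TOY6"), character())
#' sum(metabolites(gem)$isCofactor)  # 0
#' gem <- tagCofactors(gem)
#' sum(metabolites(gem)$isCofactor)  # 2 (ATP, ADP)
#' @export
tagCofactors <- function(gem, cofactorBaseIds = defaultCofactors()) {
  base <- tolower(metaboliteBaseId(gem@metabolites$id, names(gem@compartments)))
  gem@metabolites$isCofactor <- base %in% tolower(cofactorBaseIds)
  gem
}
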