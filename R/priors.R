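#' Default per-structure concentration priors
#'
#' Builds the table of Gaussian (mean, sd) protein and lipid concentration
#' priors, in mg/mL, used by [fill_concentrations()]. One row per
#' (structure, tubule type); `tubule_type == "any"` rows apply to every type
#' without a more specific entry. The defaults encode the measured
#' per-structure concentrations of healthy mouse kidney: proximal-tubule
#' cytoplasm 194.3+/-18.4 protein and 52.2+/-9.5 lipid, distal 170.8+/-16.1 and
#' 62.4+/-10.3, collecting duct 138.5+/-19.7 and 40.2+/-13.1; nuclear protein
#' 166.8/130.7/134.7 for proximal/distal/collecting duct with negligible
#' nuclear lipid; region-dependent interstitial (microvasculature) protein and
#' lipid-droplet values; sex-dependent proximal cytoplasm protein.
#'
#' @param region anatomical region preset for the interstitial microvasculature
#'   and lipid-droplet entries: `"midpole"` (77.2+/-22.3 and 66.5+/-15.6),
#'   `"rostral"` (78.3+/-21.2 and 75.4+/-22.0) or
#'   `"caudal"` (100.5+/-29.4 and 84.7+/-22.9).
#' @param sex optional `"female"` / `"male"` preset replacing the proximal
#'   cytoplasm protein prior with 256.9+/-6.9 (female) or 245.5+/-3.2 (male).
#' @param droplet_day2 optional `"iri"` / `"control"` preset replacing the
#'   lipid-droplet lipid prior with the day-2 post-ischemia values
#'   76.8+/-25.8 (ischemic) or 92.8+/-22.7 (contralateral control).
#' @return A `data.frame` of class `concentration_priors` with columns
#'   `structure`, `tubule_type`, `protein_mean`, `protein_sd`, `lipid_mean`,
#'   `lipid_sd`.
#' @examples
#' p <- default_priors()
#' subset(p, structure == "cytoplasm")
#' @export
default_priors <- function(region = c("midpole", "rostral", "caudal"),
                           sex = NULL, droplet_day2 = NULL) {
  region <- match.arg(region)
  row <- function(structure, type, pm, ps, lm, ls)
    data.frame(structure = structure, tubule_type = type,
               protein_mean = pm, protein_sd = ps,
               lipid_mean = lm, lipid_sd = ls,
               stringsAsFactors = FALSE)
  micro <- switch(region,
    midpole = c(77.2, 22.3), rostral = c(78.3, 21.2), caudal = c(100.5, 29.4))
  droplet <- switch(region,
    midpole = c(66.5, 15.6), rostral = c(75.4, 22.0), caudal = c(84.7, 22.9))
  p <- rbind(
    row("cytoplasm", "proximal",        194.3, 18.4, 52.2,  9.5),
    row("cytoplasm", "distal",          170.8, 16.1, 62.4, 10.3),
    row("cytoplasm", "collecting_duct", 138.5, 19.7, 40.2, 13.1),
    row("nucleus",   "proximal",        166.8, 20.3,  5.0,  2.0),
    row("nucleus",   "distal",          130.7, 22.4,  5.0,  2.0),
    row("nucleus",   "collecting_duct", 134.7, 19.3,  5.0,  2.0),
    row("nucleolus", "any",             210.0, 25.0,  8.0,  3.0),
    row("brush_border", "any",          125.0, 15.0, 35.4, 11.2),
    row("lumen",     "any",              15.0,  8.0,  5.0,  3.0),
    row("microvasculature", "any",  micro[1], micro[2], 20.0, 8.0),
    row("lipid_droplet", "any",          30.0, 10.0, droplet[1], droplet[2])
  )
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("female", "male"))
    v <- if (sex == "female") c(256.9, 6.9) else c(245.5, 3.2)
    p <- set_prior(p, "cytoplasm", "proximal",
                   protein_mean = v[1], protein_sd = v[2])
  }
  if (!is.null(droplet_day2)) {
    droplet_day2 <- match.arg(droplet_day2, c("iri", "control"))
    v <- if (droplet_day2 == "iri") c(76.8, 25.8) else c(92.8, 22.7)
    p <- set_prior(p, "lipid_droplet", "any",
                   lipid_mean = v[1], lipid_sd = v[2])
  }
  validate_priors(p)
}

#' Override one prior entry
#'
#' @param priors a priors table from [default_priors()].
#' @param structure,tubule_type the entry to modify (added if absent).
#' @param protein_mean,protein_sd,lipid_mean,lipid_sd replacement values;
#'   `NULL` keeps the current value.
#' @return The modified priors table.
#' @export
set_prior <- function(priors, structure, tubule_type = "any",
                      protein_mean = NULL, protein_sd = NULL,
                      lipid_mean = NULL, lipid_sd = NULL) {
  i <- which(priors$structure == structure & priors$tubule_type == tubule_type)
  if (length(i) == 0L) {
    priors <- rbind(priors, data.frame(
      structure = structure, tubule_type = tubule_type,
      protein_mean = protein_mean %||% 0, protein_sd = protein_sd %||% 0,
      lipid_mean = lipid_mean %||% 0, lipid_sd = lipid_sd %||% 0,
      stringsAsFactors = FALSE))
    return(validate_priors(priors))
  }
  if (!is.null(protein_mean)) priors$protein_mean[i] <- protein_mean
  if (!is.null(protein_sd))   priors$protein_sd[i]   <- protein_sd
  if (!is.null(lipid_mean))   priors$lipid_mean[i]   <- lipid_mean
  if (!is.null(lipid_sd))     priors$lipid_sd[i]     <- lipid_sd
  validate_priors(priors)
}

validate_priors <- function(p, rho_total = 1000) {
  bad <- character(0)
  if (any(p$protein_mean < 0) || any(p$lipid_mean < 0))
    bad <- c(bad, "negative mean")
  if (any(p$protein_sd < 0) || any(p$lipid_sd < 0))
    bad <- c(bad, "negative sd")
  if (any(p$protein_mean + p$lipid_mean >= rho_total))
    bad <- c(bad, sprintf("protein_mean + lipid_mean >= rho_total (%g)", rho_total))
  if (length(bad))
    stop("invalid priors: ", paste(bad, collapse = "; "), call. = FALSE)
  class(p) <- c("concentration_priors", "data.frame")
  p
}

# Look up the prior row for a structure / tubule type, falling back to "any".
prior_lookup <- function(priors, structure, tubule_type) {
  i <- which(priors$structure == structure & priors$tubule_type == tubule_type)
  if (length(i) == 0L)
    i <- which(priors$structure == structure & priors$tubule_type == "any")
  if (length(i) == 0L)
    stop(sprintf("no prior entry for structure '%s' (tubule type '%s')",
                 structure, tubule_type), call. = FALSE)
  priors[i[1], ]
}
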