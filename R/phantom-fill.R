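#' Fill a phantom layout with ground-truth concentrations
#'
#' Draws one (protein, lipid) pair per structure per tubule from the Gaussian
#' priors (truncated at zero), paints each structure with its constant draw,
#' and sets water to `rho_total - protein - lipid` at every pixel so the
#' three planes sum exactly to the total density constant. Lipid droplets
#' draw one pair per droplet instance so the across-droplet distribution
#' follows the prior. The interstitial microvasculature draws one pair per
#' image. Draws that would make water negative are re-drawn; a truncation
#' rate above 1% raises a warning.
#'
#' @param gt a `tissue_ground_truth` from [sample_tissue_layout()] or
#'   [sample_droplet_field()].
#' @param priors a priors table from [default_priors()].
#' @param seed integer seed.
#' @param rho_total total mass density constant in mg/mL (protein + lipid +
#'   water at every tissue pixel); default 1000.
#' @return The input `gt` with `conc` (list of `protein`, `lipid`, `water`
#'   matrices in mg/mL), `rho_total`, and a `draws` table recording every
#'   per-structure draw.
#' @examples
#' gt <- sample_tissue_layout(phantom_config(side = 192, n_tubules = 3), seed = 1)
#' gt <- fill_concentrations(gt, default_priors(), seed = 2)
#' range(gt$conc$protein + gt$conc$lipid + gt$conc$water)  # == rho_total
#' @export
fill_concentrations <- function(gt, priors = default_priors(), seed = 1,
                                rho_total = 1000) {
  stopifnot(inherits(gt, "tissue_ground_truth"))
  priors <- validate_priors(priors, rho_total)
  with_seed(seed, fill_impl(gt, priors, rho_total, seed))
}

fill_impl <- function(gt, priors, rho_total, seed) {
  side <- gt$side
  protein <- matrix(0, side, side)
  lipid <- matrix(0, side, side)
  redraws <- 0L
  n_draws <- 0L

  draw_pair <- function(structure, type) {
    pr <- prior_lookup(priors, structure, type)
    for (it in seq_len(100L)) {
      p <- rnorm(1, pr$protein_mean, pr$protein_sd)
      l <- rnorm(1, pr$lipid_mean, pr$lipid_sd)
      n_draws <<- n_draws + 1L
      if (p >= 0 && l >= 0 && p + l < rho_total) return(c(p, l))
      redraws <<- redraws + 1L
    }
    c(max(0, pr$protein_mean), max(0, pr$lipid_mean))
  }

  rec <- list()
  add_rec <- function(tubule, structure, droplet, pl) {
    rec[[length(rec) + 1L]] <<- data.frame(
      tubule = tubule, structure = structure, droplet = droplet,
      protein = pl[1], lipid = pl[2], stringsAsFactors = FALSE)
  }

  # Interstitium: one draw per image.
  if (any(gt$masks$microvasculature)) {
    pl <- draw_pair("microvasculature", "any")
    protein[gt$masks$microvasculature] <- pl[1]
    lipid[gt$masks$microvasculature] <- pl[2]
    add_rec(NA_integer_, "microvasculature", NA_integer_, pl)
  }

  labels <- gt$tubule_labels
  for (i in gt$tubules$tubule) {
    type <- gt$tubules$type[gt$tubules$tubule == i]
    inst <- labels == i
    paint <- function(mask, pl) {
      protein[mask] <<- pl[1]
      lipid[mask] <<- pl[2]
    }
    pl <- draw_pair("cytoplasm", type)
    paint(inst, pl)  # substructures repainted below
    add_rec(i, "cytoplasm", NA_integer_, pl)
    for (s in c("lumen", "brush_border", "nuclei", "nucleoli")) {
      mask <- inst & gt$masks[[s]]
      if (!any(mask)) next
      structure_name <- switch(s, nuclei = "nucleus", nucleoli = "nucleolus", s)
      pl <- draw_pair(structure_name, type)
      paint(mask, pl)
      add_rec(i, structure_name, NA_integer_, pl)
    }
  }

  # Droplets: one draw per droplet instance.
  drop_ids <- which(tabulate(gt$droplet_labels[gt$droplet_labels > 0L]) > 0L)
  for (d in drop_ids) {
    mask <- gt$droplet_labels == d
    tub <- gt$droplet_tubule[d]
    type <- gt$tubules$type[gt$tubules$tubule == tub]
    pl <- draw_pair("lipid_droplet", type)
    protein[mask] <- pl[1]
    lipid[mask] <- pl[2]
    add_rec(tub, "lipid_droplet", d, pl)
  }

  rate <- if (n_draws > 0) redraws / n_draws else 0
  if (rate > 0.01)
    warning(sprintf(
      "truncation rate %.2f%% of concentration draws exceeded 1%%", 100 * rate))

  gt$conc <- list(protein = protein, lipid = lipid,
                  water = rho_total - protein - lipid)
  gt$rho_total <- rho_total
  gt$draws <- do.call(rbind, rec)
  gt$fill_seed <- seed
  gt
}
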