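#' @import methods
#' @importFrom stats dnorm qnorm pnorm rnorm rbinom runif median sd var
#'   density acf ar lm coef pf quantile setNames aggregate
#' @importFrom utils read.csv write.csv head capture.output packageVersion
#' @importFrom tools md5sum
#' @importFrom Rcpp evalCpp
#' @useDynLib parasitoidQG, .registration = TRUE
NULL

#' Validated haplodiploid pedigree
#'
#' Holds a topologically ordered pedigree in which females are diploid
#' (fertilized eggs, dam and sire possible) and males are haploid
#' (unfertilized eggs, dam only, never a sire field). Construct with
#' [buildPedigree()]; slots are not meant to be touched directly.
#'
#' @slot ped data.frame with columns `id`, `sex` ("F"/"M"), `dam`, `sire`
#'   (character; `NA` = unknown parent, treated as a unique unrelated
#'   founder), ordered so that parents precede offspring.
#' @export
setClass("HaploPedigree", representation(ped = "data.frame"))

setValidity("HaploPedigree", function(object) {
  p <- object@ped
  need <- c("id", "sex", "dam", "sire")
  if (!all(need %in% names(p))) {
    return(paste("pedigree table must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(p$id)) return("duplicate individual ids")
  if (!all(p$sex %in% c("F", "M"))) return("sex must be 'F' or 'M'")
  if (any(!is.na(p$sire[p$sex == "M"]))) {
    return("haploid males arise from unfertilized eggs and cannot have a sire")
  }
  pos <- match(p$id, p$id)
  dpos <- match(p$dam, p$id)
  spos <- match(p$sire, p$id)
  if (any(dpos >= pos, na.rm = TRUE) || any(spos >= pos, na.rm = TRUE)) {
    return("parents must precede offspring (pedigree not topologically ordered)")
  }
  TRUE
})

#' Additive relatedness matrix
#'
#' Symmetric matrix of additive relationships a_ij = 2 x coancestry under
#' haplodiploid transmission, with individual ids as dimnames. Built by
#' [haplodiploidAmatrix()]; subset with [phenotypedSubmatrix()].
#'
#' @slot entries symmetric numeric matrix with matching row/col names.
#' @export
setClass("RelatednessMatrix", representation(entries = "matrix"))

setValidity("RelatednessMatrix", function(object) {
  m <- object@entries
  if (nrow(m) != ncol(m)) return("matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m))) {
    return("matrix must carry identical row and column ids")
  }
  if (!isSymmetric(unname(m), tol = 1e-8)) return("matrix must be symmetric")
  TRUE
})

#' Posterior samples from the liability-threshold animal model
#'
#' MCMC draws of the variance components (additive, testing day, mother),
#' the intercept and the per-draw narrow-sense heritability
#' h2 = Va / (Va + Vday + Vmother + Vr + Vlink), together with the
#' configuration that produced them. Created by [fitThresholdModel()].
#'
#' @slot draws data.frame with columns `mu`, `va`, `vday`, `vmother`, `h2`,
#'   one row per retained draw.
#' @slot config list of sampler settings (link, iteration counts, prior,
#'   fixed residual variance, seed).
#' @export
setClass("ThresholdModelFit",
         representation(draws = "data.frame", config = "list"))

setValidity("ThresholdModelFit", function(object) {
  need <- c("mu", "va", "vday", "vmother", "h2")
  if (!all(need %in% names(object@draws))) {
    return(paste("draws must have columns", paste(need, collapse = ", ")))
  }
  h2 <- object@draws$h2
  if (any(h2 < 0 | h2 >= 1)) return("h2 draws must lie in [0, 1)")
  if (any(object@draws$va < 0)) return("variance draws must be non-negative")
  TRUE
})

#' Trajectory of a truncation-selection experiment
#'
#' Per-female assay records and per-line, per-generation summaries from
#' [runExperiment()], the inputs to realized-heritability analysis.
#'
#' @slot records data.frame of per-female assays (line, generation, female,
#'   counts, day-standardized killing rate, breeding value, selected flag).
#' @slot summary data.frame of per-line, per-generation means (mean of all
#'   females, of the selected parents, control-vial mean survival, the host
#'   survival used).
#' @slot config list, the [selectionConfig()] used.
#' @export
setClass("SelectionTrajectory",
         representation(records = "data.frame", summary = "data.frame",
                        config = "list"))

setValidity("SelectionTrajectory", function(object) {
  need <- c("line", "generation", "mean_all", "mean_selected")
  if (!all(need %in% names(object@summary))) {
    return(paste("summary must have columns", paste(need, collapse = ", ")))
  }
  TRUE
})
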