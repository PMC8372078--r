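#' Pedigree accessors
#'
#' `pedTable()` returns the ordered pedigree data.frame, `pedIds()` the ids
#' in topological order.
#'
#' @param object a [HaploPedigree-class].
#' @return data.frame or character vector.
#' @export
setGeneric("pedTable", function(object) standardGeneric("pedTable"))

#' @rdname pedTable
#' @export
setGeneric("pedIds", function(object) standardGeneric("pedIds"))

#' Relatedness matrix accessor
#'
#' @param object a [RelatednessMatrix-class].
#' @return the numeric matrix of additive relationships.
#' @export
setGeneric("relatedness", function(object) standardGeneric("relatedness"))

#' Posterior draws accessor
#'
#' @param object a [ThresholdModelFit-class].
#' @return data.frame of retained MCMC draws.
#' @export
setGeneric("draws", function(object) standardGeneric("draws"))

#' Selection-trajectory accessors
#'
#' `trajectorySummary()` returns the per-line, per-generation means;
#' `trajectoryRecords()` the per-female assay records.
#'
#' @param object a [SelectionTrajectory-class].
#' @return data.frame.
#' @export
setGeneric("trajectorySummary",
           function(object) standardGeneric("trajectorySummary"))

#' @rdname trajectorySummary
#' @export
setGeneric("trajectoryRecords",
           function(object) standardGeneric("trajectoryRecords"))

# ---- methods ----

#' @rdname pedTable
setMethod("pedTable", "HaploPedigree", function(object) object@ped)

#' @rdname pedTable
setMethod("pedIds", "HaploPedigree", function(object) object@ped$id)

#' @rdname relatedness
setMethod("relatedness", "RelatednessMatrix", function(object) object@entries)

#' @rdname draws
setMethod("draws", "ThresholdModelFit", function(object) object@draws)

#' @rdname trajectorySummary
setMethod("trajectorySummary", "SelectionTrajectory",
          function(object) object@summary)

#' @rdname trajectorySummary
setMethod("trajectoryRecords", "SelectionTrajectory",
          function(object) object@records)

setMethod("show", "HaploPedigree", function(object) {
  p <- object@ped
  cat("HaploPedigree with", nrow(p), "individuals (",
      sum(p$sex == "F"), "diploid females,", sum(p$sex == "M"),
      "haploid males ),", sum(is.na(p$dam) & is.na(p$sire)), "founders\n")
})

setMethod("show", "RelatednessMatrix", function(object) {
  m <- object@entries
  cat("RelatednessMatrix over", nrow(m), "individuals; a = 2 x coancestry",
      "(haplodiploid)\n")
  cat("  mean off-diagonal:",
      format(mean(m[upper.tri(m)]), digits = 3), "\n")
})

setMethod("show", "ThresholdModelFit", function(object) {
  d <- object@draws
  cat("ThresholdModelFit (", object@config$link, " link, ",
      nrow(d), " retained draws )\n", sep = "")
  for (p in c("va", "vday", "vmother", "h2")) {
    hpd <- hpdInterval(d[[p]], 0.95)
    cat(sprintf("  %-8s mode %.3f  95%% HPD (%.3f, %.3f)\n",
                p, posteriorMode(d[[p]]), hpd[1], hpd[2]))
  }
})

setMethod("show", "SelectionTrajectory", function(object) {
  s <- object@summary
  cat("SelectionTrajectory:", length(unique(s$line)), "lines x",
      max(s$generation) + 1, "generations,",
      nrow(object@records), "female assays\n")
})
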