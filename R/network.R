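#' Region-of-interest channel sets
#'
#' The three ROIs of the connectivity contrasts: the bilateral frontal area
#' (F3, Fz, F4) and the motor channels of the left (C5, CP3, P7) and right
#' (C6, CP4, P8) hemispheres. Central (Cz, Pz) and occipital (O1, O2)
#' channels are excluded from all summaries, keeping three channels per ROI.
#'
#' @param name one of `"Frontal"`, `"LHem"`, `"RHem"`.
#' @return character vector of three channel labels.
#' @export
roi_channels <- function(name = c("Frontal", "LHem", "RHem")) {
  name <- match.arg(name)
  switch(name,
         Frontal = c("F3", "Fz", "F4"),
         LHem = c("C5", "CP3", "P7"),
         RHem = c("C6", "CP4", "P8"))
}

#' The five ROI contrasts
#'
#' @return a named list mapping contrast label to a pair of ROI names:
#'   hemisphere-to-frontal (both sides), between-hemisphere, and the two
#'   within-hemisphere contrasts.
#' @export
roi_contrasts <- function() {
  list("LHem-Frontal" = c("LHem", "Frontal"),
       "RHem-Frontal" = c("RHem", "Frontal"),
       "LHem-RHem" = c("LHem", "RHem"),
       "within-LHem" = c("LHem", "LHem"),
       "within-RHem" = c("RHem", "RHem"))
}

# Row indices (into a pair table) of the links joining roiA and roiB
# (9 between-ROI pairs, or the 3 within-ROI pairs when roiA == roiB).
roi_pair_index <- function(pairs, roiA, roiB) {
  a <- roi_channels(roiA); b <- roi_channels(roiB)
  if (roiA == roiB) {
    which(pairs$chan_i %in% a & pairs$chan_j %in% a)
  } else {
    which((pairs$chan_i %in% a & pairs$chan_j %in% b) |
            (pairs$chan_i %in% b & pairs$chan_j %in% a))
  }
}

#' Link-stability filter across trials and participants
#'
#' A link (channel pair, per window) is retained iff it is significant in at
#' least `within_thr` of a subject's trials for at least `across_thr` of the
#' subjects; everything else is discarded from the ROI summaries. Defaults
#' follow the 60% within- / 50% across-participant rule.
#'
#' @param masks list over subjects of logical `pairs x windows x trials`
#'   keep arrays (one (session, condition, metric) slice per subject), e.g.
#'   `mask$keep[[metric]]` from [significance_prune()].
#' @param within_thr minimum fraction of a subject's trials (default 0.60).
#' @param across_thr minimum fraction of subjects meeting the within
#'   criterion (default 0.50).
#'
#' @return logical `pairs x windows` matrix of retained links.
#' @export
stability_filter <- function(masks, within_thr = 0.60, across_thr = 0.50) {
  if (length(masks) == 0L) stop("`masks` must contain at least one subject")
  per_subject <- lapply(masks, function(k) {
    stopifnot(is.logical(k), length(dim(k)) == 3L)
    apply(k, c(1L, 2L), mean) >= within_thr
  })
  frac <- Reduce(`+`, per_subject) / length(per_subject)
  frac >= across_thr
}

#' ROI-level mean connectivity for one study cell
#'
#' Averages the pruned connectivity over the retained links joining two ROIs
#' (9 between-ROI pairs, or the 3 within-ROI pairs when `roiA == roiB`).
#' For each retained link the link value is the mean over that subject's
#' significant trials (pruned-out trials are disregarded, not counted as
#' zero); the cell value is the mean over retained links. Cells with no
#' retained link (or no significant trial on any retained link) yield `NA`,
#' never zero.
#'
#' @param pruned a pruned `connectivity_tensor` (from [significance_prune()]).
#' @param mask the matching `significance_mask`.
#' @param retained logical `pairs x windows` matrix from [stability_filter()].
#' @param roiA,roiB ROI names (equal names invoke the within-ROI variant).
#' @param metric which metric to summarise.
#'
#' @return a data.frame with one row per window: subject, session, condition,
#'   metric, window, contrast, value.
#' @export
roi_connectivity <- function(pruned, mask, retained, roiA, roiB,
                             metric = names(pruned$values)[1L]) {
  stopifnot(inherits(pruned, "connectivity_tensor"))
  for (nm in unique(c(roi_channels(roiA), roi_channels(roiB)))) {
    if (!nm %in% pruned$channel_labels)
      stop("ROI channel ", nm, " absent from the tensor")
  }
  idx <- roi_pair_index(pruned$pairs, roiA, roiB)
  v <- pruned$values[[metric]]
  k <- mask$keep[[metric]]
  out <- lapply(seq_len(nrow(pruned$windows)), function(w) {
    links <- idx[retained[idx, w]]
    val <- NA_real_
    if (length(links)) {
      link_means <- vapply(links, function(l) {
        kept <- k[l, w, ]
        if (!any(kept)) return(NA_real_)
        mean(v[l, w, kept])
      }, 0)
      if (any(!is.na(link_means))) val <- mean(link_means, na.rm = TRUE)
    }
    data.frame(subject = pruned$subject_id, session = pruned$session,
               condition = pruned$condition, metric = metric,
               window = pruned$windows$label[w],
               contrast = if (roiA == roiB) paste0("within-", roiA)
                          else paste(roiA, roiB, sep = "-"),
               value = val, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Channels never entering any ROI summary
#' @return character vector (Cz, Pz, O1, O2).
#' @export
excluded_channels <- function() c("Cz", "Pz", "O1", "O2")
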