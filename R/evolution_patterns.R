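# Rule-based classification of per-patient relapse biology into three
# genetic/epigenetic evolution patterns, from longitudinal plasma 2HG,
# bone marrow methylation, and mutation data:
#   pattern 1 - 2HG and methylation both remain suppressed at relapse
#               (relapse driven by non-IDH clones, e.g. growing KRAS);
#   pattern 2 - 2HG remains suppressed but methylation rebounds
#               (typically via an emergent TET2 mutation);
#   pattern 3 - both rebound together with an IDH homolog switch
#               (e.g. emergent IDH1 R132C during IDH2 inhibition).

#' Build a patient trajectory table
#'
#' @param patient_id identifier.
#' @param timepoint ordered labels; must include "baseline" and, for
#'   pattern classification, "relapse" (a "response" or other
#'   on-treatment point is expected in between).
#' @param mean_beta mean methylation beta per timepoint.
#' @param hg2 plasma 2HG level per timepoint (ng/ml or relative).
#' @param idh_vaf IDH mutation VAF per timepoint.
#' @param blast bone marrow blast percentage per timepoint (optional).
#' @param response response label per timepoint (optional).
#' @return data.frame of class `patient_trajectory`, rows in the given
#'   timepoint order.
#' @export
patient_trajectory <- function(patient_id, timepoint, mean_beta = NA_real_,
                               hg2 = NA_real_, idh_vaf = NA_real_,
                               blast = NA_real_, response = NA_character_) {
  if (anyDuplicated(timepoint)) stop_input("timepoints must be distinct")
  out <- data.frame(patient_id = patient_id, timepoint = timepoint,
                    mean_beta = mean_beta, hg2 = hg2, idh_vaf = idh_vaf,
                    blast = blast, response = response,
                    stringsAsFactors = FALSE)
  class(out) <- c("patient_trajectory", "data.frame")
  out
}

traj_value <- function(traj, tp, col) {
  i <- match(tp, traj$timepoint)
  if (is.na(i)) NA_real_ else traj[[col]][i]
}

#' Classify a relapse trajectory into an evolution pattern
#'
#' Decision rules (thresholds are this pipeline's choices, configurable,
#' and reported with every call):
#' \itemize{
#'   \item 2HG suppressed at relapse: relapse 2HG <= (1 - r) x baseline
#'     2HG, with `r = 0.5` by default; otherwise 2HG has rebounded.
#'   \item methylation rebound at relapse: relapse mean beta >=
#'     baseline mean beta - delta, with `delta = 0.01`; i.e. the
#'     treatment-induced demethylation has been lost to within delta.
#'   \item pattern 1 = 2HG suppressed and methylation still suppressed;
#'     pattern 2 = 2HG suppressed and methylation rebound; pattern 3 =
#'     2HG rebound and methylation rebound AND an IDH homolog-switch
#'     mutation (emergent IDH1 while the patient's mutant gene is IDH2,
#'     or vice versa) among the relapse-emergent genes. Anything else is
#'     unclassified, with the evidence retained.
#' }
#'
#' @param trajectory a [patient_trajectory()] containing "baseline" and
#'   "relapse" rows.
#' @param relapse_genes character vector of genes with emergent
#'   mutations at relapse (from [detect_relapse_events()]).
#' @param idh_gene the patient's mutant IDH gene ("IDH1" or "IDH2").
#' @param r 2HG suppression threshold (default 0.5).
#' @param delta methylation rebound tolerance on the beta scale
#'   (default 0.01).
#' @return list of class `evolution_pattern`: `pattern` (1, 2, 3 or NA
#'   = unclassified), `evidence` (named list: hg2_state, meth_state,
#'   homolog_switch, relapse_genes, thresholds), `reason` for
#'   unclassified calls.
#' @export
classify_evolution_pattern <- function(trajectory,
                                       relapse_genes = character(),
                                       idh_gene = "IDH2",
                                       r = 0.5, delta = 0.01) {
  needed <- c("baseline", "relapse")
  if (!all(needed %in% trajectory$timepoint))
    stop_input("trajectory must contain baseline and relapse timepoints")
  hg2_bl <- traj_value(trajectory, "baseline", "hg2")
  hg2_rel <- traj_value(trajectory, "relapse", "hg2")
  beta_bl <- traj_value(trajectory, "baseline", "mean_beta")
  beta_rel <- traj_value(trajectory, "relapse", "mean_beta")
  unclassified <- function(reason, hg2_state = NA, meth_state = NA,
                           switch_ = NA) {
    structure(list(pattern = NA_integer_,
                   evidence = list(hg2_state = hg2_state,
                                   meth_state = meth_state,
                                   homolog_switch = switch_,
                                   relapse_genes = relapse_genes,
                                   thresholds = c(r = r, delta = delta)),
                   reason = reason),
              class = "evolution_pattern")
  }
  if (is.na(hg2_bl) || is.na(hg2_rel))
    return(unclassified("missing 2HG series"))
  if (is.na(beta_bl) || is.na(beta_rel))
    return(unclassified("missing methylation series"))
  hg2_suppressed <- hg2_rel <= (1 - r) * hg2_bl
  meth_rebound <- beta_rel >= beta_bl - delta
  homolog <- if (idh_gene == "IDH2") "IDH1" else "IDH2"
  homolog_switch <- homolog %in% relapse_genes
  hg2_state <- if (hg2_suppressed) "suppressed" else "rebound"
  meth_state <- if (meth_rebound) "rebound" else "suppressed"
  pattern <- if (hg2_suppressed && !meth_rebound) 1L
    else if (hg2_suppressed && meth_rebound) 2L
    else if (!hg2_suppressed && meth_rebound && homolog_switch) 3L
    else NA_integer_
  structure(list(pattern = pattern,
                 evidence = list(hg2_state = hg2_state,
                                 meth_state = meth_state,
                                 homolog_switch = homolog_switch,
                                 relapse_genes = relapse_genes,
                                 thresholds = c(r = r, delta = delta)),
                 reason = if (is.na(pattern))
                   "2HG rebound without homolog switch" else NULL),
            class = "evolution_pattern")
}

#' Tidy long-format summary of a patient trajectory
#'
#' One row per (timepoint, measure) for the scalar measures (idh_vaf,
#' blast, hg2, mean_beta), plus five-number beta summaries per timepoint
#' when a beta matrix is supplied (for violin-style plotting).
#'
#' @param trajectory a [patient_trajectory()].
#' @param beta_by_timepoint optional named list of per-timepoint beta
#'   vectors for this patient.
#' @return list: `long` (data.frame `timepoint`, `measure`, `value`;
#'   missing measures omitted with a `flags` note), `beta_quantiles`
#'   (data.frame `timepoint`, `min`, `q1`, `median`, `q3`, `max`).
#' @export
summarize_trajectory <- function(trajectory, beta_by_timepoint = NULL) {
  measures <- c("idh_vaf", "blast", "hg2", "mean_beta")
  rows <- list(); flags <- character()
  for (m in measures) {
    v <- trajectory[[m]]
    if (all(is.na(v))) {
      flags <- c(flags, sprintf("measure '%s' missing; rows omitted", m))
      next
    }
    keep <- !is.na(v)
    rows[[m]] <- data.frame(timepoint = trajectory$timepoint[keep],
                            measure = m, value = v[keep],
                            stringsAsFactors = FALSE)
  }
  long <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
          else data.frame(timepoint = character(), measure = character(),
                          value = numeric())
  beta_q <- NULL
  if (!is.null(beta_by_timepoint)) {
    beta_q <- do.call(rbind, lapply(names(beta_by_timepoint), function(tp) {
      q <- stats::quantile(beta_by_timepoint[[tp]],
                           probs = c(0, .25, .5, .75, 1), names = FALSE)
      data.frame(timepoint = tp, min = q[1], q1 = q[2], median = q[3],
                 q3 = q[4], max = q[5], stringsAsFactors = FALSE)
    }))
  }
  list(long = long, beta_quantiles = beta_q, flags = flags)
}
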