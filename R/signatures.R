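# Panel assembly and candidate-signature set algebra.

#' Assemble a method panel from peptide lists
#'
#' Unsupervised selectors return several lists per method; the panel is the
#' union of the best-separating ones.  Each list is scored by the AUC of its
#' signature score on the supplied (Discovery) data, and the best list plus
#' any list within `auc_window` of it -- up to `max_lists` lists -- are
#' unioned.  This operationalises the study's review of list separation,
#' which kept the two gene-shaving lists with the largest AUCs.  A single
#' list (the supervised methods) passes through unchanged.
#'
#' @param lists A list of [new_peptide_list()] objects from one method.
#' @param X Processed matrix used for scoring (required for > 1 list).
#' @param labels Group labels aligned with `X` columns.
#' @param max_lists Maximum number of lists merged into the panel.
#' @param auc_window AUC tolerance below the best list.
#' @param name Panel name, e.g. `"GS_panel"`.
#' @return A list of class `peptide_panel`: `name`, `peptide_ids`,
#'   `constituent_lists`, `selection_rule` (per-list AUCs and the rule
#'   parameters).
#' @export
assemble_panel <- function(lists, X = NULL, labels = NULL, max_lists = 2L,
                           auc_window = 0.02,
                           name = paste0(lists[[1]]$name, "_panel")) {
  if (base::length(lists) < 1) stop("at least one peptide list is required")
  if (base::length(lists) == 1) {
    pl <- lists[[1]]
    return(structure(list(name = name, peptide_ids = pl$peptide_ids,
                          constituent_lists = pl$name,
                          selection_rule = list(type = "passthrough")),
                     class = "peptide_panel"))
  }
  if (is.null(X) || is.null(labels)) {
    stop("X and labels are required to rank more than one list")
  }
  aucs <- vapply(lists, function(pl) {
    if (base::length(pl$peptide_ids) == 0) return(NA_real_)
    signature_score(X, pl$peptide_ids, labels)$auc
  }, numeric(1))
  if (all(is.na(aucs))) stop("no non-empty lists to rank")
  best <- max(aucs, na.rm = TRUE)
  eligible <- which(!is.na(aucs) & aucs >= best - auc_window)
  eligible <- eligible[order(aucs[eligible], decreasing = TRUE)]
  chosen <- eligible[seq_len(min(max_lists, base::length(eligible)))]
  ids <- unique(unlist(lapply(lists[chosen], `[[`, "peptide_ids")))
  structure(list(
    name = name,
    peptide_ids = ids,
    constituent_lists = vapply(lists[chosen], `[[`, character(1), "name"),
    selection_rule = list(type = "auc_window", auc_window = auc_window,
                          max_lists = max_lists,
                          list_aucs = stats::setNames(
                            aucs, vapply(lists, `[[`, character(1), "name")))
  ), class = "peptide_panel")
}

new_candidate_signature <- function(name, peptide_ids, definition) {
  structure(list(name = name, peptide_ids = as.character(peptide_ids),
                 definition = definition,
                 excluded = base::length(peptide_ids) == 0),
            class = "candidate_signature")
}

#' @export
print.candidate_signature <- function(x, ...) {
  cat("<candidate_signature> ", x$name, " = ", x$definition, ": ",
      base::length(x$peptide_ids), " peptides",
      if (x$excluded) " (empty; excluded)" else "", "\n", sep = "")
  invisible(x)
}

#' Build the candidate peptide signatures CPS001-CPS007
#'
#' Combines the six method panels by set algebra:
#' \itemize{
#' \item CPS001 = GS n (RL u RF u EN)
#' \item CPS002 = sPCA u sIPCA u GS (union of unsupervised panels)
#' \item CPS003 = sPCA n sIPCA n GS (intersection of unsupervised panels)
#' \item CPS004 = RL u RF u EN (union of supervised panels)
#' \item CPS005 = RL n RF n EN (intersection of supervised panels)
#' \item CPS006 = union of all six panels
#' \item CPS007 = intersection of all six panels
#' }
#' Empty signatures are flagged `excluded` rather than dropped.  The
#' alternative definition GS n RL n RF n EN is computed and reported in the
#' `"alternative_cps001"` attribute but not carried forward (it was
#' considered and dropped for being too small).
#'
#' @param panels Named list with elements `sPCA_panel`, `sIPCA_panel`,
#'   `GS_panel`, `RL_panel`, `RF_panel`, `EN_panel` (panel objects or
#'   character vectors of peptide ids).
#' @return A named list of `candidate_signature` objects `CPS001..CPS007`,
#'   with attribute `alternative_cps001`.
#' @export
#' @examples
#' p <- list(sPCA_panel = c("1", "2"), sIPCA_panel = c("2", "3"),
#'           GS_panel = c("2", "4", "5"), RL_panel = c("4", "6"),
#'           RF_panel = c("4", "5"), EN_panel = "5")
#' sapply(build_candidate_signatures(p), function(s) length(s$peptide_ids))
build_candidate_signatures <- function(panels) {
  need <- c("sPCA_panel", "sIPCA_panel", "GS_panel",
            "RL_panel", "RF_panel", "EN_panel")
  missing <- setdiff(need, names(panels))
  if (base::length(missing) > 0) {
    stop("missing panels: ", paste(missing, collapse = ", "))
  }
  ids <- lapply(panels[need], peptide_ids_of)
  uns <- ids[c("sPCA_panel", "sIPCA_panel", "GS_panel")]
  sup <- ids[c("RL_panel", "RF_panel", "EN_panel")]
  sup_union <- Reduce(union, sup)
  sigs <- list(
    CPS001 = new_candidate_signature(
      "CPS001", intersect(ids$GS_panel, sup_union),
      "GS_panel n (RL_panel u RF_panel u EN_panel)"),
    CPS002 = new_candidate_signature(
      "CPS002", Reduce(union, uns),
      "sPCA_panel u sIPCA_panel u GS_panel"),
    CPS003 = new_candidate_signature(
      "CPS003", Reduce(intersect, uns),
      "sPCA_panel n sIPCA_panel n GS_panel"),
    CPS004 = new_candidate_signature(
      "CPS004", sup_union,
      "RL_panel u RF_panel u EN_panel"),
    CPS005 = new_candidate_signature(
      "CPS005", Reduce(intersect, sup),
      "RL_panel n RF_panel n EN_panel"),
    CPS006 = new_candidate_signature(
      "CPS006", Reduce(union, ids),
      "union of all six panels"),
    CPS007 = new_candidate_signature(
      "CPS007", Reduce(intersect, ids),
      "intersection of all six panels")
  )
  attr(sigs, "alternative_cps001") <- new_candidate_signature(
    "CPS001_alt", intersect(ids$GS_panel, Reduce(intersect, sup)),
    "GS_panel n RL_panel n RF_panel n EN_panel")
  sigs
}

#' Summarise candidate signatures
#'
#' @param sigs Output of [build_candidate_signatures()].
#' @return A data frame with `name`, `size`, `excluded`, `definition`.
#' @export
signature_summary <- function(sigs) {
  data.frame(
    name = vapply(sigs, `[[`, character(1), "name"),
    size = vapply(sigs, function(s) base::length(s$peptide_ids), integer(1)),
    excluded = vapply(sigs, `[[`, logical(1), "excluded"),
    definition = vapply(sigs, `[[`, character(1), "definition"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
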