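# Common container for selector output: a named, ordered set of peptide ids
# with the statistic that selected them.

#' Construct a peptide list
#'
#' @param name List name, e.g. `"sPCA1"`, `"GS2"`, `"RL"`.
#' @param peptide_ids Character vector of peptide ids (no duplicates).
#' @param method_params Named list of the parameters that produced the list.
#' @param scores Optional named numeric vector of per-peptide statistics
#'   (loading magnitude, adjusted p, Gini importance, selection frequency).
#' @return A list of class `peptide_list`.
#' @export
new_peptide_list <- function(name, peptide_ids, method_params = list(),
                             scores = NULL) {
  peptide_ids <- as.character(peptide_ids)
  if (anyDuplicated(peptide_ids)) stop("peptide list contains duplicate ids")
  structure(list(name = name, peptide_ids = peptide_ids,
                 method_params = method_params, scores = scores),
            class = "peptide_list")
}

#' @export
print.peptide_list <- function(x, ...) {
  cat("<peptide_list> ", x$name, ": ", base::length(x$peptide_ids),
      " peptides\n", sep = "")
  invisible(x)
}
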