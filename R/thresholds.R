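#' Classifier thresholds
#'
#' The phenotype rule tree has a single quantitative decision node, the CRP
#' concentration, plus a configurable list of body sites regarded as sterile.
#' Both live in a small threshold object so the algorithm can be re-run with
#' other cut-offs. The default CRP cut of 60 mg/L is the decision value of the
#' published classification algorithm this engine implements; comparison is
#' `crp >= cut` on the bacterial side, so a value exactly at the cut counts as
#' raised.
#'
#' @param crp_cut_mg_per_l Positive CRP decision value in mg/L.
#' @param sterile_sites Character vector of specimen sites treated as sterile.
#'   Urine is included: clean-catch/catheter urine counts as a sterile site in
#'   this framework.
#' @return A list of class `fm_thresholds`.
#' @export
#' @examples
#' classifier_thresholds()
#' classifier_thresholds(crp_cut_mg_per_l = 40)
classifier_thresholds <- function(crp_cut_mg_per_l = 60,
                                  sterile_sites = c(
                                    "blood", "CSF", "urine", "joint fluid",
                                    "pleural fluid", "bone"
                                  )) {
  if (!is.numeric(crp_cut_mg_per_l) || length(crp_cut_mg_per_l) != 1 ||
      !is.finite(crp_cut_mg_per_l) || crp_cut_mg_per_l <= 0) {
    abort("crp_cut_mg_per_l must be a single positive finite number")
  }
  sterile_sites <- as.character(sterile_sites)
  if (length(sterile_sites) == 0 || anyNA(sterile_sites) ||
      any(!nzchar(sterile_sites))) {
    abort("sterile_sites must be a non-empty character vector")
  }
  structure(
    list(
      crp_cut_mg_per_l = crp_cut_mg_per_l,
      sterile_sites = unique(sterile_sites)
    ),
    class = "fm_thresholds"
  )
}

#' @export
print.fm_thresholds <- function(x, ...) {
  cat("<fm_thresholds>\n")
  cat("  CRP cut:", x$crp_cut_mg_per_l, "mg/L (bacterial side is >= cut)\n")
  cat("  sterile sites:", paste(x$sterile_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Read and write classifier thresholds as YAML
#'
#' Round-trips the threshold configuration through a plain-text YAML file with
#' keys `crp_cut_mg_per_l` and `sterile_sites`.
#'
#' @param path File path.
#' @param thresholds An `fm_thresholds` object.
#' @return `read_thresholds()` returns an `fm_thresholds`;
#'   `write_thresholds()` returns `path` invisibly.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  classifier_thresholds(
    crp_cut_mg_per_l = cfg$crp_cut_mg_per_l,
    sterile_sites = unlist(cfg$sterile_sites)
  )
}

#' @rdname read_thresholds
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "fm_thresholds"))
  yaml::write_yaml(
    list(
      crp_cut_mg_per_l = thresholds$crp_cut_mg_per_l,
      sterile_sites = as.list(thresholds$sterile_sites)
    ),
    path
  )
  invisible(path)
}
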