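#' Top-k candidate features by model importance
#'
#' First stage of the biomarker funnel: take the k most important features
#' according to one genotype's classifier (default the heat-tolerant one,
#' whose drivers are the screening target). Ties are broken by feature id so
#' the ordering is stable.
#'
#' @param report a [categorize_features()] report, or an [mda_importance()]
#'   profile.
#' @param k number of candidates (study setting: 100).
#' @param model which genotype's importance to rank by when `report` is a
#'   `consistency_report`: `"a"`/`"b"` or a genotype label.
#' @return character vector of feature ids, most important first, with the
#'   importance scores attached as attribute `"importance"`.
#' @export
top_candidates <- function(report, k = 100, model = "tolerant") {
  if (inherits(report, "consistency_report")) {
    col <- if (model %in% c("a", report$genotype_a)) "mda_a"
           else if (model %in% c("b", report$genotype_b)) "mda_b"
           else stop("`model` must name one of the report's genotypes")
    imp <- stats::setNames(report$features[[col]], report$features$feature_id)
  } else if (inherits(report, "importance_profile")) {
    imp <- stats::setNames(report$mda, report$feature_id)
  } else stop("`report` must be a consistency_report or importance_profile")
  k <- min(k, length(imp))
  if (k == 0) return(character())
  ord <- order(-imp, names(imp))[seq_len(k)]
  out <- names(imp)[ord]
  attr(out, "importance") <- as.numeric(imp[ord])
  out
}

#' Expression-level filter of biomarker candidates
#'
#' Retains a candidate when it is either (clause 1) more abundant on average
#' in the heat-tolerant genotype than in the heat-sensitive one across
#' heat-stressed samples (above the control temperature), or (clause 2)
#' significantly up-regulated in the tolerant genotype at the extreme
#' temperature by a one-sided Welch t-test. Both clauses' evidence is kept
#' per candidate.
#'
#' @param candidates character vector from [top_candidates()] (importance
#'   attribute, if present, is carried through).
#' @param x the metabolome [omics_matrix()], both genotypes.
#' @param p_threshold one-sided p cutoff for clause 2 (default 0.05).
#' @param tolerant,sensitive genotype labels in `x`'s metadata.
#' @param control_temperature samples strictly above it count as stressed.
#' @return data.frame of class `biomarker_panel`, one row per retained
#'   candidate: rank, feature_id, importance, higher_abundance,
#'   upregulated, p_up.
#' @export
expression_filter <- function(candidates, x, p_threshold = 0.05,
                              tolerant = "tolerant", sensitive = "sensitive",
                              control_temperature = 25) {
  stopifnot(inherits(x, "omics_matrix"))
  md <- x$metadata
  if (!all(c(tolerant, sensitive) %in% md$genotype))
    stop("both genotype labels must be present in the metadata")
  ids <- intersect(candidates, rownames(x$values))
  imp <- attr(candidates, "importance")
  imp <- if (is.null(imp)) rep(NA_real_, length(candidates))
         else imp[match(ids, candidates)]

  stressed <- md$temperature_C > control_temperature
  t_max <- max(md$temperature_C)
  tol_stress <- md$genotype == tolerant & stressed
  sen_stress <- md$genotype == sensitive & stressed
  tol_max <- md$genotype == tolerant & md$temperature_C == t_max
  sen_max <- md$genotype == sensitive & md$temperature_C == t_max
  if (sum(tol_max) < 2 || sum(sen_max) < 2)
    stop("need >= 2 samples per genotype at the extreme temperature")

  v <- x$values[ids, , drop = FALSE]
  higher <- rowMeans(v[, tol_stress, drop = FALSE]) >
    rowMeans(v[, sen_stress, drop = FALSE])
  p_up <- vapply(ids, function(f)
    stats::t.test(v[f, tol_max], v[f, sen_max],
                  alternative = "greater")$p.value, numeric(1))
  up <- p_up < p_threshold

  keep <- higher | up
  out <- data.frame(feature_id = ids[keep],
                    importance = imp[keep],
                    higher_abundance = higher[keep],
                    upregulated = up[keep],
                    p_up = p_up[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$importance, out$feature_id), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "rule") <- sprintf(
    "higher mean in %s under stress OR one-sided p < %g at %g degC",
    tolerant, p_threshold, t_max)
  class(out) <- c("biomarker_panel", "data.frame")
  out
}

#' Attach annotation categories to a biomarker panel
#'
#' Looks every panel member up in a term -> features annotation (e.g. hormone
#' regulation / secondary metabolic defense / signal transduction classes).
#' Members found in several terms report all of them, with the
#' lexicographically first as primary; members absent from the annotation are
#' labelled `"unclassified"`.
#'
#' @param panel a [expression_filter()] panel.
#' @param annotation named list of feature-id vectors (e.g. from
#'   [read_gmt()]), or a two-column data.frame (term, feature_id).
#' @return the panel with `category` (primary) and `categories`
#'   (all, `;`-separated) columns added.
#' @export
annotate_panel <- function(panel, annotation) {
  stopifnot(inherits(panel, "biomarker_panel"))
  if (is.data.frame(annotation))
    annotation <- split(as.character(annotation[[2]]),
                        as.character(annotation[[1]]))
  cats <- lapply(panel$feature_id, function(f)
    sort(names(annotation)[vapply(annotation, function(s) f %in% s,
                                  logical(1))]))
  panel$category <- vapply(cats, function(cc)
    if (length(cc)) cc[1] else "unclassified", character(1))
  panel$categories <- vapply(cats, function(cc)
    if (length(cc)) paste(cc, collapse = ";") else "unclassified", character(1))
  panel
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat(sprintf("biomarker_panel: %d markers (%s)\n", nrow(x),
              attr(x, "rule") %||% "no rule recorded"))
  print(utils::head(as.data.frame(x), 10), row.names = FALSE)
  invisible(x)
}
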